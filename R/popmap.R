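#' Build a population genetic map from crossover events
#'
#' Each surviving event contributes its recombinant-gamete weight to the bin
#' containing its midpoint. An F2 population of n individuals carries 2n
#' gametes, so the genetic distance of a bin (or any interval) is
#' `cM = 100 * gamete-weighted CO count / (2n)`, and the recombination rate
#' is `cM / Mb` over the bin width.
#'
#' @param events a `co_events` data frame (events with status
#'   `removed_dco` are ignored).
#' @param grid the [build_bin_grid()] grid.
#' @param n number of individuals in the population (>= 1).
#' @param label population label.
#' @return A `population_map`: list with `label`, `n`, `gametes` (= 2n) and
#'   `bins` (data frame `chrom`, `bin`, `start`, `end`, `width_mb`,
#'   `co_gametes`, `cM`, `cM_per_Mb`).
#' @export
build_population_map <- function(events, grid, n, label = "population") {
  stopifnot(inherits(grid, "bin_grid"))
  if (!is_count(n) || n < 1) stop("n must be a positive integer")
  bins <- grid[order(grid$chrom, grid$bin),
               c("chrom", "bin", "start_p1", "end_p1")]
  names(bins) <- c("chrom", "bin", "start", "end")
  bins$width_mb <- (bins$end - bins$start) / 1e6
  bins$co_gametes <- 0
  ev <- events[events$status != "removed_dco", , drop = FALSE]
  if (nrow(ev) > 0L) {
    for (ch in unique(ev$chrom)) {
      sel <- ev$chrom == ch
      idx <- bin_index_of(grid, ch, ev$mid[sel])
      add <- tapply(ev$gametes[sel], idx, sum)
      rows <- which(bins$chrom == ch)[as.integer(names(add)) + 1L]
      bins$co_gametes[rows] <- bins$co_gametes[rows] + as.numeric(add)
    }
  }
  bins$cM <- 100 * bins$co_gametes / (2 * n)
  bins$cM_per_Mb <- bins$cM / bins$width_mb
  rownames(bins) <- NULL
  structure(list(label = label, n = n, gametes = 2L * n, bins = bins),
            class = "population_map")
}

#' Population map from simulation truth
#'
#' Builds the map an error-free caller would produce: every true gamete
#' crossover contributes one recombinant gamete to its bin.
#'
#' @param pop an [simulate_f2_population()] population.
#' @param grid the [build_bin_grid()] grid.
#' @param label population label.
#' @return A `population_map`.
#' @export
population_map_from_truth <- function(pop, grid, label = "truth") {
  stopifnot(inherits(pop, "f2_population"))
  tr <- pop$truth
  ev <- data.frame(sample = tr$sample, chrom = tr$chrom, start = tr$pos,
                   end = tr$pos, mid = tr$pos, left = NA_character_,
                   right = NA_character_, gametes = 1L,
                   region = NA_character_, status = "kept",
                   stringsAsFactors = FALSE)
  build_population_map(ev, grid, pop$n, label = label)
}

# gamete-weighted CO count of an interval (bins by midpoint)
interval_gametes <- function(map, chrom, start, end) {
  b <- map$bins
  mid <- (b$start + b$end) / 2
  sum(b$co_gametes[b$chrom == chrom & mid >= start & mid < end])
}

#' Genetic distance of a physical interval
#'
#' Sums the per-bin cM of all bins whose midpoint falls in
#' `[start, end)`.
#'
#' @param map a `population_map`.
#' @param chrom chromosome.
#' @param start,end interval in bp (parent-1 coordinates).
#' @return Genetic distance in cM.
#' @export
interval_cM <- function(map, chrom, start, end) {
  100 * interval_gametes(map, chrom, start, end) / map$gametes
}

#' Delimit pericentric regions from a control map
#'
#' Starting at the centromere bin, the pericentric interval is extended left
#' and right for as long as the windowed mean recombination rate stays below
#' `threshold` cM/Mb; the emitted interval is the maximal such contiguous
#' span. The rate is smoothed over a `window_mb` window first because single
#' ~1 Mb bins mostly carry zero observed crossovers at realistic population
#' sizes, which would make a raw threshold rule degenerate.
#'
#' @param map the control (untreated) `population_map`.
#' @param layout the [genome_layout()] (for centromere positions).
#' @param threshold pericentric rate threshold in cM/Mb (default 0.1).
#' @param window_mb smoothing window in Mb (default 10; rounded to an odd
#'   number of bins).
#' @param subtel_frac passed to [classify_regions()] for the flanking
#'   subtelomeric classes.
#' @return A `region_classification` whose pericentric intervals are the
#'   delimited spans; attribute `"spans"` holds a data frame `chrom`,
#'   `start`, `end`, `span_mb`.
#' @export
delimit_pericentric <- function(map, layout, threshold = 0.1, window_mb = 10,
                                subtel_frac = 0.1) {
  stopifnot(inherits(map, "population_map"), inherits(layout, "genome_layout"))
  spans <- lapply(seq_len(nrow(layout)), function(i) {
    ch <- layout$chrom[i]
    b <- map$bins[map$bins$chrom == ch, , drop = FALSE]
    if (nrow(b) == 0L) stop("map has no bins for chromosome ", ch)
    b <- b[order(b$bin), , drop = FALSE]
    nb <- nrow(b)
    w <- b$end[1] - b$start[1]
    cen <- layout$centromere[i]
    if (cen < 0 || cen > nb * w) stop("centromere outside chromosome ", ch)
    wb <- max(1L, as.integer(round(window_mb * 1e6 / w)))
    if (wb %% 2L == 0L) wb <- wb + 1L
    hh <- (wb - 1L) %/% 2L
    cs <- cumsum(b$cM_per_Mb)
    idx <- seq_len(nb)
    lo <- pmax(1L, idx - hh)
    hi <- pmin(nb, idx + hh)
    sm <- (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
    cb <- min(nb, as.integer(floor(cen / w)) + 1L)
    l <- cb; r <- cb
    while (l > 1L && sm[l - 1L] < threshold) l <- l - 1L
    while (r < nb && sm[r + 1L] < threshold) r <- r + 1L
    data.frame(chrom = ch, start = b$start[l], end = b$end[r],
               stringsAsFactors = FALSE)
  })
  spans <- do.call(rbind, spans)
  spans$span_mb <- (spans$end - spans$start) / 1e6
  out <- classify_regions(layout, pericentric = spans,
                          subtel_frac = subtel_frac)
  attr(out, "spans") <- spans
  out
}
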