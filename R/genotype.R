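#' Filter read records on quality, uniqueness and mismatches
#'
#' Keeps reads with mapping quality strictly above `mapq_min`, uniquely
#' mapped, and with zero mismatches (perfect match). The number of records
#' failing each criterion is attached as attribute `"removed"`.
#'
#' @param reads data frame with (at least) columns `mapq` (numeric),
#'   `unique` (logical or 0/1) and `nm` (edit distance).
#' @param mapq_min quality threshold; reads must exceed it (default 30).
#' @return The kept records, with attribute `removed = c(low_quality,
#'   multi_mapped, mismatched, total)`.
#' @export
filter_reads <- function(reads, mapq_min = 30) {
  require_columns(reads, c("mapq", "unique", "nm"), "reads")
  for (col in c("mapq", "unique", "nm")) {
    bad <- which(is.na(reads[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("read record %d has missing attribute '%s'", bad[1], col))
    }
  }
  uniq <- as.logical(reads$unique)
  fail_q <- reads$mapq <= mapq_min
  fail_u <- !uniq
  fail_m <- reads$nm != 0
  keep <- !(fail_q | fail_u | fail_m)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(low_quality = sum(fail_q),
                            multi_mapped = sum(fail_u),
                            mismatched = sum(fail_m),
                            total = sum(!keep))
  out
}

#' Aggregate parent-assigned reads into matched bins
#'
#' A read mapped to parent k at position x increments matched bin
#' `floor(x / bin_width_k)` of its chromosome; the two parents' counts for a
#' matched bin pair are kept separately and summed into a total downstream.
#' Positions are 0-based; a position exactly on a bin boundary falls in the
#' right-hand bin (half-open bins).
#'
#' @param reads data frame with columns `parent` (`"P1"`/`"P2"` or 1/2),
#'   `chrom`, `pos`; an optional `sample` column splits the output by sample.
#' @param grid a [build_bin_grid()] grid.
#' @param sample sample id used when `reads` has no `sample` column.
#' @return A `bin_counts` data frame (`sample`, `chrom`, `bin`, `start`,
#'   `end`, `reads_p1`, `reads_p2`) covering every bin of the grid.
#' @export
aggregate_counts <- function(reads, grid, sample = "sample_1") {
  stopifnot(inherits(grid, "bin_grid"))
  require_columns(reads, c("parent", "chrom", "pos"), "reads")
  if (!"sample" %in% names(reads)) {
    reads$sample <- rep(sample, nrow(reads))
  }
  unk <- setdiff(unique(reads$chrom), unique(grid$chrom))
  if (length(unk) > 0L) stop("unknown chromosome: ", paste(unk, collapse = ", "))
  pk <- reads$parent
  if (is.numeric(pk)) pk <- ifelse(pk == 1, "P1", "P2")
  if (!all(pk %in% c("P1", "P2"))) stop("parent must be P1/P2 or 1/2")
  samples <- unique(reads$sample)
  if (length(samples) == 0L) samples <- sample  # empty set: all-zero track
  out <- vector("list", length(samples) * length(unique(grid$chrom)))
  k <- 0L
  for (s in samples) {
    for (ch in unique(grid$chrom)) {
      g <- grid_chrom(grid, ch)
      nb <- nrow(g)
      r1 <- integer(nb); r2 <- integer(nb)
      sel <- reads$sample == s & reads$chrom == ch
      for (parent in c("P1", "P2")) {
        pos <- reads$pos[sel & pk == parent]
        if (length(pos) > 0L) {
          idx <- bin_index_of(grid, ch, pos, parent = if (parent == "P1") 1L else 2L)
          cnt <- tabulate(idx + 1L, nbins = nb)
          if (parent == "P1") r1 <- r1 + cnt else r2 <- r2 + cnt
        }
      }
      k <- k + 1L
      out[[k]] <- data.frame(sample = s, chrom = ch, bin = g$bin,
                             start = g$start_p1, end = g$end_p1,
                             reads_p1 = r1, reads_p2 = r2,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("bin_counts", "data.frame")
  res
}

#' Raw parent-1 read-fraction track
#'
#' The per-bin ratio is the parent-1 read fraction `r = reads_p1 / total`,
#' on which the 0.9/0.1 homozygosity thresholds apply directly. Bins with
#' fewer than `min_reads` total reads are masked (ignored): their raw ratio
#' is excluded from the smoothing windows downstream.
#'
#' @param counts a `bin_counts` data frame.
#' @param min_reads bins with `total < min_reads` are masked (default 10;
#'   the comparison is strict, so a 9-read bin is masked and a 10-read bin
#'   is not).
#' @return A `ratio_track` data frame adding `total`, `ratio` (NA where
#'   `total == 0`) and `masked`.
#' @export
compute_ratio_track <- function(counts, min_reads = 10) {
  require_columns(counts, c("sample", "chrom", "bin", "reads_p1", "reads_p2"),
                  "counts")
  if (any(counts$reads_p1 < 0 | counts$reads_p2 < 0)) {
    stop("read counts must be non-negative")
  }
  out <- counts
  out$total <- out$reads_p1 + out$reads_p2
  out$ratio <- ifelse(out$total > 0, out$reads_p1 / out$total, NA_real_)
  out$masked <- out$total < min_reads
  class(out) <- c("ratio_track", "data.frame")
  out
}

#' Sliding-window mean of the ratio track
#'
#' Re-calculates each bin as the mean raw ratio of the surrounding
#' `window_bins` bins (the focal bin plus `(window_bins - 1) / 2` on each
#' side). Masked bins contribute nothing to any window; windows are
#' truncated at chromosome ends (never padded, which would bias the
#' subtelomeric calls). A bin whose whole window is masked stays masked.
#'
#' @param track a [compute_ratio_track()] track.
#' @param window_bins odd window width in bins (default 15).
#' @return The track with columns `smooth` (windowed mean ratio, NA where no
#'   window bin is available) and `smooth_n` (number of bins averaged).
#' @export
smooth_ratio <- function(track, window_bins = 15) {
  stopifnot(inherits(track, "ratio_track"))
  if (!is_count(window_bins) || window_bins < 1 || window_bins %% 2 == 0) {
    stop("window_bins must be a positive odd integer (centered window)")
  }
  h <- (window_bins - 1) / 2
  smooth_col <- rep(NA_real_, nrow(track))
  n_col <- integer(nrow(track))
  key <- paste(track$sample, track$chrom, sep = "\r")
  groups <- split(seq_len(nrow(track)), factor(key, levels = unique(key)))
  ratio_all <- track$ratio
  masked_all <- track$masked
  bin_all <- track$bin
  for (sel in groups) {
    sel <- sel[order(bin_all[sel])]
    r <- ratio_all[sel]
    use <- !masked_all[sel] & !is.na(r)
    v <- ifelse(use, r, 0)
    n <- length(sel)
    cs <- cumsum(v)
    cn <- cumsum(as.integer(use))
    i <- seq_len(n)
    lo <- pmax(1L, i - h)
    hi <- pmin(n, i + h)
    s <- cs[hi] - c(0, cs)[lo]
    m <- cn[hi] - c(0L, cn)[lo]
    smooth_col[sel] <- ifelse(m > 0L, s / m, NA_real_)
    n_col[sel] <- m
  }
  track$smooth <- smooth_col
  track$smooth_n <- n_col
  track
}

#' Call per-bin genotypes from the smoothed ratio
#'
#' A bin is homozygous parent-1 if its smoothed ratio is strictly above
#' `hi`, homozygous parent-2 if strictly below `lo`, otherwise heterozygous;
#' a ratio of exactly 0.9 is heterozygous. Bins without a smoothed value are
#' `MISSING`.
#'
#' @param track a [smooth_ratio()] track.
#' @param hi,lo homozygosity thresholds (defaults 0.9 and 0.1; must satisfy
#'   `lo < hi`).
#' @return A `genotype_tracks` data frame with a `call` column in
#'   `HOM_P1`/`HET`/`HOM_P2`/`MISSING`.
#' @export
call_genotypes <- function(track, hi = 0.9, lo = 0.1) {
  if (lo >= hi) stop("lo must be strictly below hi")
  if (!"smooth" %in% names(track)) {
    stop("track has no smoothed ratio; run smooth_ratio() first")
  }
  s <- track$smooth
  call <- ifelse(is.na(s), "MISSING",
                 ifelse(s > hi, "HOM_P1", ifelse(s < lo, "HOM_P2", "HET")))
  track$call <- call
  class(track) <- c("genotype_tracks", "data.frame")
  track
}

#' Bin counts to genotype calls in one step
#'
#' Convenience wrapper: raw ratio (with the `< min_reads` mask), sliding
#' window smoothing, threshold genotype calls, and an optional hard bin mask
#' (e.g. parental-consistency, see [mask_parent_inconsistent_bins()]).
#' Hard-masked bins contribute nothing to smoothing windows and are always
#' called `MISSING`.
#'
#' @inheritParams compute_ratio_track
#' @inheritParams smooth_ratio
#' @inheritParams call_genotypes
#' @param bin_mask optional `bin_mask` data frame (`chrom`, `bin`, `masked`).
#' @return A `genotype_tracks` data frame.
#' @export
genotype_bins <- function(counts, min_reads = 10, window_bins = 15,
                          hi = 0.9, lo = 0.1, bin_mask = NULL) {
  track <- compute_ratio_track(counts, min_reads = min_reads)
  hard <- rep(FALSE, nrow(track))
  if (!is.null(bin_mask)) {
    require_columns(bin_mask, c("chrom", "bin", "masked"), "bin_mask")
    bm <- bin_mask[bin_mask$masked, , drop = FALSE]
    hard <- paste(track$chrom, track$bin) %in% paste(bm$chrom, bm$bin)
    track$masked <- track$masked | hard
  }
  track <- smooth_ratio(track, window_bins = window_bins)
  track <- call_genotypes(track, hi = hi, lo = lo)
  if (any(hard)) track$call[hard] <- "MISSING"
  track
}

#' Mask bins inconsistent with the parental genotypes
#'
#' Given genotype tracks of the two pure parental libraries run through the
#' same binning, a bin is masked if the parent-1 library is not called
#' `HOM_P1` or the parent-2 library is not called `HOM_P2`. The mask is
#' applied to all progeny tracks (via `bin_mask` of [genotype_bins()]).
#' Parental tracks are best called without smoothing (`window_bins = 1`):
#' window averaging would dilute exactly the isolated aberrant bins this
#' screen exists to find.
#'
#' @param p1_track,p2_track `genotype_tracks` of the parent-1 and parent-2
#'   libraries on the same grid.
#' @return A `bin_mask` data frame (`chrom`, `bin`, `masked`) with attribute
#'   `"fraction"`, the masked fraction of bins.
#' @export
mask_parent_inconsistent_bins <- function(p1_track, p2_track) {
  for (tr in list(p1_track, p2_track)) {
    if (!"call" %in% names(tr)) stop("parent tracks must carry genotype calls")
  }
  o1 <- order(p1_track$chrom, p1_track$bin)
  o2 <- order(p2_track$chrom, p2_track$bin)
  p1 <- p1_track[o1, , drop = FALSE]
  p2 <- p2_track[o2, , drop = FALSE]
  if (nrow(p1) != nrow(p2) || any(p1$chrom != p2$chrom) || any(p1$bin != p2$bin)) {
    stop("parent tracks are on mismatched grids")
  }
  masked <- p1$call != "HOM_P1" | p2$call != "HOM_P2"
  out <- data.frame(chrom = p1$chrom, bin = p1$bin, masked = masked,
                    stringsAsFactors = FALSE)
  attr(out, "fraction") <- mean(masked)
  class(out) <- c("bin_mask", "data.frame")
  out
}
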