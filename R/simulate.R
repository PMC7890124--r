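#' GBS coverage model
#'
#' Mean read depth per ~1 Mb bin by region class, the per-read parental
#' misassignment probability, and an optional per-bin "artifact" probability.
#' The depth defaults are the regimes observed in a wheat F2 GBS experiment:
#' 62.9 reads per bin on the arms, 38.8 in the pericentric region, 102.7 and
#' 73.9 in the left and right subtelomeric regions.
#'
#' Artifact bins model positions where read assignment to a parent is
#' unreliable (e.g. collapsed or highly similar regions of the two
#' assemblies): in such bins reads are assigned to either parent with
#' probability 1/2 regardless of the true genotype. They are a property of
#' the bin grid, shared by all samples including the parental libraries, so
#' parental-consistency masking can detect and remove them; the default rate
#' of 0.025 mirrors the 2-3% of bins such screens typically remove.
#'
#' @param mean_arm,mean_pericentric,mean_subtel_left,mean_subtel_right mean
#'   total reads per bin by region class.
#' @param epsilon per-read misassignment probability (0 <= epsilon < 0.5).
#' @param p_artifact per-bin probability of an unreliable (artifact) bin.
#' @return A `coverage_model` list.
#' @export
coverage_model <- function(mean_arm = 62.9, mean_pericentric = 38.8,
                           mean_subtel_left = 102.7, mean_subtel_right = 73.9,
                           epsilon = 0.01, p_artifact = 0.025) {
  means <- c(arm = mean_arm, pericentric = mean_pericentric,
             subtel_left = mean_subtel_left, subtel_right = mean_subtel_right)
  if (any(means <= 0)) stop("per-bin mean read counts must be positive")
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must be in [0, 0.5)")
  if (p_artifact < 0 || p_artifact >= 1) stop("p_artifact must be in [0, 1)")
  structure(list(means = means, epsilon = epsilon, p_artifact = p_artifact),
            class = "coverage_model")
}

#' Draw artifact bins for a grid
#'
#' Marks each bin of the grid as an artifact bin with probability
#' `p_artifact` (see [coverage_model()]). Artifact status is positional: the
#' same bins behave aberrantly in every sample simulated against this grid.
#'
#' @param grid a [build_bin_grid()] grid.
#' @param p_artifact per-bin artifact probability.
#' @param seed optional integer seed.
#' @return Data frame `chrom`, `bin`, `artifact` (logical).
#' @export
draw_artifact_bins <- function(grid, p_artifact, seed = NULL) {
  stopifnot(inherits(grid, "bin_grid"))
  if (!is.null(seed)) set.seed(seed)
  data.frame(chrom = grid$chrom, bin = grid$bin,
             artifact = stats::runif(nrow(grid)) < p_artifact,
             stringsAsFactors = FALSE)
}

#' Simulate one gamete's crossovers
#'
#' The number of crossovers is Poisson with mean `total cM / 100`; positions
#' are drawn independently from the landscape density (no crossover
#' interference); the starting parental origin is uniform. Wheat chromosomes
#' carry on the order of one to three crossovers each.
#'
#' @param landscape a [recomb_landscape()]; if it covers several chromosomes,
#'   `chrom` selects one.
#' @param chrom chromosome to simulate (default: the only one present).
#' @return A `gamete_truth` list: `chrom`, `length`, `crossovers` (strictly
#'   increasing bp positions), `start_parent` (1 or 2: parental origin of the
#'   leftmost segment).
#' @export
simulate_gamete <- function(landscape, chrom = NULL) {
  stopifnot(inherits(landscape, "recomb_landscape"))
  if (is.null(chrom)) {
    chrom <- unique(landscape$chrom)
    if (length(chrom) != 1L) stop("landscape covers several chromosomes; give `chrom`")
  }
  seg <- landscape[landscape$chrom == chrom, , drop = FALSE]
  if (nrow(seg) == 0L) stop("unknown chromosome: ", chrom)
  L <- max(seg$end)
  if (L <= 0) stop("zero-length chromosome: ", chrom)
  w_cm <- seg$cM_per_Mb * (seg$end - seg$start) / 1e6
  tot <- sum(w_cm)
  n <- stats::rpois(1L, tot / 100)
  pos <- numeric(0)
  if (n > 0L) {
    idx <- sample.int(nrow(seg), n, replace = TRUE, prob = w_cm)
    pos <- sort(stats::runif(n, seg$start[idx], seg$end[idx]))
  }
  structure(list(chrom = chrom, length = L, crossovers = pos,
                 start_parent = sample(1:2, 1L)),
            class = "gamete_truth")
}

# parental origin (1 or 2) of a gamete at positions
gamete_origin <- function(gamete, pos) {
  k <- findInterval(pos, gamete$crossovers)
  ((gamete$start_parent - 1L + k) %% 2L) + 1L
}

# piecewise-constant parent-1 dosage track of two gametes on one chromosome
dosage_segments <- function(g1, g2, L) {
  bk <- sort(unique(c(g1$crossovers, g2$crossovers)))
  start <- c(0, bk)
  end <- c(bk, L)
  mid <- (start + end) / 2
  d <- (gamete_origin(g1, mid) == 1L) + (gamete_origin(g2, mid) == 1L)
  keep <- c(TRUE, diff(d) != 0)
  idx <- which(keep)
  data.frame(start = start[idx], end = c(start[idx][-1], L), dosage = d[idx])
}

#' Simulate an F2 population with known crossover truth
#'
#' Each F2 individual is formed from two independently simulated gametes per
#' chromosome (selfed F1), so a population of n individuals carries 2n
#' gametes. The true parent-1 allele dosage (0/1/2) along each chromosome is
#' derived from the two gametes and recorded together with every true
#' crossover position.
#'
#' @param n number of individuals (>= 1).
#' @param landscape a [recomb_landscape()] covering all chromosomes.
#' @param seed optional integer seed.
#' @param sample_prefix prefix for sample ids.
#' @return An `f2_population` list: `n`, `chroms` (data frame `chrom`,
#'   `length`), `individuals` (per sample, per chromosome: the two
#'   `gamete_truth` objects and the dosage segment table) and `truth`
#'   (data frame `sample`, `chrom`, `pos`, `gamete` of all true crossovers).
#' @export
simulate_f2_population <- function(n, landscape, seed = NULL,
                                   sample_prefix = "F2_") {
  if (!is_count(n) || n < 1) stop("n must be a positive integer")
  stopifnot(inherits(landscape, "recomb_landscape"))
  if (!is.null(seed)) set.seed(seed)
  chroms <- unique(landscape$chrom)
  lens <- vapply(chroms, function(ch) chrom_length_of(landscape, ch), 0)
  ids <- sprintf("%s%03d", sample_prefix, seq_len(n))
  truth <- vector("list", n * length(chroms))
  individuals <- vector("list", n)
  names(individuals) <- ids
  k <- 0L
  for (i in seq_len(n)) {
    per_chrom <- vector("list", length(chroms))
    names(per_chrom) <- chroms
    for (j in seq_along(chroms)) {
      ch <- chroms[j]
      g1 <- simulate_gamete(landscape, ch)
      g2 <- simulate_gamete(landscape, ch)
      per_chrom[[j]] <- list(g1 = g1, g2 = g2,
                             dosage = dosage_segments(g1, g2, lens[j]))
      ncx <- length(g1$crossovers) + length(g2$crossovers)
      if (ncx > 0L) {
        k <- k + 1L
        truth[[k]] <- data.frame(
          sample = ids[i], chrom = ch,
          pos = c(g1$crossovers, g2$crossovers),
          gamete = rep(1:2, c(length(g1$crossovers), length(g2$crossovers))),
          stringsAsFactors = FALSE)
      }
    }
    individuals[[i]] <- list(sample = ids[i], chroms = per_chrom)
  }
  truth <- if (k > 0L) do.call(rbind, truth[seq_len(k)]) else
    data.frame(sample = character(0), chrom = character(0),
               pos = numeric(0), gamete = integer(0))
  truth <- truth[order(truth$sample, truth$chrom, truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  structure(list(n = n,
                 chroms = data.frame(chrom = chroms, length = unname(lens),
                                     stringsAsFactors = FALSE),
                 individuals = individuals, truth = truth),
            class = "f2_population")
}

# majority-length dosage per bin for one chromosome of one individual;
# a crossover inside a bin assigns the bin its majority-length dosage
majority_dosage <- function(dos, nbins, width) {
  acc <- matrix(0, nrow = 3L, ncol = nbins)
  for (r in seq_len(nrow(dos))) {
    s <- dos$start[r]; e <- dos$end[r]
    i0 <- max(0L, min(nbins - 1L, as.integer(floor(s / width))))
    i1 <- max(0L, min(nbins - 1L, as.integer(ceiling(e / width)) - 1L))
    bins <- i0:i1
    ov <- pmin(e, (bins + 1) * width) - pmax(s, bins * width)
    row <- dos$dosage[r] + 1L
    acc[row, bins + 1L] <- acc[row, bins + 1L] + ov
  }
  max.col(t(acc), ties.method = "first") - 1L
}

#' Simulate per-bin parent-specific GBS read counts
#'
#' For every bin, the total read count is Poisson with the region-class mean
#' of the coverage model, and each read is assigned to parent 1 with
#' probability `p = d/2 * (1 - eps) + (1 - d/2) * eps`, where `d` is the
#' bin's true (majority) parent-1 dosage and `eps` the per-read
#' misassignment rate. In artifact bins (see [draw_artifact_bins()])
#' `p = 1/2` regardless of genotype.
#'
#' @param pop an [simulate_f2_population()] population.
#' @param grid a [build_bin_grid()] grid covering the population's
#'   chromosomes.
#' @param model a [coverage_model()].
#' @param regions a [classify_regions()] classification (sets each bin's
#'   region class, hence its mean depth).
#' @param seed optional integer seed.
#' @param artifact_bins optional data frame from [draw_artifact_bins()].
#' @return A `bin_counts` data frame: `sample`, `chrom`, `bin`, `start`,
#'   `end` (parent-1 coordinates), `reads_p1`, `reads_p2`.
#' @export
simulate_bin_counts <- function(pop, grid, model = coverage_model(),
                                regions, seed = NULL, artifact_bins = NULL) {
  stopifnot(inherits(pop, "f2_population"), inherits(grid, "bin_grid"),
            inherits(model, "coverage_model"))
  missing_ch <- setdiff(pop$chroms$chrom, unique(grid$chrom))
  if (length(missing_ch) > 0L) {
    stop("bin grid does not cover chromosome(s): ",
         paste(missing_ch, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  chroms <- pop$chroms$chrom
  prep <- lapply(chroms, function(ch) {
    g <- grid_chrom(grid, ch)
    cls <- region_class_at(regions, ch, (g$start_p1 + g$end_p1) / 2)
    mu <- unname(model$means[cls])
    art <- rep(FALSE, nrow(g))
    if (!is.null(artifact_bins)) {
      ab <- artifact_bins[artifact_bins$chrom == ch, , drop = FALSE]
      art[match(ab$bin[ab$artifact], g$bin)] <- TRUE
    }
    list(g = g, mu = mu, art = art, width = g$end_p1[1] - g$start_p1[1])
  })
  names(prep) <- chroms
  eps <- model$epsilon
  nb_tot <- sum(vapply(prep, function(pc) nrow(pc$g), 0L))
  N <- pop$n * nb_tot
  col_sample <- character(N); col_chrom <- character(N)
  col_bin <- integer(N); col_start <- numeric(N); col_end <- numeric(N)
  col_r1 <- integer(N); col_r2 <- integer(N)
  at <- 0L
  for (ind in pop$individuals) {
    for (ch in chroms) {
      pc <- prep[[ch]]
      nb <- nrow(pc$g)
      d <- majority_dosage(ind$chroms[[ch]]$dosage, nb, pc$width)
      p <- d / 2 * (1 - eps) + (1 - d / 2) * eps
      p[pc$art] <- 0.5
      tot <- stats::rpois(nb, pc$mu)
      r1 <- stats::rbinom(nb, tot, p)
      idx <- at + seq_len(nb)
      col_sample[idx] <- ind$sample; col_chrom[idx] <- ch
      col_bin[idx] <- pc$g$bin
      col_start[idx] <- pc$g$start_p1; col_end[idx] <- pc$g$end_p1
      col_r1[idx] <- r1; col_r2[idx] <- tot - r1
      at <- at + nb
    }
  }
  res <- data.frame(sample = col_sample, chrom = col_chrom, bin = col_bin,
                    start = col_start, end = col_end, reads_p1 = col_r1,
                    reads_p2 = col_r2, stringsAsFactors = FALSE)
  class(res) <- c("bin_counts", "data.frame")
  res
}

#' Simulate a pure parental GBS library
#'
#' A parental library is homozygous everywhere (dosage 2 for parent 1,
#' dosage 0 for parent 2); reads are drawn under the same coverage model as
#' progeny, including misassignment and artifact bins. Used to derive the
#' parental-consistency bin mask.
#'
#' @inheritParams simulate_bin_counts
#' @param parent 1 or 2.
#' @param sample sample id of the library.
#' @return A `bin_counts` data frame (one sample).
#' @export
simulate_parent_counts <- function(grid, model = coverage_model(), regions,
                                   parent = 1L, seed = NULL,
                                   artifact_bins = NULL,
                                   sample = paste0("parent_", parent)) {
  stopifnot(inherits(grid, "bin_grid"), parent %in% 1:2)
  if (!is.null(seed)) set.seed(seed)
  eps <- model$epsilon
  d <- if (parent == 1L) 2 else 0
  out <- lapply(unique(grid$chrom), function(ch) {
    g <- grid_chrom(grid, ch)
    cls <- region_class_at(regions, ch, (g$start_p1 + g$end_p1) / 2)
    mu <- unname(model$means[cls])
    p <- rep(d / 2 * (1 - eps) + (1 - d / 2) * eps, nrow(g))
    if (!is.null(artifact_bins)) {
      ab <- artifact_bins[artifact_bins$chrom == ch, , drop = FALSE]
      p[match(ab$bin[ab$artifact], g$bin)] <- 0.5
    }
    tot <- stats::rpois(nrow(g), mu)
    r1 <- stats::rbinom(nrow(g), tot, p)
    data.frame(sample = sample, chrom = ch, bin = g$bin,
               start = g$start_p1, end = g$end_p1,
               reads_p1 = r1, reads_p2 = tot - r1, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("bin_counts", "data.frame")
  res
}

#' Read true genotypes at marker positions
#'
#' Codominant, error-free marker genotyping of a simulated population: the
#' dosage at each marker position is read off the individual's true dosage
#' track.
#'
#' @param pop an [simulate_f2_population()] population.
#' @param markers data frame with columns `marker_id`, `chrom`, `pos` (bp).
#' @return Data frame `sample`, `marker_id`, `chrom`, `pos`, `dosage`
#'   (0/1/2), `call` (`P2`/`HET`/`P1`).
#' @export
simulate_marker_genotypes <- function(pop, markers) {
  stopifnot(inherits(pop, "f2_population"))
  require_columns(markers, c("marker_id", "chrom", "pos"), "markers")
  bad <- !(markers$chrom %in% pop$chroms$chrom)
  if (any(bad)) stop("marker chromosome not in population: ",
                     paste(unique(markers$chrom[bad]), collapse = ", "))
  lens <- pop$chroms$length[match(markers$chrom, pop$chroms$chrom)]
  if (any(markers$pos < 0 | markers$pos >= lens)) {
    stop("marker position out of chromosome range")
  }
  out <- lapply(pop$individuals, function(ind) {
    dos <- vapply(seq_len(nrow(markers)), function(j) {
      seg <- ind$chroms[[markers$chrom[j]]]$dosage
      seg$dosage[findInterval(markers$pos[j], seg$start)]
    }, 0)
    data.frame(sample = ind$sample, marker_id = markers$marker_id,
               chrom = markers$chrom, pos = markers$pos, dosage = dos,
               call = c("P2", "HET", "P1")[dos + 1L], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' True crossovers as gamete-level events
#'
#' @param pop an [simulate_f2_population()] population.
#' @return BED-like data frame of all true crossovers (`chrom`, `start`,
#'   `end`, `sample`, `gamete`), each spanning the single true position.
#' @export
true_co_events <- function(pop) {
  stopifnot(inherits(pop, "f2_population"))
  data.frame(chrom = pop$truth$chrom, start = pop$truth$pos,
             end = pop$truth$pos, sample = pop$truth$sample,
             gamete = pop$truth$gamete, stringsAsFactors = FALSE)
}

#' True dosage-level crossover events
#'
#' Converts each individual's true dosage track into the event representation
#' used by the calling pipeline: one event per dosage breakpoint with
#' `gametes` equal to the absolute dosage change. Crossover pairs that cancel
#' at the dosage level (e.g. the two gametes crossing in opposite directions
#' at nearly the same position) produce no breakpoint and are therefore
#' excluded -- they are undetectable by any dosage-based caller and must not
#' enter recall denominators.
#'
#' @param pop an [simulate_f2_population()] population.
#' @return A `co_events` data frame (see [call_crossovers()]) with zero-width
#'   intervals at the true breakpoints and status `"kept"`.
#' @export
true_dosage_events <- function(pop) {
  stopifnot(inherits(pop, "f2_population"))
  out <- list(); k <- 0L
  lab <- c("HOM_P2", "HET", "HOM_P1")
  for (ind in pop$individuals) {
    for (ch in names(ind$chroms)) {
      seg <- ind$chroms[[ch]]$dosage
      if (nrow(seg) < 2L) next
      i <- seq_len(nrow(seg) - 1L)
      k <- k + 1L
      out[[k]] <- data.frame(
        sample = ind$sample, chrom = ch,
        start = seg$end[i], end = seg$end[i], mid = seg$end[i],
        left = lab[seg$dosage[i] + 1L], right = lab[seg$dosage[i + 1L] + 1L],
        gametes = abs(diff(seg$dosage)), region = NA_character_,
        status = "kept", stringsAsFactors = FALSE)
    }
  }
  res <- if (k > 0L) do.call(rbind, out) else empty_co_events()
  rownames(res) <- NULL
  class(res) <- c("co_events", "data.frame")
  res
}
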