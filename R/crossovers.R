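empty_co_events <- function() {
  data.frame(sample = character(0), chrom = character(0), start = numeric(0),
             end = numeric(0), mid = numeric(0), left = character(0),
             right = character(0), gametes = integer(0),
             region = character(0), status = character(0),
             stringsAsFactors = FALSE)
}

# least-squares refinement of a junction between two genotype runs: choose the
# bin boundary (cut index) around the called transition that best splits the
# raw ratios into the left and right expected values. Ties go to the cut
# closest to the unrefined junction, then leftmost.
# `ratio`/`usable` are per-bin vectors of the whole chromosome (bin b at
# index b + 1); cuts and run bounds are 0-based bin indices. A cut c puts
# bins < c on the left side and bins >= c on the right side; valid cuts keep
# at least one bin of each run on its own side. `left_bin`/`right_bin` are
# the last/first non-missing bins of the two runs around the called
# junction; with a missing gap between them the candidate range spans it.
refine_junction <- function(ratio, usable, run_lo, run_hi, left_bin,
                            right_bin, left, right, h) {
  cut0 <- right_bin
  eL <- call_expected_ratio[[left]]
  eR <- call_expected_ratio[[right]]
  cmin <- max(run_lo + 1L, left_bin + 1L - h)
  cmax <- min(run_hi, right_bin + h)
  if (cmax <= cmin) return(cut0)
  bins <- cmin:(cmax - 1L)  # the bins whose side depends on the cut
  r <- ratio[bins + 1L]
  u <- usable[bins + 1L] & !is.na(r)
  dl <- ifelse(u, (r - eL)^2, 0)
  dr <- ifelse(u, (r - eR)^2, 0)
  cdl <- c(0, cumsum(dl))
  cdr <- c(0, cumsum(dr))
  cuts <- cmin:cmax
  t <- cuts - cmin + 1L
  score <- cdl[t] + (sum(dr) - cdr[t])
  cand <- cuts[score <= min(score) + 1e-12]
  cand[order(abs(cand - cut0), cand)][1]
}

#' Call crossovers from genotype tracks
#'
#' One crossover event is emitted per adjacent change between non-missing
#' bin genotypes; `MISSING` bins are skipped, i.e. the genotype is carried
#' across them and the event's bounding interval spans the gap. The event's
#' recombinant-gamete count is the absolute dosage difference between the
#' flanking genotypes (`HOM_P1` = 2, `HET` = 1, `HOM_P2` = 0), so a
#' `HOM_P1` to `HOM_P2` change counts two recombinant gametes.
#'
#' The junction position is refined against the raw (unsmoothed) ratios:
#' window smoothing displaces the threshold crossing several bins toward the
#' homozygous side, so the cut within the two flanking runs that best fits
#' the raw data (least squares against the expected ratios) is used. The
#' bounding interval is the two bins flanking the refined junction (plus any
#' skipped missing gap), and contains the true crossover up to the grid's
#' bin resolution.
#'
#' @param tracks a `genotype_tracks` data frame (see [genotype_bins()]).
#' @param grid the [build_bin_grid()] grid the tracks were computed on.
#' @param regions optional [classify_regions()] classification; sets each
#'   event's region class at its midpoint.
#' @param refine refine junction positions against raw ratios (default TRUE).
#' @param max_gap_bp events bridging more than this much missing data are
#'   flagged `low_conf` instead of `kept` (default 100 Mb).
#' @return A `co_events` data frame: `sample`, `chrom`, `start`, `end`,
#'   `mid`, `left`, `right`, `gametes`, `region`, `status`.
#' @export
call_crossovers <- function(tracks, grid, regions = NULL, refine = TRUE,
                            max_gap_bp = 1e8) {
  stopifnot(inherits(grid, "bin_grid"))
  require_columns(tracks, c("sample", "chrom", "bin", "call"), "tracks")
  h <- 7L
  if ("smooth_n" %in% names(tracks)) {
    # use the smoothing half-window if recoverable (smooth_n <= window)
    h <- max(1L, as.integer((max(tracks$smooth_n) - 1) / 2))
  }
  key <- paste(tracks$sample, tracks$chrom, sep = "\r")
  groups <- split(seq_len(nrow(tracks)), factor(key, levels = unique(key)))
  widths <- vapply(unique(tracks$chrom), function(ch) bin_width(grid, ch),
                   0)
  e_sample <- list(); e_chrom <- list(); e_start <- list(); e_end <- list()
  e_left <- list(); e_right <- list(); e_status <- list()
  k <- 0L
  for (sel in groups) {
    sel <- sel[order(tracks$bin[sel])]
    calls <- tracks$call[sel]
    smp <- tracks$sample[sel[1]]
    ch <- tracks$chrom[sel[1]]
    w <- widths[[ch]]
    nm <- which(calls != "MISSING")
    if (length(nm) == 0L) {
      warning("all bins missing for sample ", smp, " on ", ch)
      next
    }
    if (length(nm) < 2L) next
    r <- rle(calls[nm])
    if (length(r$values) < 2L) next
    cum <- cumsum(r$lengths)
    ratio <- tracks$ratio[sel]
    usable <- !tracks$masked[sel] & !is.na(ratio)
    nj <- length(r$values) - 1L
    start_v <- numeric(nj); end_v <- numeric(nj); status_v <- character(nj)
    nm0 <- nm - 1L  # 0-based non-missing bins
    for (j in seq_len(nj)) {
      left_bin <- nm[cum[j]] - 1L          # 0-based bin indices
      right_bin <- nm[cum[j] + 1L] - 1L
      left <- r$values[j]
      right <- r$values[j + 1L]
      lb <- left_bin; rb <- right_bin
      if (refine) {
        run_lo <- nm[if (j == 1L) 1L else cum[j - 1L] + 1L] - 1L
        run_hi <- nm[cum[j + 1L]] - 1L
        cut <- refine_junction(ratio, usable, run_lo, run_hi, left_bin,
                               right_bin, left, right, h)
        # bound the event by the nearest non-missing bins around the cut
        lb <- max(nm0[nm0 <= cut - 1L])
        rb <- min(nm0[nm0 >= cut])
      }
      start_v[j] <- lb * w
      end_v[j] <- (rb + 1L) * w
      gap_bp <- max(0L, rb - lb - 1L) * w
      status_v[j] <- if (gap_bp > max_gap_bp) "low_conf" else "kept"
    }
    k <- k + 1L
    e_sample[[k]] <- rep(smp, nj); e_chrom[[k]] <- rep(ch, nj)
    e_start[[k]] <- start_v; e_end[[k]] <- end_v
    e_left[[k]] <- r$values[-length(r$values)]; e_right[[k]] <- r$values[-1]
    e_status[[k]] <- status_v
  }
  if (k == 0L) {
    res <- empty_co_events()
  } else {
    left <- unlist(e_left); right <- unlist(e_right)
    start <- unlist(e_start); end <- unlist(e_end)
    res <- data.frame(
      sample = unlist(e_sample), chrom = unlist(e_chrom), start = start,
      end = end, mid = (start + end) / 2, left = left, right = right,
      gametes = unname(abs(call_dosage[left] - call_dosage[right])),
      region = NA_character_, status = unlist(e_status),
      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  if (!is.null(regions) && nrow(res) > 0L) {
    res$region <- region_class_at(regions, res$chrom, res$mid)
  }
  class(res) <- c("co_events", "data.frame")
  res
}

#' Region-aware double-crossover filter
#'
#' Close double crossovers are implausible (genotyping noise or gene
#' conversion) and are removed: for each pair of consecutive events bounding
#' a genotype segment, if their midpoint separation is below the threshold
#' of the segment's region class (8 Mb subtelomeric/arm, 70 Mb pericentric),
#' both events are dropped and the short segment reverts to the flanking
#' genotype. The scan repeats until no pair qualifies (fixed point), always
#' removing the shortest qualifying segment first (ties leftmost). In the
#' triple-change edge case where the two flanks differ, the pair is replaced
#' by a single merged event spanning both.
#'
#' @param events a `co_events` data frame from [call_crossovers()].
#' @param regions a [classify_regions()] classification; the class of the
#'   segment between two events (at its midpoint) picks the threshold.
#' @param d_subtel minimum separation outside pericentric regions (default
#'   8e6).
#' @param d_pericen minimum separation in pericentric regions (default 7e7).
#' @return The events with removed pairs re-labelled `status =
#'   "removed_dco"`, plus any merged events; idempotent.
#' @export
filter_double_crossovers <- function(events, regions, d_subtel = 8e6,
                                     d_pericen = 7e7) {
  stopifnot(inherits(events, "data.frame"))
  if (nrow(events) == 0L) return(events)
  key <- paste(events$sample, events$chrom, sep = "\r")
  removed <- list(); kept <- list(); k_r <- 0L; k_k <- 0L
  for (kk in unique(key)) {
    ev <- events[key == kk, , drop = FALSE]
    ev <- ev[order(ev$mid), , drop = FALSE]
    act <- ev[ev$status != "removed_dco", , drop = FALSE]
    pre_removed <- ev[ev$status == "removed_dco", , drop = FALSE]
    repeat {
      n <- nrow(act)
      if (n < 2L) break
      sep <- diff(act$mid)
      seg_mid <- (act$mid[-n] + act$mid[-1]) / 2
      cls <- region_class_at(regions, act$chrom[1], seg_mid)
      thr <- ifelse(cls == "pericentric", d_pericen, d_subtel)
      cand <- which(sep < thr)
      if (length(cand) == 0L) break
      i <- cand[which.min(sep[cand])]  # shortest first, ties leftmost
      pair <- act[c(i, i + 1L), , drop = FALSE]
      pair$status <- "removed_dco"
      k_r <- k_r + 1L
      removed[[k_r]] <- pair
      merged <- NULL
      if (act$left[i] != act$right[i + 1L]) {
        merged <- act[i, , drop = FALSE]
        merged$end <- act$end[i + 1L]
        merged$mid <- (merged$start + merged$end) / 2
        merged$right <- act$right[i + 1L]
        merged$gametes <- abs(call_dosage[[merged$left]] -
                              call_dosage[[merged$right]])
        merged$region <- region_class_at(regions, merged$chrom, merged$mid)
        merged$status <- "kept"
      }
      act <- act[-c(i, i + 1L), , drop = FALSE]
      if (!is.null(merged)) {
        act <- rbind(act, merged)
        act <- act[order(act$mid), , drop = FALSE]
      }
    }
    k_k <- k_k + 1L
    kept[[k_k]] <- rbind(act, pre_removed)
  }
  res <- do.call(rbind, c(kept, removed))
  res <- res[order(res$sample, res$chrom, res$mid), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("co_events", "data.frame")
  res
}

#' Per-sample, per-chromosome crossover counts
#'
#' Sums the recombinant-gamete weights of the surviving events (status other
#' than `removed_dco`); the unweighted event count is reported alongside.
#'
#' @param events a `co_events` data frame.
#' @param samples,chroms optional vectors to include zero rows for
#'   samples/chromosomes without events.
#' @return Data frame `sample`, `chrom`, `co_gametes`, `n_events`.
#' @export
count_crossovers <- function(events, samples = NULL, chroms = NULL) {
  keep <- events$status != "removed_dco"
  ev <- events[keep, , drop = FALSE]
  samples <- samples %||% unique(events$sample)
  chroms <- chroms %||% unique(events$chrom)
  out <- expand.grid(sample = samples, chrom = chroms,
                     stringsAsFactors = FALSE)
  out <- out[order(out$sample, out$chrom), , drop = FALSE]
  key <- paste(ev$sample, ev$chrom, sep = "\r")
  okey <- paste(out$sample, out$chrom, sep = "\r")
  g <- tapply(ev$gametes, key, sum)
  ne <- tapply(rep(1L, nrow(ev)), key, sum)
  out$co_gametes <- as.numeric(ifelse(is.na(g[okey]), 0, g[okey]))
  out$n_events <- as.integer(ifelse(is.na(ne[okey]), 0L, ne[okey]))
  rownames(out) <- NULL
  out
}
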