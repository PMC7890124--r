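#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("Genome layout: %d chromosome(s), parents %s\n", nrow(x),
              paste(attr(x, "parents"), collapse = " x ")))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
print.f2_population <- function(x, ...) {
  cat(sprintf("F2 population: %d individuals (%d gametes), %d chromosome(s)\n",
              x$n, 2 * x$n, nrow(x$chroms)))
  cat(sprintf("true crossovers: %d (%.2f per gamete per chromosome)\n",
              nrow(x$truth),
              nrow(x$truth) / (2 * x$n * nrow(x$chroms))))
  invisible(x)
}

#' @export
print.coverage_model <- function(x, ...) {
  cat("GBS coverage model (mean reads/bin):\n")
  print(x$means)
  cat(sprintf("per-read misassignment epsilon = %g; per-bin artifact rate = %g\n",
              x$epsilon, x$p_artifact))
  invisible(x)
}

#' @export
print.population_map <- function(x, ...) {
  cat(sprintf("Population map '%s': n = %d individuals (%d gametes)\n",
              x$label, x$n, x$gametes))
  tot <- tapply(x$bins$cM, x$bins$chrom, sum)
  for (ch in names(tot)) {
    cat(sprintf("  %s: %.1f cM over %d bins\n", ch, tot[[ch]],
                sum(x$bins$chrom == ch)))
  }
  invisible(x)
}

#' @export
summary.population_map <- function(object, ...) {
  b <- object$bins
  out <- do.call(rbind, lapply(unique(b$chrom), function(ch) {
    bb <- b[b$chrom == ch, ]
    data.frame(chrom = ch, bins = nrow(bb), co_gametes = sum(bb$co_gametes),
               cM = sum(bb$cM), mean_cM_per_Mb = sum(bb$cM) / sum(bb$width_mb),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Plot a recombination landscape profile
#'
#' Per-chromosome cM/Mb against physical position (Mb), one panel per
#' chromosome.
#'
#' @param x a `population_map`.
#' @param chroms chromosomes to plot (default: all).
#' @param ... passed to [graphics::plot()].
#' @export
plot.population_map <- function(x, chroms = NULL, ...) {
  b <- x$bins
  chroms <- chroms %||% unique(b$chrom)
  old <- graphics::par(mfrow = c(min(length(chroms), 4), 1),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (ch in chroms) {
    bb <- b[b$chrom == ch, ]
    graphics::plot((bb$start + bb$end) / 2e6, bb$cM_per_Mb, type = "h",
                   xlab = "position (Mb)", ylab = "cM/Mb",
                   main = paste(x$label, ch), ...)
  }
  invisible(x)
}

#' @export
print.co_events <- function(x, ...) {
  kept <- sum(x$status != "removed_dco")
  cat(sprintf("Crossover events: %d kept (%d low-confidence), %d removed by double-CO filter\n",
              kept, sum(x$status == "low_conf"),
              sum(x$status == "removed_dco")))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s vs %s\n", x$test, x$populations[1], x$populations[2]))
  where <- paste(vapply(x$where, function(v) paste(format(v), collapse = "-"),
                        ""), collapse = " ")
  cat("  where:", where, "\n")
  cat(sprintf("  statistic = %s, p = %.4g, percent change = %s\n",
              format(x$statistic), x$p_value,
              if (is.na(x$percent_change)) "NA" else
                sprintf("%+.1f%%", x$percent_change)))
  invisible(x)
}

#' @export
print.marker_interval <- function(x, ...) {
  cat(sprintf("Interval %s - %s: %.2f cM (%d recombinant gametes, n = %d used, %d excluded)\n",
              x$markers[1], x$markers[2], x$cM, x$recombinant_gametes,
              x$n_used, x$n_excluded))
  invisible(x)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run config: %d population(s) [%s], n = %d, seed = %d\n",
              length(x$landscapes),
              paste(names(x$landscapes), collapse = ", "), x$n, x$seed))
  cat(sprintf("  bins %.0f bp, window %d, thresholds %.2f/%.2f, min reads %d\n",
              x$bin_bp, x$window_bins, x$hi, x$lo, x$min_reads))
  cat(sprintf("  double-CO filter: %.0f Mb subtelomeric, %.0f Mb pericentric\n",
              x$d_subtel / 1e6, x$d_pericen / 1e6))
  invisible(x)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run\n")
  for (lab in names(x$maps)) {
    m <- x$maps[[lab]]
    cat(sprintf("  %s: n = %d, total map %.1f cM\n", lab, m$n,
                sum(m$bins$cM)))
  }
  cat(sprintf("  parent-inconsistent bins masked: %.2f%%\n",
              100 * attr(x$mask, "fraction")))
  invisible(x)
}
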