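new_comparison <- function(test, where, populations, statistic, df, p,
                           percent_change, extra = list()) {
  structure(c(list(test = test, where = where, populations = populations,
                   statistic = statistic, df = df, p_value = p,
                   direction = if (is.na(percent_change)) NA_integer_ else
                     sign(percent_change),
                   percent_change = percent_change), extra),
            class = "comparison_result")
}

#' Chi-square comparison of recombination rate in an interval
#'
#' Pearson chi-square (df 1, no continuity correction) on the 2x2 table of
#' recombinant vs non-recombinant gametes in the two populations, where the
#' recombinant gametes of an interval are its gamete-weighted crossover
#' count (capped at the population's 2n gametes). The percent change is
#' `100 * (cM_a - cM_b) / cM_b`.
#'
#' @param map_a,map_b `population_map`s of the two populations (a is the
#'   treatment, b the reference).
#' @param chrom,start,end the interval compared.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return A `comparison_result` with the statistic, p-value, direction and
#'   percent change; a degenerate table (zero marginal) yields p = 1 with a
#'   warning.
#' @export
compare_interval_chisq <- function(map_a, map_b, chrom, start, end,
                                   correct = FALSE) {
  ra <- min(interval_gametes(map_a, chrom, start, end), map_a$gametes)
  rb <- min(interval_gametes(map_b, chrom, start, end), map_b$gametes)
  tab <- rbind(a = c(recomb = ra, nonrecomb = map_a$gametes - ra),
               b = c(recomb = rb, nonrecomb = map_b$gametes - rb))
  ca <- interval_cM(map_a, chrom, start, end)
  cb <- interval_cM(map_b, chrom, start, end)
  pc <- if (cb > 0) 100 * (ca - cb) / cb else NA_real_
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (zero marginal); p set to 1")
    return(new_comparison("chi-square", list(chrom = chrom, start = start,
                                             end = end),
                          c(map_a$label, map_b$label), 0, 1L, 1, pc,
                          list(cM = c(ca, cb), table = tab)))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  new_comparison("chi-square", list(chrom = chrom, start = start, end = end),
                 c(map_a$label, map_b$label),
                 unname(ct$statistic), unname(ct$parameter),
                 unname(ct$p.value), pc, list(cM = c(ca, cb), table = tab))
}

#' Paired Wilcoxon test on pericentric genetic distance
#'
#' Two-sided paired Wilcoxon signed-rank test across chromosomes on the
#' pericentric cM of the two populations (one pair per chromosome; N = 14
#' for tetraploid wheat). The exact null distribution is used for N <= 25
#' where ties and zero differences permit. Identical maps (all differences
#' zero) give p = 1.
#'
#' @param map_a,map_b `population_map`s.
#' @param regions a `region_classification` with pericentric intervals for
#'   every chromosome.
#' @return A `comparison_result`; `percent_change` is the mean per-chromosome
#'   percent change of pericentric cM (over chromosomes with nonzero
#'   reference cM).
#' @export
compare_pericentric_wilcoxon <- function(map_a, map_b, regions) {
  stopifnot(inherits(regions, "region_classification"))
  peri <- regions[regions$class == "pericentric", , drop = FALSE]
  if (nrow(peri) < 6L) {
    warning("fewer than 6 chromosomes; signed-rank test is degenerate")
  }
  x <- mapply(function(ch, s, e) interval_cM(map_a, ch, s, e),
              peri$chrom, peri$start, peri$end)
  y <- mapply(function(ch, s, e) interval_cM(map_b, ch, s, e),
              peri$chrom, peri$start, peri$end)
  nz <- y > 0
  pc <- if (any(nz)) mean(100 * (x[nz] - y[nz]) / y[nz]) else NA_real_
  if (all(x == y)) {
    return(new_comparison("wilcoxon-signed-rank",
                          list(region = "pericentric", N = nrow(peri)),
                          c(map_a$label, map_b$label), NA_real_, NA_integer_,
                          1, pc, list(cM_a = unname(x), cM_b = unname(y))))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            exact = nrow(peri) <= 25))
  new_comparison("wilcoxon-signed-rank",
                 list(region = "pericentric", N = nrow(peri)),
                 c(map_a$label, map_b$label), unname(wt$statistic),
                 NA_integer_, unname(wt$p.value), pc,
                 list(cM_a = unname(x), cM_b = unname(y)))
}
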