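#' Genetic distance between two codominant markers
#'
#' Direct recombinant-gamete count: for each individual genotyped at both
#' markers, the absolute dosage difference (`P1` = 2, `HET` = 1, `P2` = 0)
#' counts the recombinant gametes between the loci, and
#' `cM = 100 * sum |dosage_1 - dosage_2| / (2n)`. No mapping function is
#' applied; at the interval sizes the method targets (roughly 9-22 cM) a
#' Kosambi or Haldane correction would be within the counting noise.
#' Individuals missing a call at either marker are excluded.
#'
#' @param calls data frame of marker genotypes with columns `sample`,
#'   `marker_id` and either `dosage` (0/1/2) or `call`
#'   (`P1`/`HET`/`P2`/`NA`).
#' @param marker1,marker2 the two marker ids.
#' @return A `marker_interval` list: `cM`, `n_used`, `n_excluded`,
#'   `recombinant_gametes`, `markers`.
#' @export
interval_distance_from_markers <- function(calls, marker1, marker2) {
  require_columns(calls, c("sample", "marker_id"), "calls")
  if (!"dosage" %in% names(calls)) {
    require_columns(calls, "call", "calls")
    map <- c(P2 = 0, HET = 1, P1 = 2)
    calls$dosage <- unname(map[as.character(calls$call)])
  }
  d1 <- calls[calls$marker_id == marker1, c("sample", "dosage")]
  d2 <- calls[calls$marker_id == marker2, c("sample", "dosage")]
  if (nrow(d1) == 0L || nrow(d2) == 0L) stop("marker not found in calls")
  m <- merge(d1, d2, by = "sample", suffixes = c("_1", "_2"))
  ok <- !is.na(m$dosage_1) & !is.na(m$dosage_2)
  n_used <- sum(ok)
  if (n_used == 0L) stop("no individual genotyped at both markers")
  rec <- sum(abs(m$dosage_1[ok] - m$dosage_2[ok]))
  n_excluded <- length(unique(c(d1$sample, d2$sample))) - n_used
  structure(list(cM = 100 * rec / (2 * n_used), n_used = n_used,
                 n_excluded = n_excluded, recombinant_gametes = rec,
                 markers = c(marker1, marker2)),
            class = "marker_interval")
}

#' Filter whole-genome-alignment variants to InDel marker candidates
#'
#' Keeps insertions and deletions on the target chromosome whose length is
#' between `min_len` and `max_len` inclusive -- the size range that is easy
#' to score as a PCR product-size difference on an agarose gel. Malformed
#' records (missing chromosome, type or length) are skipped with a warning.
#'
#' @param variants data frame in the whole-genome-aligner dialect, with
#'   columns `chrom`, `start`, `end`, `type` (e.g. `Insertion`,
#'   `Deletion`, `Repeat_expansion`, ...) and `length` (bp).
#' @param target_chrom chromosome to design markers on.
#' @param min_len,max_len inclusive length bounds in bp (defaults 20 and 200).
#' @return The candidate records, with attribute `counts`
#'   (`n_in`, `n_malformed`, `n_kept`).
#' @export
filter_indel_candidates <- function(variants, target_chrom, min_len = 20,
                                    max_len = 200) {
  require_columns(variants, c("chrom", "type", "length"), "variants")
  bad <- is.na(variants$chrom) | is.na(variants$type) | is.na(variants$length)
  if (any(bad)) {
    warning(sum(bad), " malformed variant record(s) skipped")
  }
  v <- variants[!bad, , drop = FALSE]
  is_indel <- tolower(v$type) %in% c("insertion", "deletion")
  keep <- is_indel & v$chrom == target_chrom &
    v$length >= min_len & v$length <= max_len
  out <- v[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- c(n_in = nrow(variants), n_malformed = sum(bad),
                           n_kept = nrow(out))
  out
}
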