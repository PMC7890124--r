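#' Two-parent genome layout
#'
#' Anchors all coordinates of the analysis: one row per chromosome with the
#' chromosome's length in each parental assembly and the centromere position
#' (parent-1 coordinates). The two parents of the cross typically differ
#' slightly in assembly length; matched bin grids (see [build_bin_grid()])
#' divide both into the same number of bins.
#'
#' @param chrom character vector of chromosome names.
#' @param length_p1,length_p2 chromosome lengths in bp for parent 1 and
#'   parent 2. `length_p2` defaults to `length_p1`.
#' @param centromere centromere positions in bp, parent-1 coordinates.
#' @param parents length-2 character vector of parent labels.
#' @return A `genome_layout` data frame with columns `chrom`, `length_p1`,
#'   `length_p2`, `centromere`.
#' @examples
#' genome_layout("1A", 600e6, 590e6, centromere = 270e6)
#' @export
genome_layout <- function(chrom, length_p1, length_p2 = length_p1, centromere,
                          parents = c("P1", "P2")) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) stop("duplicated chromosome names")
  if (any(length_p1 <= 0) || any(length_p2 <= 0)) {
    stop("chromosome lengths must be positive")
  }
  if (any(centromere < 0 | centromere > length_p1)) {
    stop("centromere position outside chromosome")
  }
  out <- data.frame(chrom = chrom,
                    length_p1 = as.numeric(length_p1),
                    length_p2 = as.numeric(length_p2),
                    centromere = as.numeric(centromere),
                    stringsAsFactors = FALSE)
  attr(out, "parents") <- as.character(parents)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Classify chromosome regions
#'
#' Partitions every chromosome into `subtel_left`, `arm`, `pericentric` and
#' `subtel_right` intervals (0-based half-open, parent-1 coordinates). The
#' pericentric interval can be supplied explicitly (e.g. from
#' [delimit_pericentric()]) or defaults to a symmetric span around the
#' centromere covering `pericentric_frac` of the chromosome.
#'
#' @param layout a [genome_layout()].
#' @param pericentric optional data frame with columns `chrom`, `start`,
#'   `end` giving pericentric intervals; defaults to centromere +/-
#'   `pericentric_frac * length / 2`.
#' @param subtel_frac fraction of chromosome length classified as
#'   subtelomeric at each end (default 0.1).
#' @param pericentric_frac fraction of the chromosome covered by the default
#'   pericentric interval (default 0.5, in line with the large
#'   low-recombination cores of wheat chromosomes).
#' @return A `region_classification` data frame with columns `chrom`,
#'   `start`, `end`, `class`.
#' @export
classify_regions <- function(layout, pericentric = NULL, subtel_frac = 0.1,
                             pericentric_frac = 0.5) {
  stopifnot(inherits(layout, "genome_layout"))
  if (subtel_frac < 0 || subtel_frac >= 0.5) stop("subtel_frac must be in [0, 0.5)")
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    ch <- layout$chrom[i]
    L <- layout$length_p1[i]
    s <- subtel_frac * L
    if (is.null(pericentric)) {
      half <- pericentric_frac * L / 2
      a <- max(0, layout$centromere[i] - half)
      b <- min(L, layout$centromere[i] + half)
    } else {
      j <- match(ch, pericentric$chrom)
      if (is.na(j)) stop("no pericentric interval for chromosome ", ch)
      a <- pericentric$start[j]
      b <- pericentric$end[j]
    }
    if (!(layout$centromere[i] >= a && layout$centromere[i] <= b)) {
      stop("pericentric interval does not contain the centromere on ", ch)
    }
    a <- max(a, s)
    b <- min(b, L - s)
    seg <- data.frame(chrom = ch,
                      start = c(0, s, a, b, L - s),
                      end = c(s, a, b, L - s, L),
                      class = c("subtel_left", "arm", "pericentric", "arm",
                                "subtel_right"),
                      stringsAsFactors = FALSE)
    seg[seg$end > seg$start, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("region_classification", "data.frame")
  out
}

#' Region class at genomic positions
#'
#' @param regions a `region_classification` from [classify_regions()] or
#'   [delimit_pericentric()].
#' @param chrom chromosome name(s), recycled against `pos`.
#' @param pos positions in bp (parent-1 coordinates).
#' @return Character vector of region classes.
#' @export
region_class_at <- function(regions, chrom, pos) {
  stopifnot(inherits(regions, "region_classification"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(pos, n)
  out <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    seg <- regions[regions$chrom == ch, , drop = FALSE]
    if (nrow(seg) == 0L) stop("unknown chromosome: ", ch)
    seg <- seg[order(seg$start), , drop = FALSE]
    sel <- which(chrom == ch)
    p <- pmin(pos[sel], max(seg$end) - 1e-9)  # clamp pos == chromosome end
    idx <- findInterval(p, seg$start)
    idx[p < 0] <- NA_integer_
    out[sel] <- seg$class[idx]
  }
  out
}
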