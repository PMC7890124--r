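#' Piecewise-constant recombination landscape
#'
#' A crossover density along each chromosome, given as cM per Mb on segments
#' that tile `[0, chromosome length)` with no gaps or overlaps. The total map
#' length of a chromosome is the integral of the density.
#'
#' @param chrom chromosome of each segment.
#' @param start,end segment boundaries in bp, 0-based half-open. Per
#'   chromosome, segments must start at 0 and tile without gaps.
#' @param cM_per_Mb non-negative crossover density of each segment.
#' @return A `recomb_landscape` data frame.
#' @seealso [wheat_landscape()] for a convenience constructor with
#'   subtelomeric hotspots and a pericentric low-recombination core;
#'   [total_cM()] for map lengths.
#' @export
recomb_landscape <- function(chrom, start, end, cM_per_Mb) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), cM_per_Mb = as.numeric(cM_per_Mb),
                   stringsAsFactors = FALSE)
  if (any(df$cM_per_Mb < 0)) stop("cM_per_Mb must be non-negative")
  if (any(df$end <= df$start)) stop("segments must have positive width")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  for (ch in unique(df$chrom)) {
    seg <- df[df$chrom == ch, , drop = FALSE]
    if (seg$start[1] != 0) stop("segments must start at 0 on ", ch)
    if (nrow(seg) > 1L && any(seg$start[-1] != seg$end[-nrow(seg)])) {
      stop("segments have gaps or overlaps on ", ch)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("recomb_landscape", "data.frame")
  df
}

#' Total genetic map length of a landscape
#'
#' @param landscape a [recomb_landscape()].
#' @return Named numeric vector: total cM per chromosome (integral of the
#'   cM/Mb density).
#' @export
total_cM <- function(landscape) {
  stopifnot(inherits(landscape, "recomb_landscape"))
  w <- (landscape$end - landscape$start) / 1e6
  tapply(landscape$cM_per_Mb * w, landscape$chrom, sum)[unique(landscape$chrom)]
}

chrom_length_of <- function(landscape, chrom) {
  max(landscape$end[landscape$chrom == chrom])
}

#' Wheat-like recombination landscape
#'
#' Builds a landscape with the broad shape of a wheat chromosome: crossovers
#' concentrated in one hotspot block per subtelomeric arm, a wide
#' low-recombination pericentric core, and no recombination elsewhere.
#'
#' @param layout a [genome_layout()]; one landscape is built per chromosome.
#' @param cM_subtel_left,cM_subtel_right total cM of the left/right
#'   subtelomeric hotspot blocks.
#' @param pericentric_cM_per_Mb density of the pericentric core in cM/Mb.
#' @param pericentric optional data frame (`chrom`, `start`, `end`) for the
#'   core; defaults to the central half of the chromosome.
#' @param hotspot_mb width in Mb of each hotspot block (default 60).
#' @param offset_mb distance in Mb of each hotspot block from the chromosome
#'   end (default 10).
#' @return A [recomb_landscape()] covering every chromosome of `layout`.
#' @export
wheat_landscape <- function(layout, cM_subtel_left = 35, cM_subtel_right = 35,
                            pericentric_cM_per_Mb = 0.00667,
                            pericentric = NULL,
                            hotspot_mb = 60, offset_mb = 10) {
  stopifnot(inherits(layout, "genome_layout"))
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    ch <- layout$chrom[i]
    L <- layout$length_p1[i]
    off <- offset_mb * 1e6
    hw <- hotspot_mb * 1e6
    if (is.null(pericentric)) {
      a <- max(0, layout$centromere[i] - L / 4)
      b <- min(L, layout$centromere[i] + L / 4)
    } else {
      j <- match(ch, pericentric$chrom)
      a <- pericentric$start[j]
      b <- pericentric$end[j]
    }
    if (off + hw > a || L - off - hw < b) {
      stop("hotspot blocks overlap the pericentric core on ", ch)
    }
    bounds <- c(0, off, off + hw, a, b, L - off - hw, L - off, L)
    dens <- c(0, cM_subtel_left / hotspot_mb, 0, pericentric_cM_per_Mb, 0,
              cM_subtel_right / hotspot_mb, 0)
    keep <- diff(bounds) > 0
    data.frame(chrom = ch, start = bounds[-length(bounds)][keep],
               end = bounds[-1][keep], cM_per_Mb = dens[keep],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  recomb_landscape(df$chrom, df$start, df$end, df$cM_per_Mb)
}
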