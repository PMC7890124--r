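#' Build matched bin grids over the two parental genomes
#'
#' Each chromosome is divided into the same number of bins in both parental
#' coordinate systems: `n = round(length_p1 / target_bin_bp)` (minimum 1)
#' equal-width bins per parent, so that bin index `i` of parent 1 matches bin
#' index `i` of parent 2. At the default 1 Mb target, wheat-sized chromosomes
#' (598-851 Mb) yield 598-851 bins.
#'
#' @param layout a [genome_layout()].
#' @param target_bin_bp target bin width in bp (default 1e6).
#' @return A `bin_grid` data frame with columns `chrom`, `bin` (0-based),
#'   `start_p1`, `end_p1`, `start_p2`, `end_p2`. Bin boundaries tile
#'   `[0, length)` half-open in each parent.
#' @examples
#' gl <- genome_layout("1A", 600e6, 595e6, centromere = 270e6)
#' g <- build_bin_grid(gl)
#' nrow(g)  # 600
#' @export
build_bin_grid <- function(layout, target_bin_bp = 1e6) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.numeric(target_bin_bp) || length(target_bin_bp) != 1L ||
      !is.finite(target_bin_bp) || target_bin_bp <= 0) {
    stop("target_bin_bp must be a positive number")
  }
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    L1 <- layout$length_p1[i]
    L2 <- layout$length_p2[i]
    n <- max(1L, as.integer(round(L1 / target_bin_bp)))
    w1 <- L1 / n
    w2 <- L2 / n
    bin <- 0:(n - 1L)
    data.frame(chrom = layout$chrom[i], bin = bin,
               start_p1 = bin * w1, end_p1 = (bin + 1) * w1,
               start_p2 = bin * w2, end_p2 = (bin + 1) * w2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "target_bin_bp") <- target_bin_bp
  attr(out, "layout") <- layout
  class(out) <- c("bin_grid", "data.frame")
  out
}

# bins of one chromosome, ordered
grid_chrom <- function(grid, chrom) {
  g <- grid[grid$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0L) stop("unknown chromosome: ", chrom)
  g[order(g$bin), , drop = FALSE]
}

# per-chromosome bin width for one parent
bin_width <- function(grid, chrom, parent = 1L) {
  g <- grid_chrom(grid, chrom)
  if (parent == 1L) g$end_p1[1] - g$start_p1[1] else g$end_p2[1] - g$start_p2[1]
}

# bin index of positions (half-open: a position on a boundary falls in the
# right-hand bin); positions exactly at chromosome end go to the last bin
bin_index_of <- function(grid, chrom, pos, parent = 1L) {
  g <- grid_chrom(grid, chrom)
  n <- nrow(g)
  w <- bin_width(grid, chrom, parent)
  L <- n * w
  if (any(pos < 0 | pos > L)) stop("position outside chromosome ", chrom)
  pmin(as.integer(floor(pos / w)), n - 1L)
}
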