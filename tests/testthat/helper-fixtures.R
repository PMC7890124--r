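# shared fixtures, all built in code

# 600 Mb single wheat-like chromosome, the standard study design
wt_layout <- function() genome_layout("1A", 600e6, 595e6, centromere = 300e6)

wt_pericentric <- function() data.frame(chrom = "1A", start = 150e6,
                                        end = 450e6)

wt_regions <- function() {
  classify_regions(wt_layout(), pericentric = wt_pericentric(),
                   subtel_frac = 0.125)
}

# 70 cM split between two subtelomeric hotspot blocks + 2 cM pericentric
wt_landscape <- function() {
  wheat_landscape(wt_layout(), cM_subtel_left = 35, cM_subtel_right = 35,
                  pericentric_cM_per_Mb = 2 / 300,
                  pericentric = wt_pericentric())
}

# tetraploid-like 14-chromosome layout spanning the 598-851 Mb range
tetraploid_layout <- function() {
  lens <- round(seq(598e6, 851e6, length.out = 14))
  chroms <- paste0(rep(1:7, 2), rep(c("A", "B"), each = 7))
  genome_layout(chroms, lens, lens, centromere = round(0.45 * lens))
}

tetraploid_pericentric <- function(layout) {
  data.frame(chrom = layout$chrom, start = round(0.2 * layout$length_p1),
             end = round(0.7 * layout$length_p1))
}

# genotype track with prescribed calls on a uniform grid; raw ratios default
# to the call's expected value (1 / 0.5 / 0 / NA)
make_tracks <- function(calls, width = 1e6, chrom = "chr1", sample = "s1",
                        ratio = NULL, total = 60) {
  n <- length(calls)
  exp_ratio <- c(HOM_P1 = 1, HET = 0.5, HOM_P2 = 0, MISSING = NA_real_)
  if (is.null(ratio)) ratio <- unname(exp_ratio[calls])
  tr <- data.frame(sample = sample, chrom = chrom, bin = 0:(n - 1),
                   start = (0:(n - 1)) * width, end = (1:n) * width,
                   reads_p1 = round(total * ifelse(is.na(ratio), 0, ratio)),
                   reads_p2 = round(total * ifelse(is.na(ratio), 0, 1 - ratio)),
                   total = ifelse(calls == "MISSING", 0L, total),
                   ratio = ratio, masked = calls == "MISSING",
                   smooth = ratio, smooth_n = 1L, call = calls,
                   stringsAsFactors = FALSE)
  class(tr) <- c("genotype_tracks", "data.frame")
  tr
}

grid_for <- function(length_bp, width = 1e6, chrom = "chr1") {
  build_bin_grid(genome_layout(chrom, length_bp, length_bp,
                               centromere = length_bp / 2), width)
}

# co_events table with prescribed midpoints (zero-width bounding intervals)
make_events <- function(mids, left, right, chrom = "chr1", sample = "s1") {
  lab_dos <- c(HOM_P2 = 0, HET = 1, HOM_P1 = 2)
  if (length(mids) == 0L) {
    df <- data.frame(sample = character(0), chrom = character(0),
                     start = numeric(0), end = numeric(0), mid = numeric(0),
                     left = character(0), right = character(0),
                     gametes = numeric(0), region = character(0),
                     status = character(0), stringsAsFactors = FALSE)
  } else {
    df <- data.frame(sample = sample, chrom = chrom, start = mids, end = mids,
                     mid = mids, left = left, right = right,
                     gametes = unname(abs(lab_dos[left] - lab_dos[right])),
                     region = NA_character_, status = "kept",
                     stringsAsFactors = FALSE)
  }
  class(df) <- c("co_events", "data.frame")
  df
}

# population map with a prescribed number of recombinant gametes placed in
# the bin containing each position
map_with_gametes <- function(grid, n, pos, gametes, chrom = "chr1",
                             label = "pop") {
  ev <- data.frame(sample = "s", chrom = chrom, start = pos, end = pos,
                   mid = pos, left = NA, right = NA, gametes = gametes,
                   region = NA, status = "kept", stringsAsFactors = FALSE)
  build_population_map(ev, grid, n, label = label)
}
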