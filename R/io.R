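# Tabular readers/writers. All genomic intervals are written 0-based
# half-open (BED convention); coordinates are rounded to whole bp on output.

#' Read a genome layout TSV
#'
#' Columns: `chrom`, `length_p1`, `length_p2`, `centromere`.
#' @param path file path.
#' @return A [genome_layout()].
#' @export
read_layout_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("chrom", "length_p1", "length_p2", "centromere"),
                  "layout file")
  genome_layout(df$chrom, df$length_p1, df$length_p2, df$centromere)
}

#' Read / write a recombination landscape TSV
#'
#' Columns: `chrom`, `start`, `end`, `cM_per_Mb` (0-based half-open
#' segments).
#' @param path file path.
#' @return A [recomb_landscape()].
#' @export
read_landscape_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("chrom", "start", "end", "cM_per_Mb"),
                  "landscape file")
  recomb_landscape(df$chrom, df$start, df$end, df$cM_per_Mb)
}

#' @rdname read_landscape_tsv
#' @param landscape a [recomb_landscape()].
#' @export
write_landscape_tsv <- function(landscape, path) {
  utils::write.table(as.data.frame(landscape), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a parent-assigned read table (TSV)
#'
#' Columns: `sample`, `parent` (`P1`/`P2`), `chrom`, `pos` (0-based bp on
#' that parent's assembly), `mapq`, `unique` (0/1), `nm` (mismatch count).
#' @param path file path.
#' @return Data frame of read records for [filter_reads()] /
#'   [aggregate_counts()].
#' @export
read_reads_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("parent", "chrom", "pos"), "reads file")
  df
}

#' Write crossover events as BED-like TSV
#'
#' Columns: `chrom`, `start`, `end`, `sample`, `gametes`, `region`,
#' `status`.
#' @param events a `co_events` data frame.
#' @param path file path.
#' @export
write_events_tsv <- function(events, path) {
  out <- data.frame(chrom = events$chrom, start = round(events$start),
                    end = round(events$end), sample = events$sample,
                    gametes = events$gametes, region = events$region,
                    status = events$status, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a population map as bedGraph
#'
#' One line per bin with the recombination rate (cM/Mb).
#' @param map a `population_map`.
#' @param path file path.
#' @export
write_map_bedgraph <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s cM/Mb"', map$label), con)
  b <- map$bins
  writeLines(sprintf("%s\t%d\t%d\t%.6g", b$chrom, round(b$start),
                     round(b$end), b$cM_per_Mb), con)
  invisible(path)
}

#' Write per-sample genotype tracks as BED4
#'
#' Consecutive bins with the same call are merged into one BED record;
#' one file `<sample>.bed` per sample.
#' @param tracks a `genotype_tracks` data frame.
#' @param dir output directory (created if needed).
#' @export
write_genotypes_bed <- function(tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in unique(tracks$sample)) {
    tr <- tracks[tracks$sample == s, , drop = FALSE]
    rows <- list(); k <- 0L
    for (ch in unique(tr$chrom)) {
      t1 <- tr[tr$chrom == ch, , drop = FALSE]
      t1 <- t1[order(t1$bin), , drop = FALSE]
      r <- rle(t1$call)
      hi <- cumsum(r$lengths)
      lo <- hi - r$lengths + 1L
      k <- k + 1L
      rows[[k]] <- data.frame(chrom = ch, start = round(t1$start[lo]),
                              end = round(t1$end[hi]), call = r$values,
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    utils::write.table(out, file.path(dir, paste0(s, ".bed")), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Write per-sample smoothed ratio tracks as bedGraph
#'
#' One file `<sample>.bedgraph` per sample with the smoothed parent-1 read
#' fraction; bins without a smoothed value are skipped.
#' @param tracks a `ratio_track`/`genotype_tracks` data frame with a
#'   `smooth` column.
#' @param dir output directory (created if needed).
#' @export
write_ratio_bedgraph <- function(tracks, dir) {
  if (!"smooth" %in% names(tracks)) {
    stop("tracks have no smoothed ratio; run smooth_ratio() first")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in unique(tracks$sample)) {
    tr <- tracks[tracks$sample == s & !is.na(tracks$smooth), , drop = FALSE]
    tr <- tr[order(tr$chrom, tr$bin), , drop = FALSE]
    con <- file(file.path(dir, paste0(s, ".bedgraph")), "w")
    writeLines(sprintf('track type=bedGraph name="%s parent-1 ratio"', s),
               con)
    writeLines(sprintf("%s\t%d\t%d\t%.6g", tr$chrom, round(tr$start),
                       round(tr$end), tr$smooth), con)
    close(con)
  }
  invisible(dir)
}

#' Read marker genotype calls (CSV)
#'
#' Columns: `sample`, `marker_id`, `chrom`, `pos`, `call` in
#' `P1`/`HET`/`P2`/`NA`.
#' @param path file path.
#' @return Data frame for [interval_distance_from_markers()].
#' @export
read_marker_calls_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  require_columns(df, c("sample", "marker_id", "call"), "marker file")
  df
}

#' Read a whole-genome-alignment variant table (BED-like TSV)
#'
#' Columns: `chrom`, `start`, `end`, `type`, `length`.
#' @param path file path.
#' @return Data frame for [filter_indel_candidates()].
#' @export
read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("chrom", "start", "end", "type", "length"),
                  "variants file")
  df
}
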