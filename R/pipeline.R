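#' Configuration of an end-to-end synthetic run
#'
#' Bundles the genome layout, the per-population recombination landscapes,
#' the coverage model, every pipeline threshold and the RNG seed. The seed
#' fans out deterministically into per-stage, per-population substreams, so
#' a run is reproducible from its serialized configuration alone.
#'
#' @param layout a [genome_layout()].
#' @param landscapes named list of [recomb_landscape()]s, one per population;
#'   the first is the control (reference) population.
#' @param n individuals per population (>= 1).
#' @param coverage a [coverage_model()].
#' @param regions optional [classify_regions()] classification used for
#'   coverage simulation and the double-crossover filter; defaults to
#'   `classify_regions(layout, subtel_frac = subtel_frac)`.
#' @param bin_bp bin width target (default 1e6).
#' @param window_bins ratio smoothing window (odd, default 15).
#' @param hi,lo homozygosity thresholds (defaults 0.9, 0.1).
#' @param min_reads minimum reads per bin (default 10).
#' @param mapq_min read mapping-quality threshold (default 30; read-level
#'   input only).
#' @param d_subtel,d_pericen double-crossover minimum separations (defaults
#'   8e6 and 7e7).
#' @param peri_threshold,peri_window_mb pericentric delimitation rate
#'   threshold (cM/Mb) and smoothing window (Mb).
#' @param subtel_frac subtelomeric fraction for region classification.
#' @param seed integer RNG seed.
#' @return A `run_config` list.
#' @export
run_config <- function(layout, landscapes, n = 90,
                       coverage = coverage_model(), regions = NULL,
                       bin_bp = 1e6, window_bins = 15, hi = 0.9, lo = 0.1,
                       min_reads = 10, mapq_min = 30,
                       d_subtel = 8e6, d_pericen = 7e7,
                       peri_threshold = 0.1, peri_window_mb = 10,
                       subtel_frac = 0.1, seed = 1L) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.list(landscapes) || is.null(names(landscapes)) ||
      any(names(landscapes) == "")) {
    stop("landscapes must be a named list of recomb_landscape objects")
  }
  for (l in landscapes) stopifnot(inherits(l, "recomb_landscape"))
  if (!is_count(n) || n < 1) stop("n must be a positive integer")
  if (lo >= hi) stop("lo must be strictly below hi")
  for (v in c(bin_bp, window_bins, min_reads, d_subtel, d_pericen,
              peri_threshold, peri_window_mb)) {
    if (!is.numeric(v) || v <= 0) stop("all thresholds must be positive")
  }
  if (is.null(regions)) {
    regions <- classify_regions(layout, subtel_frac = subtel_frac)
  }
  structure(list(layout = layout, landscapes = landscapes, n = as.integer(n),
                 coverage = coverage, regions = regions, bin_bp = bin_bp,
                 window_bins = window_bins, hi = hi, lo = lo,
                 min_reads = min_reads, mapq_min = mapq_min,
                 d_subtel = d_subtel, d_pericen = d_pericen,
                 peri_threshold = peri_threshold,
                 peri_window_mb = peri_window_mb, subtel_frac = subtel_frac,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize / load a run configuration (YAML)
#'
#' @param config a [run_config()].
#' @param path file path.
#' @export
config_to_yaml <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list(
    layout = lapply(seq_len(nrow(config$layout)), function(i)
      as.list(as.data.frame(config$layout)[i, ])),
    landscapes = lapply(config$landscapes, function(l)
      lapply(seq_len(nrow(l)), function(i) as.list(as.data.frame(l)[i, ]))),
    regions = lapply(seq_len(nrow(config$regions)), function(i)
      as.list(as.data.frame(config$regions)[i, ])),
    coverage = list(means = as.list(config$coverage$means),
                    epsilon = config$coverage$epsilon,
                    p_artifact = config$coverage$p_artifact),
    n = config$n, bin_bp = config$bin_bp, window_bins = config$window_bins,
    hi = config$hi, lo = config$lo, min_reads = config$min_reads,
    mapq_min = config$mapq_min, d_subtel = config$d_subtel,
    d_pericen = config$d_pericen, peri_threshold = config$peri_threshold,
    peri_window_mb = config$peri_window_mb,
    subtel_frac = config$subtel_frac, seed = config$seed)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname config_to_yaml
#' @export
config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  lay <- do.call(rbind, lapply(x$layout, as.data.frame))
  layout <- genome_layout(lay$chrom, lay$length_p1, lay$length_p2,
                          lay$centromere)
  landscapes <- lapply(x$landscapes, function(l) {
    df <- do.call(rbind, lapply(l, as.data.frame))
    recomb_landscape(df$chrom, df$start, df$end, df$cM_per_Mb)
  })
  regions <- do.call(rbind, lapply(x$regions, as.data.frame))
  class(regions) <- c("region_classification", "data.frame")
  cov <- coverage_model(x$coverage$means$arm, x$coverage$means$pericentric,
                        x$coverage$means$subtel_left,
                        x$coverage$means$subtel_right,
                        x$coverage$epsilon, x$coverage$p_artifact)
  run_config(layout, landscapes, n = x$n, coverage = cov, regions = regions,
             bin_bp = x$bin_bp, window_bins = x$window_bins, hi = x$hi,
             lo = x$lo, min_reads = x$min_reads, mapq_min = x$mapq_min,
             d_subtel = x$d_subtel, d_pericen = x$d_pericen,
             peri_threshold = x$peri_threshold,
             peri_window_mb = x$peri_window_mb,
             subtel_frac = x$subtel_frac, seed = x$seed)
}

#' Run the full synthetic pipeline
#'
#' Simulate the configured populations and the two parental libraries,
#' genotype all bins, mask parent-inconsistent bins, call and filter
#' crossovers, build population maps, delimit pericentric regions from the
#' control map, and compare every other population against the control
#' (per-chromosome pericentric chi-square, whole-chromosome chi-square, and
#' a genome-wide paired Wilcoxon on pericentric cM). Deterministic given the
#' config seed.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory; when given, the configuration,
#'   truth tables, event tables, maps and a machine-readable JSON report are
#'   written there.
#' @param write_tracks also write per-sample genotype BED tracks (default
#'   FALSE; they are bulky).
#' @return Invisibly, a `pipeline_run` list: `maps`, `events`, `mask`,
#'   `populations` (the simulated truth), `regions_delimited`,
#'   `comparisons`, `report`.
#' @export
run_pipeline <- function(config, out_dir = NULL, write_tracks = FALSE) {
  stopifnot(inherits(config, "run_config"))
  sd <- function(...) substream_seed(config$seed, ...)
  grid <- build_bin_grid(config$layout, config$bin_bp)
  regions <- config$regions
  labels <- names(config$landscapes)

  artifact <- draw_artifact_bins(grid, config$coverage$p_artifact,
                                 seed = sd(1))
  p1c <- simulate_parent_counts(grid, config$coverage, regions, parent = 1L,
                                seed = sd(2, 1), artifact_bins = artifact)
  p2c <- simulate_parent_counts(grid, config$coverage, regions, parent = 2L,
                                seed = sd(2, 2), artifact_bins = artifact)
  # parental tracks are called unsmoothed so isolated aberrant bins stay
  # visible to the consistency screen
  p1t <- genotype_bins(p1c, config$min_reads, window_bins = 1,
                       hi = config$hi, lo = config$lo)
  p2t <- genotype_bins(p2c, config$min_reads, window_bins = 1,
                       hi = config$hi, lo = config$lo)
  mask <- mask_parent_inconsistent_bins(p1t, p2t)

  pops <- list(); events <- list(); maps <- list(); tracks_out <- list()
  log_lines <- c(sprintf("masked parent-inconsistent bins: %d of %d (%.2f%%)",
                         sum(mask$masked), nrow(mask),
                         100 * attr(mask, "fraction")))
  for (k in seq_along(labels)) {
    lab <- labels[k]
    pop <- simulate_f2_population(config$n, config$landscapes[[k]],
                                  seed = sd(3, k),
                                  sample_prefix = paste0(lab, "_"))
    counts <- simulate_bin_counts(pop, grid, config$coverage, regions,
                                  seed = sd(4, k), artifact_bins = artifact)
    tracks <- genotype_bins(counts, config$min_reads, config$window_bins,
                            config$hi, config$lo, bin_mask = mask)
    ev <- call_crossovers(tracks, grid, regions)
    fev <- filter_double_crossovers(ev, regions, config$d_subtel,
                                    config$d_pericen)
    n_rm <- sum(fev$status == "removed_dco")
    log_lines <- c(log_lines,
                   sprintf("%s: %d events called, %d removed by double-CO filter, %d kept",
                           lab, nrow(ev), n_rm, nrow(fev) - n_rm))
    pops[[lab]] <- pop
    events[[lab]] <- fev
    maps[[lab]] <- build_population_map(fev, grid, config$n, label = lab)
    if (write_tracks) tracks_out[[lab]] <- tracks
  }

  delim <- delimit_pericentric(maps[[1]], config$layout,
                               config$peri_threshold, config$peri_window_mb,
                               config$subtel_frac)

  peri <- config$regions[config$regions$class == "pericentric", , drop = FALSE]
  comparisons <- list()
  if (length(labels) > 1L) {
    for (k in 2:length(labels)) {
      percs <- lapply(seq_len(nrow(peri)), function(i) {
        compare_interval_chisq(maps[[k]], maps[[1]], peri$chrom[i],
                               peri$start[i], peri$end[i])
      })
      names(percs) <- peri$chrom
      whole <- lapply(seq_len(nrow(config$layout)), function(i) {
        compare_interval_chisq(maps[[k]], maps[[1]], config$layout$chrom[i],
                               0, config$layout$length_p1[i])
      })
      names(whole) <- config$layout$chrom
      wilx <- compare_pericentric_wilcoxon(maps[[k]], maps[[1]],
                                           config$regions)
      comparisons[[labels[k]]] <- list(pericentric_chisq = percs,
                                       chromosome_chisq = whole,
                                       pericentric_wilcoxon = wilx)
    }
  }

  report <- build_report(config, maps, events, mask, delim, comparisons)
  run <- structure(list(maps = maps, events = events, mask = mask,
                        populations = pops, regions_delimited = delim,
                        comparisons = comparisons, report = report),
                   class = "pipeline_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    config_to_yaml(config, file.path(out_dir, "config.yaml"))
    for (lab in labels) {
      tr <- pops[[lab]]$truth
      truth_bed <- data.frame(chrom = tr$chrom, start = round(tr$pos),
                              end = round(tr$pos), sample = tr$sample,
                              gamete = tr$gamete, stringsAsFactors = FALSE)
      utils::write.table(truth_bed,
                         file.path(out_dir, paste0("truth_", lab, ".bed")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_events_tsv(events[[lab]],
                       file.path(out_dir, paste0("events_", lab, ".tsv")))
      write_map_bedgraph(maps[[lab]],
                         file.path(out_dir, paste0("map_", lab, ".bedgraph")))
      if (write_tracks) {
        write_genotypes_bed(tracks_out[[lab]],
                            file.path(out_dir, paste0("tracks_", lab)))
        write_ratio_bedgraph(tracks_out[[lab]],
                             file.path(out_dir, paste0("ratios_", lab)))
      }
    }
    writeLines(log_lines, file.path(out_dir, "log.txt"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(run)
}

comparison_as_list <- function(cmp) {
  list(test = cmp$test, where = cmp$where, populations = cmp$populations,
       statistic = cmp$statistic, df = cmp$df, p_value = cmp$p_value,
       direction = cmp$direction, percent_change = cmp$percent_change)
}

build_report <- function(config, maps, events, mask, delim, comparisons) {
  spans <- attr(delim, "spans")
  pops <- lapply(names(maps), function(lab) {
    m <- maps[[lab]]
    per_chrom <- lapply(unique(m$bins$chrom), function(ch) {
      b <- m$bins[m$bins$chrom == ch, ]
      ev <- events[[lab]]
      list(chrom = ch, co_gametes = sum(b$co_gametes), cM = sum(b$cM),
           n_events = sum(ev$chrom == ch & ev$status != "removed_dco"),
           n_removed_dco = sum(ev$chrom == ch & ev$status == "removed_dco"))
    })
    peri <- config$regions[config$regions$class == "pericentric", ]
    peri_cM <- mapply(function(ch, s, e) interval_cM(m, ch, s, e),
                      peri$chrom, peri$start, peri$end)
    list(label = lab, n = m$n, gametes = m$gametes,
         chromosomes = per_chrom,
         pericentric_cM = as.list(stats::setNames(peri_cM, peri$chrom)))
  })
  names(pops) <- names(maps)
  list(
    seed = config$seed, n = config$n,
    thresholds = list(bin_bp = config$bin_bp,
                      window_bins = config$window_bins, hi = config$hi,
                      lo = config$lo, min_reads = config$min_reads,
                      d_subtel = config$d_subtel,
                      d_pericen = config$d_pericen,
                      peri_threshold = config$peri_threshold,
                      peri_window_mb = config$peri_window_mb),
    masked_bins = list(n = sum(mask$masked), total = nrow(mask),
                       fraction = attr(mask, "fraction")),
    pericentric_delimited = lapply(seq_len(nrow(spans)), function(i)
      as.list(spans[i, ])),
    populations = pops,
    comparisons = lapply(comparisons, function(cc) {
      list(pericentric_chisq = lapply(cc$pericentric_chisq,
                                      comparison_as_list),
           chromosome_chisq = lapply(cc$chromosome_chisq,
                                     comparison_as_list),
           pericentric_wilcoxon = comparison_as_list(
             cc$pericentric_wilcoxon))
    }))
}
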