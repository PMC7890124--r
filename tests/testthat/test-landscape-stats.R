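test_that("population maps convert gamete counts to cM and cM/Mb", {
  grid <- grid_for(100e6)
  # n = 100: 10 recombinant gametes in one interval = 5 cM
  m <- map_with_gametes(grid, 100, pos = rep(30.5e6, 10), gametes = 1)
  expect_equal(interval_cM(m, "chr1", 20e6, 40e6), 5)
  expect_equal(sum(m$bins$cM), 5)
  expect_equal(m$bins$cM_per_Mb[m$bins$bin == 30], 5)
  # no events: flat zero
  z <- build_population_map(make_events(numeric(0), character(0),
                                        character(0)), grid, 100)
  expect_true(all(z$bins$cM == 0))
  # doubling the events doubles every cM (2n fixed)
  m2 <- map_with_gametes(grid, 100, pos = rep(30.5e6, 20), gametes = 1)
  expect_equal(m2$bins$cM, 2 * m$bins$cM)
  expect_error(build_population_map(make_events(1e6, "HET", "HOM_P1"),
                                    grid, 0), "positive")
})

test_that("map conservation: cM/Mb integrates back to total cM", {
  grid <- build_bin_grid(wt_layout())
  pop <- simulate_f2_population(60, wt_landscape(), seed = 40)
  m <- population_map_from_truth(pop, grid)
  expect_equal(sum(m$bins$cM_per_Mb * m$bins$width_mb),
               100 * nrow(pop$truth) / (2 * 60))
  # monotonicity: adding events never decreases interval cM
  extra <- make_events(123.5e6, "HET", "HOM_P1", chrom = "1A",
                       sample = "extra")
  ev <- rbind(true_dosage_events(pop), extra)
  m2 <- build_population_map(ev, grid, 60)
  m1 <- build_population_map(true_dosage_events(pop), grid, 60)
  expect_true(all(m2$bins$co_gametes >= m1$bins$co_gametes))
  expect_gt(interval_cM(m2, "1A", 120e6, 130e6),
            interval_cM(m1, "1A", 120e6, 130e6) - 1e-12)
})

test_that("pericentric delimitation spans the low-recombination core", {
  gl <- wt_layout()
  grid <- build_bin_grid(gl)
  # flat-zero control map: the whole chromosome is pericentric
  z <- build_population_map(make_events(numeric(0), character(0),
                                        character(0), chrom = "1A"),
                            grid, 90)
  rg <- delimit_pericentric(z, gl)
  spans <- attr(rg, "spans")
  expect_equal(spans$start, 0)
  expect_equal(spans$end, 600e6)
  # uniformly hot map: the span collapses to the centromere bin
  hot <- population_map_from_truth(
    simulate_f2_population(200, recomb_landscape("1A", 0, 600e6, 1),
                           seed = 41), grid)
  rg2 <- delimit_pericentric(hot, gl)
  expect_lt(attr(rg2, "spans")$span_mb, 30)
  # zero-density central 400 Mb flanked by hotspot blocks: recovered span
  # within +/- 2 windows of the truth
  ls <- recomb_landscape("1A", c(0, 40e6, 100e6, 500e6, 560e6),
                         c(40e6, 100e6, 500e6, 560e6, 600e6),
                         c(0, 0.5, 0, 0.5, 0))
  m <- population_map_from_truth(simulate_f2_population(90, ls, seed = 42),
                                 grid)
  rg3 <- delimit_pericentric(m, gl)
  sp <- attr(rg3, "spans")
  expect_lt(abs(sp$start - 100e6), 20e6)
  expect_lt(abs(sp$end - 500e6), 20e6)
  expect_error(delimit_pericentric(z, genome_layout("1B", 1e8, 1e8, 5e7)),
               "no bins")
})

test_that("interval chi-square matches the brute-force statistic", {
  grid <- grid_for(100e6)
  # recombinant gametes 30/200 vs 15/200
  ma <- map_with_gametes(grid, 100, rep(10.5e6, 30), 1, label = "a")
  mb <- map_with_gametes(grid, 100, rep(10.5e6, 15), 1, label = "b")
  cmp <- compare_interval_chisq(ma, mb, "chr1", 0, 100e6)
  tab <- rbind(c(30, 170), c(15, 185))
  expect_equal(cmp$statistic, chisq_oracle(tab), tolerance = 1e-12)
  expect_equal(cmp$statistic, 5.6338, tolerance = 1e-4)
  expect_equal(cmp$df, 1)
  expect_equal(cmp$percent_change, 100)
  # swapping rows leaves statistic and p unchanged
  cmp_sw <- compare_interval_chisq(mb, ma, "chr1", 0, 100e6)
  expect_equal(cmp_sw$statistic, cmp$statistic)
  expect_equal(cmp_sw$p_value, cmp$p_value)
  # identical populations: statistic 0, p 1
  cmp_id <- compare_interval_chisq(ma, ma, "chr1", 0, 100e6)
  expect_equal(cmp_id$statistic, 0, tolerance = 1e-12)
  expect_equal(cmp_id$p_value, 1)
  # degenerate table (no events anywhere): p = 1 with a warning
  z <- build_population_map(make_events(numeric(0), character(0),
                                        character(0)), grid, 100)
  expect_warning(cmp_z <- compare_interval_chisq(z, z, "chr1", 0, 100e6),
                 "degenerate")
  expect_equal(cmp_z$p_value, 1)
})

test_that("paired pericentric Wilcoxon matches exact enumeration", {
  gl <- tetraploid_layout()
  peri <- tetraploid_pericentric(gl)
  rg <- classify_regions(gl, pericentric = peri)
  grid <- build_bin_grid(gl)
  # distinct recombinant-gamete counts so no absolute differences tie
  base_k <- 15 + 2 * (1:14)
  trt_k <- base_k + seq(3, 29, by = 2)
  mk_map <- function(ks, label) {
    pos <- (peri$start + peri$end) / 2
    ev <- do.call(rbind, lapply(1:14, function(i) {
      k <- ks[i]
      make_events(rep(pos[i], k), rep("HET", k), rep("HOM_P1", k),
                  chrom = gl$chrom[i])
    }))
    build_population_map(ev, grid, 90, label = label)
  }
  mb <- mk_map(base_k, "control")
  ma <- mk_map(trt_k, "treated")
  cmp <- compare_pericentric_wilcoxon(ma, mb, rg)
  # all 14 differences positive: the exact two-sided p is 2 / 2^14
  expect_equal(cmp$p_value, 2 / 2^14, tolerance = 1e-10)
  xa <- vapply(1:14, function(i)
    interval_cM(ma, gl$chrom[i], peri$start[i], peri$end[i]), 0)
  xb <- vapply(1:14, function(i)
    interval_cM(mb, gl$chrom[i], peri$start[i], peri$end[i]), 0)
  expect_equal(cmp$p_value, signrank_p_oracle(xa - xb), tolerance = 1e-10)
  # identical maps: p = 1
  expect_equal(compare_pericentric_wilcoxon(mb, mb, rg)$p_value, 1)
  # sign-flipping every difference leaves the two-sided p unchanged
  cmp_fl <- compare_pericentric_wilcoxon(mb, ma, rg)
  expect_equal(cmp_fl$p_value, cmp$p_value)
})

test_that("marker-pair genetic distance counts recombinant gametes directly", {
  calls <- data.frame(sample = rep(sprintf("s%03d", 1:100), each = 2),
                      marker_id = rep(c("m1", "m2"), 100),
                      call = "P1", stringsAsFactors = FALSE)
  expect_equal(interval_distance_from_markers(calls, "m1", "m2")$cM, 0)
  # 10 of 100 individuals with a single-gamete change: 5 cM
  calls$call[calls$marker_id == "m2"][1:10] <- "HET"
  d <- interval_distance_from_markers(calls, "m1", "m2")
  expect_equal(d$cM, 5)
  expect_equal(d$recombinant_gametes, 10)
  # a homozygote-to-homozygote change contributes two gametes
  calls$call[calls$marker_id == "m2"][11] <- "P2"
  expect_equal(interval_distance_from_markers(calls, "m1", "m2")$cM, 6)
  # missing calls exclude the individual and are reported
  calls$call[2] <- NA
  d2 <- interval_distance_from_markers(calls, "m1", "m2")
  expect_equal(d2$n_used, 99)
  expect_equal(d2$n_excluded, 1)
  expect_equal(d2$cM, 100 * 11 / 198)
})

test_that("InDel candidate filtering applies inclusive 20-200 bp bounds", {
  v <- data.frame(chrom = c("1A", "1A", "1A", "2A", "1A", "1A"),
                  start = 1:6, end = 2:7,
                  type = c("Deletion", "Insertion", "Deletion", "Insertion",
                           "Repeat_expansion", "Deletion"),
                  length = c(20, 200, 19, 150, 100, 201))
  out <- filter_indel_candidates(v, "1A")
  expect_equal(out$length, c(20, 200))  # inclusive bounds, indels, 1A only
  cnt <- attr(out, "counts")
  expect_equal(unname(cnt["n_kept"]), 2)
  v$type[1] <- NA
  expect_warning(out2 <- filter_indel_candidates(v, "1A"), "malformed")
  expect_equal(nrow(out2), 1)
})
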