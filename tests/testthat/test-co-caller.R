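test_that("crossovers are called at genotype transitions with gamete weights", {
  grid <- grid_for(10e6)
  ev <- call_crossovers(make_tracks(c("HOM_P1", "HOM_P1", "HET", "HET",
                                      rep("HET", 6))), grid)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$gametes, 1)
  expect_equal(ev$mid, 2e6)                 # junction between bins 1 and 2
  expect_equal(c(ev$start, ev$end), c(1e6, 3e6))  # two bounding bins
  # homozygote-to-homozygote change implies both gametes recombined
  ev2 <- call_crossovers(make_tracks(c("HOM_P1", "HOM_P2", rep("HOM_P2", 8))),
                         grid)
  expect_equal(ev2$gametes, 2)
  # genotype is carried across missing bins: no event
  ev3 <- call_crossovers(make_tracks(c("HET", "MISSING", "HET",
                                       rep("HET", 7))), grid)
  expect_equal(nrow(ev3), 0L)
  # ... and an event bridging a gap spans it
  ev4 <- call_crossovers(make_tracks(c("HOM_P1", "HOM_P1", "MISSING",
                                       "MISSING", "HET", rep("HET", 5))),
                         grid)
  expect_equal(nrow(ev4), 1L)
  expect_equal(c(ev4$start, ev4$end), c(1e6, 5e6))
  expect_warning(call_crossovers(make_tracks(rep("MISSING", 10)), grid),
                 "all bins missing")
})

test_that("junction refinement undoes the smoothing displacement", {
  # raw ratios switch 1 -> 0.5 at bin 20; smoothing shifts the called
  # transition ~5 bins toward the homozygous side, refinement restores it
  n <- 40
  cnt <- data.frame(sample = "s", chrom = "chr1", bin = 0:(n - 1),
                    start = (0:(n - 1)) * 1e6, end = (1:n) * 1e6,
                    reads_p1 = c(rep(60, 20), rep(30, 20)),
                    reads_p2 = c(rep(0, 20), rep(30, 20)))
  tracks <- genotype_bins(cnt)
  grid <- grid_for(n * 1e6)
  ev_raw <- call_crossovers(tracks, grid, refine = FALSE)
  ev_ref <- call_crossovers(tracks, grid, refine = TRUE)
  expect_equal(nrow(ev_ref), 1L)
  expect_lt(ev_raw$mid, 20e6)   # displaced by the window mean
  expect_equal(ev_ref$mid, 20e6)
  expect_equal(c(ev_ref$start, ev_ref$end), c(19e6, 21e6))
})

test_that("double-crossover filter removes close pairs by region class", {
  gl <- genome_layout("chr1", 400e6, 400e6, centromere = 200e6)
  rg <- classify_regions(gl, pericentric = data.frame(chrom = "chr1",
                                                      start = 100e6,
                                                      end = 300e6))
  # subtelomeric pair 5 Mb apart: removed; 9 Mb apart: kept
  ev <- make_events(c(10e6, 15e6), c("HOM_P1", "HET"), c("HET", "HOM_P1"))
  out <- filter_double_crossovers(ev, rg)
  expect_true(all(out$status == "removed_dco"))
  ev <- make_events(c(10e6, 19e6), c("HOM_P1", "HET"), c("HET", "HOM_P1"))
  out <- filter_double_crossovers(ev, rg)
  expect_true(all(out$status == "kept"))
  # pericentric pair 50 Mb apart: removed (50 < 70)
  ev <- make_events(c(180e6, 230e6), c("HET", "HOM_P1"), c("HOM_P1", "HET"))
  out <- filter_double_crossovers(ev, rg)
  expect_true(all(out$status == "removed_dco"))
  # pair straddling the pericentric boundary takes the segment's class
  ev <- make_events(c(90e6, 140e6), c("HET", "HOM_P1"), c("HOM_P1", "HET"))
  out <- filter_double_crossovers(ev, rg)  # segment midpoint 115e6: pericentric
  expect_true(all(out$status == "removed_dco"))
})

test_that("filter boundary is strict at 8 Mb and 70 Mb", {
  gl <- genome_layout("chr1", 400e6, 400e6, centromere = 200e6)
  rg <- classify_regions(gl, pericentric = data.frame(chrom = "chr1",
                                                      start = 100e6,
                                                      end = 300e6))
  near <- filter_double_crossovers(
    make_events(c(10e6, 17.99e6), c("HOM_P1", "HET"), c("HET", "HOM_P1")), rg)
  far <- filter_double_crossovers(
    make_events(c(10e6, 18.01e6), c("HOM_P1", "HET"), c("HET", "HOM_P1")), rg)
  expect_true(all(near$status == "removed_dco"))
  expect_true(all(far$status == "kept"))
  peri_near <- filter_double_crossovers(
    make_events(c(150e6, 219e6), c("HET", "HOM_P1"), c("HOM_P1", "HET")), rg)
  peri_far <- filter_double_crossovers(
    make_events(c(150e6, 221e6), c("HET", "HOM_P1"), c("HOM_P1", "HET")), rg)
  expect_true(all(peri_near$status == "removed_dco"))
  expect_true(all(peri_far$status == "kept"))
})

test_that("triple-change edge case merges into one spanning event", {
  gl <- genome_layout("chr1", 400e6, 400e6, centromere = 200e6)
  rg <- classify_regions(gl, pericentric = data.frame(chrom = "chr1",
                                                      start = 100e6,
                                                      end = 300e6))
  # HOM_P1 | HET (3 Mb) | HOM_P2: flanks differ; pair replaced by one event
  ev <- make_events(c(10e6, 13e6), c("HOM_P1", "HET"), c("HET", "HOM_P2"))
  out <- filter_double_crossovers(ev, rg)
  kept <- out[out$status == "kept", ]
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$left, "HOM_P1")
  expect_equal(kept$right, "HOM_P2")
  expect_equal(kept$gametes, 2)
  expect_equal(sum(out$status == "removed_dco"), 2L)
})

test_that("the double-crossover filter is idempotent", {
  gl <- wt_layout(); rg <- wt_regions(); grid <- build_bin_grid(gl)
  pop <- simulate_f2_population(40, wt_landscape(), seed = 30)
  counts <- simulate_bin_counts(pop, grid, coverage_model(), rg, seed = 31)
  ev <- call_crossovers(genotype_bins(counts), grid, rg)
  once <- filter_double_crossovers(ev, rg)
  twice <- filter_double_crossovers(once, rg)
  o <- function(x) x[order(x$sample, x$mid, x$status), ]
  expect_equal(o(twice), o(once), ignore_attr = TRUE)
})

test_that("dosage changes telescope along every chromosome", {
  grid <- build_bin_grid(wt_layout())
  pop <- simulate_f2_population(30, wt_landscape(), seed = 32)
  counts <- simulate_bin_counts(pop, grid, coverage_model(), wt_regions(),
                                seed = 33)
  tracks <- genotype_bins(counts)
  ev <- call_crossovers(tracks, grid)
  dos <- c(HOM_P2 = 0, HET = 1, HOM_P1 = 2)
  for (s in unique(tracks$sample)) {
    tt <- tracks[tracks$sample == s, ]
    tt <- tt[order(tt$bin), ]
    calls <- tt$call[tt$call != "MISSING"]
    ee <- ev[ev$sample == s, ]
    expect_equal(sum(dos[ee$right] - dos[ee$left]),
                 unname(dos[calls[length(calls)]] - dos[calls[1]]))
  }
})

test_that("well-separated true crossovers are recovered without spurious calls", {
  gl <- wt_layout(); rg <- wt_regions(); grid <- build_bin_grid(gl)
  pop <- simulate_f2_population(100, wt_landscape(), seed = 34)
  cm <- coverage_model(mean_arm = 60, mean_pericentric = 60,
                       mean_subtel_left = 60, mean_subtel_right = 60,
                       epsilon = 0, p_artifact = 0)
  counts <- simulate_bin_counts(pop, grid, cm, rg, seed = 35)
  ev <- filter_double_crossovers(call_crossovers(genotype_bins(counts),
                                                 grid, rg), rg)
  kept <- ev[ev$status != "removed_dco", ]
  n_checked <- 0L
  for (ind in pop$individuals) {
    seg <- ind$chroms[["1A"]]$dosage
    bk <- seg$end[-nrow(seg)]
    # condition on separations the filter is designed to keep: >= 20 Mb
    # generally, >= 70 Mb when the intervening segment is pericentric
    if (length(bk) > 1) {
      sep <- diff(bk)
      midp <- (bk[-1] + bk[-length(bk)]) / 2
      if (min(sep) < 20e6) next
      if (any(midp > 150e6 & midp < 450e6 & sep < 70e6)) next
    }
    if (length(bk) > 0 && (min(bk) < 20e6 || max(bk) > 580e6)) next
    n_checked <- n_checked + 1L
    ee <- kept[kept$sample == ind$sample, ]
    expect_equal(nrow(ee), length(bk))  # no spurious, none missed
    if (length(bk) > 0) {
      hit <- vapply(bk, function(b) any(ee$start <= b & ee$end >= b), TRUE)
      expect_true(all(hit))             # bounding interval contains the truth
    }
  }
  expect_gt(n_checked, 50)
})

test_that("crossover counts sum gamete weights per sample and chromosome", {
  ev <- make_events(c(10e6, 50e6), c("HOM_P1", "HET"), c("HET", "HOM_P2"))
  cc <- count_crossovers(ev)
  expect_equal(cc$co_gametes, 2)   # 1 + 1
  expect_equal(cc$n_events, 2L)
  ev$status[2] <- "removed_dco"
  cc2 <- count_crossovers(ev)
  expect_equal(cc2$co_gametes, 1)
  cc3 <- count_crossovers(ev[0, ], samples = "s1", chroms = "chr1")
  expect_equal(cc3$co_gametes, 0)
})
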