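# The synthetic-data generator: geometry, sampling design, noise injection
# and end-to-end recovery.

test_that("synthetic maps reproduce the target geometry", {
  sc <- synth_scenario(seed = 41)
  map <- synth_marker_map(sc)
  expect_equal(nrow(map$markers), 277)
  gaps <- diff(map$markers$position)
  expect_gt(median(gaps), 3500)   # ~4.4 kb median against ~5.4 kb mean
  expect_lt(median(gaps), 5300)
  expect_gt(mean(gaps), median(gaps))  # right-skewed spacing

  # zero jitter gives (near-)equal spacing
  sc0 <- small_scenario(seed = 2, gap_sdlog = 0)
  gaps0 <- diff(synth_marker_map(sc0)$markers$position)
  expect_lte(diff(range(gaps0)), 2)

  # determinism
  expect_identical(synth_marker_map(sc)$markers, synth_marker_map(sc)$markers)
})

test_that("synthetic genomes hit the target GC and accept planted motifs", {
  sc <- small_scenario(seed = 3)
  g <- synth_genome(sc)
  gcf <- sum(strsplit(g$sequence, "")[[1]] %in% c("G", "C")) /
    nchar(g$sequence)
  expect_equal(gcf, 0.36, tolerance = 0.01)

  # planted motif density is recovered by the counter
  win <- matrix(c(1e6 + 1000, 1e6 + 11000), 1)
  scp <- small_scenario(seed = 3, planted = list(
    list(motif = "AACAAC", windows = win, per_kb = 3)))
  gp <- synth_genome(scp)
  hot_seq <- substr(gp$sequence, 1001, 11000)
  expect_gte(count_nonoverlapping(hot_seq, "AACAAC"), 30)
  cold_seq <- substr(gp$sequence, 100001, 110000)
  expect_lt(count_nonoverlapping(cold_seq, "AACAAC"), 15)

  # infeasible density errors out
  expect_error(synth_genome(small_scenario(seed = 3, planted = list(
    list(motif = "AACAAC", windows = win, per_kb = 200)))), "infeasible")
})

test_that("panel totals reproduce the two-cross sampling skew exactly", {
  sc <- small_scenario(seed = 4)
  map <- synth_marker_map(sc)
  pan <- synth_panel(sc, map)
  tab <- tabulate_crossovers(call_breakpoints(pan$panel, map)$crossovers, map)
  expect_equal(unname(side_cross_totals(tab)),
               matrix(c(80, 50, 50, 50), 2, byrow = TRUE))
})

test_that("zero-noise panels round-trip through breakpoint calling", {
  sc <- small_scenario(seed = 5)
  map <- synth_marker_map(sc)
  pan <- synth_panel(sc, map)
  res <- call_breakpoints(pan$panel, map)
  expect_equal(res$qc$n_retained, nrow(pan$truth))
  got <- res$crossovers[match(pan$truth$strain_id,
                              res$crossovers$strain_id), ]
  expect_equal(got$left_bound, pan$truth$interval_start)
  expect_equal(got$right_bound, pan$truth$interval_end)
})

test_that("injected double recombinants are exactly the QC exclusions", {
  sc <- small_scenario(seed = 6, double_recomb_rate = 0.1)
  map <- synth_marker_map(sc)
  pan <- synth_panel(sc, map)
  res <- call_breakpoints(pan$panel, map)
  injected <- pan$truth$strain_id[pan$truth$double_recombinant]
  expect_gt(length(injected), 5)
  flagged <- res$qc$excluded$strain_id[
    res$qc$excluded$reason == "double_recombinant"]
  expect_setequal(flagged, injected)
})

test_that("injected heterozygous runs are excluded as het stretches", {
  sc <- small_scenario(seed = 7, het_rate = 0.15)
  map <- synth_marker_map(sc)
  pan <- synth_panel(sc, map)
  res <- call_breakpoints(pan$panel, map)
  injected <- pan$truth$strain_id[pan$truth$het_injected &
                                    !pan$truth$double_recombinant]
  flagged <- res$qc$excluded$strain_id[res$qc$excluded$reason == "het_stretch"]
  expect_true(all(injected %in% flagged))
})

test_that("end-to-end: binned rates match the generating landscape", {
  sc <- synth_scenario(seed = 8, span = c(1e6, 1.3e6), n_markers = 31,
                       totals = matrix(c(400, 400, 400, 400), 2, byrow = TRUE,
                                       dimnames = list(c("FaxNIL", "LonNIL"),
                                                       c("left", "right"))),
                       landscape = list(kind = "uniform"),
                       missing_rate = 0, het_rate = 0, double_recomb_rate = 0)
  map <- synth_marker_map(sc)
  pan <- synth_panel(sc, map)
  tab <- tabulate_crossovers(call_breakpoints(pan$panel, map)$crossovers, map)
  for (sd in c("left", "right")) {
    sub <- nilscape:::.unmasked(tab, sd)
    cnt <- sub$count_faxnil + sub$count_lonnil
    chi <- suppressWarnings(
      chisq.test(cnt, p = sub$length / sum(sub$length)))
    expect_gt(chi$p.value, 0.01)
  }
})

test_that("gamma panels are more heterogeneous than uniform panels", {
  wins <- 0
  for (r in 1:10) {
    scu <- small_scenario(seed = 100 + r, landscape = list(kind = "uniform"))
    scg <- small_scenario(seed = 100 + r,
                          landscape = list(kind = "gamma", shape_left = 1.7,
                                           shape_right = 1.7))
    map <- synth_marker_map(scu)
    gu <- lorenz_gini(tabulate_crossovers(
      call_breakpoints(synth_panel(scu, map)$panel, map)$crossovers, map))$gini
    gg <- lorenz_gini(tabulate_crossovers(
      call_breakpoints(synth_panel(scg, map)$panel, map)$crossovers, map))$gini
    wins <- wins + (gg > gu)
  }
  expect_gte(wins, 9)
})

test_that("fixture writer emits readable files with a truth record", {
  outdir <- withr::local_tempdir()
  sc <- small_scenario(seed = 9)
  obj <- synth_write_fixtures(sc, outdir)
  expect_true(all(file.exists(file.path(outdir,
    c("map.tsv", "panel.tsv", "region.fa", "truth.json")))))
  map2 <- read_marker_map(file.path(outdir, "map.tsv"),
                          indel_position = obj$map$indel_position)
  expect_equal(map2$markers, obj$map$markers)
  pan2 <- read_genotypes(file.path(outdir, "panel.tsv"), map2)
  expect_equal(pan2$calls, obj$panel$calls, ignore_attr = TRUE)
  fa <- read_region_fasta(file.path(outdir, "region.fa"))
  expect_equal(fa$seq_start, sc$span[1])
  expect_equal(nchar(fa$sequence), nchar(obj$genome$sequence))
  truth <- jsonlite::read_json(file.path(outdir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth), nrow(obj$truth))
})
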