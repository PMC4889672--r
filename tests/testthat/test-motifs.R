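# dsDNA motif catalogs, greedy non-overlapping counting, repeat features,
# degenerate motifs and the scan/permutation machinery.

test_that("canonical catalogs have the combinatorial sizes", {
  # 4^k/2 + (even k) 4^(k/2)/2
  expect_length(enumerate_motifs(4)$motifs, 136)
  expect_length(enumerate_motifs(5)$motifs, 512)
  expect_length(enumerate_motifs(6)$motifs, 2080)
  cat4 <- enumerate_motifs(4)$motifs
  # no two entries are reverse complements; palindromes appear once
  rc <- nilscape:::.revcomp(cat4)
  expect_true(all(cat4 <= rc))
  expect_equal(anyDuplicated(cat4), 0)
  expect_error(enumerate_motifs(0, strict = FALSE), "at least 1")
  expect_error(enumerate_motifs(3), "4..8")
})

test_that("reverse complements collapse to one catalog entry", {
  cm <- nilscape:::.canon_map(4)
  expect_equal(unname(cm$names[cm$ids[match("TGTT",
    do.call(paste0, lapply(1:4, function(j)
      c("A","C","G","T")[((0:255 %/% 4^(4-j)) %% 4) + 1])))]]), "AACA")
  expect_equal(count_nonoverlapping("TGTT", "AACA"), 1)
})

test_that("greedy non-overlapping counting follows the hand traces", {
  expect_equal(count_nonoverlapping("AAAA", "AA"), 2)
  expect_equal(count_nonoverlapping("AACAACA", "AACA"), 1)
  expect_equal(count_nonoverlapping("", "AACA"), 0)
  expect_equal(count_nonoverlapping("AANAA", "AA"), 2)  # N never matches
  expect_equal(count_nonoverlapping("ACGT", "ACGT"), 1) # palindrome once
})

test_that("catalog counting agrees with the single-motif counter", {
  set.seed(23)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 4000, TRUE,
                    prob = c(0.32, 0.18, 0.18, 0.32, 0.002)), collapse = "")
  for (k in c(4, 5)) {
    cc <- nilscape:::.catalog_counts(s, enumerate_motifs(k))
    pick <- sample(names(cc), 40)
    ind <- vapply(pick, function(m) count_nonoverlapping(s, m), integer(1))
    expect_equal(unname(cc[pick]), unname(ind))
    # per-motif occupancy bound: a motif's non-overlapping occurrences
    # cannot cover more bases than the sequence has
    expect_lte(max(cc) * k, nchar(s))
  }
})

test_that("counting is strand-symmetric", {
  set.seed(24)
  s <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  s_rc <- nilscape:::.revcomp(s)
  for (k in c(4, 6)) {
    expect_equal(nilscape:::.catalog_counts(s, enumerate_motifs(k)),
                 nilscape:::.catalog_counts(s_rc, enumerate_motifs(k)))
  }
})

test_that("repeat-feature runs are counted once per maximal run", {
  expect_equal(count_repeat_features("AAATAAAAC", "polyA", 4), 1)
  expect_equal(count_repeat_features("TTTTT", "polyA", 4), 1)
  expect_equal(count_repeat_features("CACACACACA", "CA", 5), 1)
  expect_equal(count_repeat_features("AAAA", "polyA", 5), 0)
  expect_equal(count_repeat_features("AAAAGTTTT", "polyA", 4), 2)
  expect_equal(count_repeat_features("CACACAGTGTGTG", "CA", 3), 2)
  expect_error(count_repeat_features("AAAA", "polyA", 1), "at least 2")
})

test_that("degenerate motifs match IUPAC codes on both strands", {
  expect_equal(count_degenerate_motif("AAAAAATTATAT",
                                      "AAAA[AT]AT[TC]AT[AT]T"), 1)
  # reverse complement of the instance also matches
  expect_equal(count_degenerate_motif(
    nilscape:::.revcomp("AAAAAATTATAT"), "AAAA[AT]AT[TC]AT[AT]T"), 1)
  # plain patterns reduce to count_nonoverlapping
  set.seed(25)
  s <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  expect_equal(count_degenerate_motif(s, "AACA"),
               count_nonoverlapping(s, "AACA"))
  # IUPAC letters
  expect_equal(count_degenerate_motif("AGGA", "ARRA"), 1)
  expect_equal(count_degenerate_motif("", "ARRA"), 0)
  expect_error(count_degenerate_motif("ACGT", "AXGT"), "invalid IUPAC")
})

test_that("interval shuffles preserve per-interval base composition", {
  set.seed(26)
  ints <- lapply(1:5, function(i) sample(1:4, 300, TRUE))
  set.seed(99)
  sh <- nilscape:::.permute_interval_ints(ints)
  for (i in 1:5) {
    expect_equal(sort(sh[[i]]), sort(ints[[i]]))
    expect_false(identical(sh[[i]], ints[[i]]))
  }
})

test_that("a planted motif effect ranks first in the scan", {
  set.seed(27)
  n_iv <- 24
  len <- rep(1500, n_iv)
  side <- rep(c("left", "right"), each = n_iv / 2)
  seqs <- vapply(seq_len(n_iv), function(i)
    paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = ""),
    character(1))
  motif <- "GACGTC"  # plant extra copies in half the intervals
  hot <- seq_len(n_iv) %% 2 == 0
  for (i in which(hot)) {
    at <- seq(20, 1400, by = 100)
    for (a in at) substr(seqs[i], a, a + 5) <- motif
  }
  dens <- vapply(seqs, count_nonoverlapping, integer(1), motif = motif) / len
  counts <- rpois(n_iv, exp(log(len) - 6 + 250 * dens))
  tab <- toy_table(counts, len, side = side)
  seq_all <- paste(seqs, collapse = "")
  scan <- scan_motifs(tab, seq_all, seq_start = tab$start[1], k_range = 6)
  best <- scan$motif[which.min(scan$residual_deviance)]
  expect_equal(best, "GACGTC")
  expect_equal(scan$effect_direction[scan$motif == "GACGTC"], "+")
  # a motif absent everywhere is flagged degenerate with 0% explained
  absent <- scan[scan$degenerate, ]
  if (nrow(absent)) expect_true(all(absent$deviance_explained == 0))
})

test_that("motif pairs: nesting, collinear duplicates, budget guard", {
  set.seed(28)
  n_iv <- 16
  len <- rep(1200, n_iv)
  side <- rep(c("left", "right"), each = 8)
  seqs <- vapply(seq_len(n_iv), function(i)
    paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = ""),
    character(1))
  counts <- rpois(n_iv, len * 0.004)
  tab <- toy_table(counts, len, side = side)
  seq_all <- paste(seqs, collapse = "")
  res <- scan_motif_pairs(tab, seq_all, c("AACA", "GGAT", "AACA"),
                          seq_start = tab$start[1])
  dup <- res[res$motif1 == "AACA" & res$motif2 == "AACA", ]
  expect_true(all(dup$collinear))
  single <- scan_motifs(tab, seq_all, seq_start = tab$start[1], k_range = 4)
  expect_equal(dup$residual_deviance[1],
               single$residual_deviance[single$motif == "AACA"],
               tolerance = 1e-6)
  # joint fit explains at least as much as each marginal
  pair <- res[res$motif1 == "AACA" & res$motif2 == "GGAT", ]
  expect_gte(pair$deviance_explained + 1e-8,
             max(single$deviance_explained[single$motif %in% c("AACA", "GGAT")]))
  expect_error(scan_motif_pairs(tab, seq_all, enumerate_motifs(4)$motifs,
                                seq_start = tab$start[1], max_pairs = 10),
               "budget")
})

test_that("permutation null is deterministic and reports a selection effect", {
  set.seed(29)
  n_iv <- 12
  len <- rep(800, n_iv)
  seqs <- vapply(seq_len(n_iv), function(i)
    paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = ""),
    character(1))
  counts <- rpois(n_iv, len * 0.005)
  tab <- toy_table(counts, len, side = rep(c("left", "right"), each = 6))
  seq_all <- paste(seqs, collapse = "")
  pn1 <- permutation_null(tab, seq_all, seq_start = tab$start[1],
                          k_range = 4, n_perm = 99, seed = 5)
  pn2 <- permutation_null(tab, seq_all, seq_start = tab$start[1],
                          k_range = 4, n_perm = 99, seed = 5)
  expect_identical(pn1$min_resid_dev, pn2$min_resid_dev)
  # even under the null the best motif explains some deviance
  expect_gt(mean(pn1$max_dev_explained[, "k4"]), 0)
  scan <- scan_motifs(tab, seq_all, seq_start = tab$start[1], k_range = 4)
  rep <- motif_test_report(scan, pn1)
  expect_true(all(rep$permutation_p > 0 & rep$permutation_p <= 1))
  expect_equal(rep$additional_deviance_explained,
               rep$deviance_explained - rep$expected_deviance_explained)
})
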