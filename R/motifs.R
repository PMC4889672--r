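# Exhaustive double-strand k-mer association scan.
#
# A dsDNA motif is a k-mer identified with its reverse complement; the
# canonical representative is the lexicographic minimum of the pair.
# Occurrences are counted greedily left-to-right on both strands in one
# pass: at each position a match of the motif or its reverse complement
# consumes k bases, so later overlapping matches are skipped. N never
# matches.

#' Enumerate the canonical double-strand k-mer catalog
#'
#' @param k Motif length (default bounds 4..8; any k >= 1 is accepted via
#'   `strict = FALSE`).
#' @param strict Enforce the 4..8 bp scan bounds.
#' @return An object of class `motif_catalog`: list with `k` and `motifs`
#'   (sorted canonical k-mers; palindromes appear once).
#' @examples
#' length(enumerate_motifs(4)$motifs)  # 136
#' @export
enumerate_motifs <- function(k, strict = TRUE) {
  .assert(k >= 1, "k must be at least 1")
  if (strict) .assert(k >= 4 && k <= 8, "k must be in 4..8 (use strict = FALSE to override)")
  kmers <- do.call(paste0, rev(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                           stringsAsFactors = FALSE)))
  canon <- pmin(kmers, .revcomp_fast(kmers, k))
  structure(list(k = k, motifs = sort(unique(canon))),
            class = "motif_catalog")
}

# Vectorized reverse complement for equal-length plain ACGT k-mers.
.revcomp_fast <- function(x, k) {
  m <- matrix(unlist(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)),
              nrow = k)
  do.call(paste0, lapply(rev(seq_len(k)), function(i) m[i, ]))
}

#' @export
print.motif_catalog <- function(x, ...) {
  cat(sprintf("motif_catalog: %d canonical %d-mers\n", length(x$motifs), x$k))
  invisible(x)
}

#' Count non-overlapping double-strand occurrences of a motif
#'
#' Greedy left-to-right single pass: a match of the motif or its reverse
#' complement consumes `k` bases.
#'
#' @param sequence DNA string over `A/C/G/T/N`.
#' @param motif The k-mer (any representative; its reverse complement is
#'   matched too).
#' @return Integer count.
#' @examples
#' count_nonoverlapping("AACAACA", "AACA")  # 1
#' count_nonoverlapping("AAAA", "AA")       # 2
#' @export
count_nonoverlapping <- function(sequence, motif) {
  if (nchar(sequence) == 0) return(0L)
  k <- nchar(motif)
  rc <- .revcomp(motif)
  pats <- unique(c(motif, rc))
  pos <- sort(unique(unlist(lapply(pats, function(p) .all_positions(sequence, p)))))
  .greedy_count(pos, k)
}

# Per-motif greedy non-overlapping counts for a whole canonical catalog in
# one rolling-code pass over the sequence. Returns a named integer vector
# over catalog$motifs (sorted canonical order).
.catalog_counts <- function(sequence, catalog) {
  .counts_from_ints(.seq_ints(sequence), catalog$k)
}

# One GC-preserving permutation: shuffle each interval's bases within the
# interval, leaving the per-interval base composition exactly unchanged.
.permute_interval_ints <- function(ints) lapply(ints, sample)

# DNA string -> integer codes 1..4 (NA for N or other letters).
.seq_ints <- function(sequence) {
  match(strsplit(sequence, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
}

# Greedy catalog counts from integer-coded sequence: windows are 4-ary
# rolling codes, mapped to canonical-group ids by a cached lookup; windows
# containing N drop out as NA.
.counts_from_ints <- function(ints, k) {
  cache <- .canon_map(k)
  out <- stats::setNames(integer(length(cache$names)), cache$names)
  L <- length(ints)
  if (L < k) return(out)
  v <- ints - 1L
  code <- v[seq_len(L - k + 1)]
  for (j in 2:k) code <- code * 4L + v[j:(L - k + j)]
  keep <- which(!is.na(code))
  if (length(keep) == 0) return(out)
  cid <- cache$ids[code[keep] + 1L]
  by_motif <- split(keep, cid)
  cnt <- vapply(by_motif, .greedy_count, integer(1), k = k)
  out[as.integer(names(cnt))] <- cnt
  out
}

# Cached canonical lookup for all 4^k codes: `ids` maps code+1 to the index
# of its canonical motif in the sorted catalog `names`.
.canon_cache <- new.env(parent = emptyenv())
.canon_map <- function(k) {
  key <- as.character(k)
  if (!is.null(.canon_cache[[key]])) return(.canon_cache[[key]])
  codes <- 0:(4^k - 1)
  bases <- c("A", "C", "G", "T")
  kmers <- do.call(paste0, lapply(seq_len(k), function(j) {
    bases[((codes %/% 4^(k - j)) %% 4) + 1]
  }))
  canon <- pmin(kmers, .revcomp_fast(kmers, k))
  nms <- sort(unique(canon))
  mp <- list(ids = match(canon, nms), names = nms)
  .canon_cache[[key]] <- mp
  mp
}

#' Count runs of simple repeats on either strand
#'
#' `polyA`: maximal runs of at least `n` consecutive `A` (or `T`, the
#' reverse strand). `CA`: maximal perfect `(CA)` (or `(TG)`) dinucleotide
#' repeats of at least `n` units. Each maximal run counts once.
#'
#' @param sequence DNA string.
#' @param feature `"polyA"` or `"CA"`.
#' @param n Minimum run length (bases for polyA, units for CA); `n >= 2`.
#' @return Integer count.
#' @examples
#' count_repeat_features("AAATAAAAC", "polyA", 4)  # 1
#' count_repeat_features("CACACACACA", "CA", 5)    # 1
#' @export
count_repeat_features <- function(sequence, feature = c("polyA", "CA"), n) {
  feature <- match.arg(feature)
  .assert(n >= 2, "threshold n must be at least 2")
  pats <- if (feature == "polyA") {
    c(sprintf("A{%d,}", n), sprintf("T{%d,}", n))
  } else {
    c(sprintf("(?:CA){%d,}", n), sprintf("(?:TG){%d,}", n))
  }
  sum(vapply(pats, function(p) {
    hits <- gregexpr(p, sequence, perl = TRUE)[[1]]
    if (hits[1] == -1L) 0L else length(hits)
  }, integer(1)))
}

#' Count non-overlapping occurrences of a degenerate (IUPAC) motif
#'
#' The pattern may use IUPAC ambiguity codes and/or explicit bracket
#' classes like `AAAA[AT]AT[TC]AT[AT]T`. Both the pattern and its reverse
#' complement are matched; `N` in the sequence never matches.
#'
#' @param sequence DNA string.
#' @param pattern Degenerate motif.
#' @return Integer count.
#' @export
count_degenerate_motif <- function(sequence, pattern) {
  if (nchar(sequence) == 0) return(0L)
  toks <- .parse_iupac(pattern)
  k <- length(toks)
  fwd <- paste(vapply(toks, .class_regex, character(1)), collapse = "")
  rev_toks <- rev(lapply(toks, .complement_set))
  rc <- paste(vapply(rev_toks, .class_regex, character(1)), collapse = "")
  pos <- sort(unique(c(.all_positions(sequence, fwd),
                       .all_positions(sequence, rc))))
  .greedy_count(pos, k)
}

.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# Tokenize an IUPAC/bracket pattern into a list of base sets.
.parse_iupac <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  toks <- list()
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1
      set <- character(0)
      while (j <= length(chars) && chars[j] != "]") {
        .assert(chars[j] %in% names(.iupac_sets), "invalid IUPAC code '%s'", chars[j])
        set <- union(set, .iupac_sets[[chars[j]]])
        j <- j + 1
      }
      .assert(j <= length(chars), "unterminated '[' in pattern")
      toks[[length(toks) + 1]] <- sort(set)
      i <- j + 1
    } else {
      .assert(ch %in% names(.iupac_sets), "invalid IUPAC code '%s'", ch)
      toks[[length(toks) + 1]] <- .iupac_sets[[ch]]
      i <- i + 1
    }
  }
  toks
}

.class_regex <- function(set) {
  if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
}

.complement_set <- function(set) {
  sort(chartr("ACGT", "TGCA", set))
}

#' Scan all motifs of given lengths against crossover counts
#'
#' For every canonical k-mer the per-interval occurrence density
#' (non-overlapping count / interval length) enters an offset+side Poisson
#' model as a covariate. Reported per motif: effect direction, residual
#' deviance, percent deviance explained over the offset+side base model,
#' and the nominal 1-df chi-square p-value.
#'
#' @param table A `crossover_table`.
#' @param sequence DNA string covering the shared span.
#' @param seq_start Physical coordinate of the first base of `sequence`.
#' @param k_range Motif lengths to scan (default 4:6).
#' @return A data.frame of class `motif_scan` with one row per motif,
#'   carrying the per-interval density matrix and model skeleton as
#'   attributes for permutation control.
#' @export
scan_motifs <- function(table, sequence, seq_start = attr(table, "shared_span")[1],
                        k_range = 4:6) {
  sub <- .unmasked(table)
  seqs <- .interval_seqs(sequence, seq_start, sub)
  counts <- sub$count_faxnil + sub$count_lonnil
  base <- fit_poisson(counts, sub$length, sub$side)
  res <- list()
  for (k in k_range) {
    catalog <- enumerate_motifs(k, strict = FALSE)
    mat <- t(vapply(seqs, .catalog_counts, integer(length(catalog$motifs)),
                    catalog = catalog))
    res[[as.character(k)]] <- .scan_density_matrix(
      mat, counts, sub$length, sub$side, base, k)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("motif_scan", "data.frame"),
            skeleton = sub, base_deviance = base$residual_deviance,
            k_range = k_range)
}

# Fit every column of a count matrix as a density covariate; shared base
# fit. Uses the internal IRLS fast path (agrees with fit_poisson to
# convergence tolerance; the scan refits thousands of models).
.scan_density_matrix <- function(mat, counts, lengths, side, base, k) {
  dens <- mat / lengths
  n_motif <- ncol(mat)
  side_ind <- if (is.numeric(side)) side else as.numeric(factor(side)) - 1
  X0 <- cbind(1, side_ind)
  if (length(unique(side_ind)) == 1) X0 <- X0[, 1, drop = FALSE]
  off <- log(lengths)
  coef <- numeric(n_motif); rdev <- numeric(n_motif)
  dexp <- numeric(n_motif); pval <- numeric(n_motif)
  degen <- logical(n_motif)
  for (m in seq_len(n_motif)) {
    d <- dens[, m]
    if (stats::sd(d) == 0) {
      degen[m] <- TRUE
      coef[m] <- 0; rdev[m] <- base$residual_deviance; dexp[m] <- 0; pval[m] <- 1
      next
    }
    fit <- .fast_poisson(cbind(X0, d), counts, off)
    coef[m] <- fit$coefficients[ncol(X0) + 1]
    rdev[m] <- fit$deviance
    dexp[m] <- 100 * max(0, base$residual_deviance - fit$deviance) /
      base$residual_deviance
    pval[m] <- stats::pchisq(max(0, base$residual_deviance - fit$deviance),
                             df = 1, lower.tail = FALSE)
  }
  data.frame(motif = colnames(mat), k = k,
             effect_direction = ifelse(degen, NA, ifelse(coef >= 0, "+", "-")),
             coefficient = coef, residual_deviance = rdev,
             deviance_explained = dexp, nominal_p = pval,
             degenerate = degen, stringsAsFactors = FALSE)
}

# Substring per-interval sequences (1-based half-open intervals).
.interval_seqs <- function(sequence, seq_start, sub) {
  from <- sub$start - seq_start + 1
  to <- sub$end - seq_start
  .assert(all(from >= 1) && all(to <= nchar(sequence)),
          "sequence does not cover every unmasked interval")
  substring(sequence, from, to)
}

#' GC-preserving sequence-permutation null for the motif scan
#'
#' Each permutation independently shuffles the nucleotides within every
#' unmasked interval, preserving each interval's exact base composition
#' (hence GC content). All motifs are recounted and refitted; the minimum
#' residual deviance (equivalently the maximum deviance explained) across
#' motifs of each length class is stored, so permutation p-values control
#' the family-wise error within a length class.
#'
#' @param table A `crossover_table`.
#' @param sequence DNA string covering the shared span.
#' @param seq_start Physical coordinate of the first base of `sequence`.
#' @param k_range Motif lengths.
#' @param n_perm Number of sequence permutations (>= 99).
#' @param seed Integer seed.
#' @return An object of class `permutation_null`: list with `min_resid_dev`
#'   and `max_dev_explained` (`n_perm` x length-class matrices), `n_perm`,
#'   `seed`, `k_range`.
#' @export
permutation_null <- function(table, sequence,
                             seq_start = attr(table, "shared_span")[1],
                             k_range = 4:6, n_perm = 1000, seed = 1) {
  .assert(n_perm >= 99, "n_perm must be at least 99")
  sub <- .unmasked(table)
  seqs <- .interval_seqs(sequence, seq_start, sub)
  ints <- lapply(seqs, .seq_ints)
  counts <- sub$count_faxnil + sub$count_lonnil
  base <- fit_poisson(counts, sub$length, sub$side)
  n_motifs <- vapply(k_range, function(k) length(.canon_map(k)$names),
                     integer(1))
  min_dev <- matrix(NA_real_, n_perm, length(k_range),
                    dimnames = list(NULL, paste0("k", k_range)))
  max_exp <- min_dev
  set.seed(seed)
  for (p in seq_len(n_perm)) {
    shuffled <- .permute_interval_ints(ints)
    for (ki in seq_along(k_range)) {
      mat <- t(vapply(shuffled, .counts_from_ints,
                      integer(n_motifs[ki]), k = k_range[ki]))
      scan <- .scan_density_matrix(mat, counts, sub$length, sub$side, base,
                                   k_range[ki])
      min_dev[p, ki] <- min(scan$residual_deviance)
      max_exp[p, ki] <- max(scan$deviance_explained)
    }
  }
  structure(list(min_resid_dev = min_dev, max_dev_explained = max_exp,
                 n_perm = n_perm, seed = seed, k_range = k_range),
            class = "permutation_null")
}

#' Combine a motif scan with its permutation null
#'
#' Per motif: the permutation p-value is the add-one fraction of
#' permutations whose length-class minimum residual deviance is at most the
#' motif's observed residual deviance; the additional deviance explained is
#' the observed percent minus the permutation-expected best-motif percent
#' for the class (the selection-effect baseline).
#'
#' @param scan A `motif_scan`.
#' @param null A matching `permutation_null`.
#' @return The scan data.frame with columns `expected_deviance_explained`,
#'   `additional_deviance_explained` and `permutation_p` appended.
#' @export
motif_test_report <- function(scan, null) {
  .assert(all(unique(scan$k) %in% null$k_range),
          "permutation null lacks some motif length classes")
  scan$expected_deviance_explained <- NA_real_
  scan$additional_deviance_explained <- NA_real_
  scan$permutation_p <- NA_real_
  for (k in unique(scan$k)) {
    ki <- match(k, null$k_range)
    rows <- scan$k == k
    exp_best <- mean(null$max_dev_explained[, ki])
    scan$expected_deviance_explained[rows] <- exp_best
    scan$additional_deviance_explained[rows] <-
      scan$deviance_explained[rows] - exp_best
    scan$permutation_p[rows] <- vapply(scan$residual_deviance[rows],
                                       function(rd) {
                                         .mc_pvalue(null$min_resid_dev[, ki], rd, "lower")
                                       }, numeric(1))
  }
  scan
}

#' Joint scan of motif pairs
#'
#' Fits two occurrence-density covariates jointly for every pair from a
#' motif subset. A pair of identical motifs collapses to the single-motif
#' fit and is flagged collinear.
#'
#' @param table A `crossover_table`.
#' @param sequence DNA string covering the shared span.
#' @param motifs Character vector of motifs to pair (the subset bounds the
#'   search space).
#' @param seq_start Physical coordinate of the first base of `sequence`.
#' @param max_pairs Budget guard: error before computing if exceeded.
#' @return data.frame with one row per pair: coefficients, joint residual
#'   deviance and percent deviance explained, nominal 2-df p, collinearity
#'   flag.
#' @export
scan_motif_pairs <- function(table, sequence, motifs,
                             seq_start = attr(table, "shared_span")[1],
                             max_pairs = 5000) {
  n_pairs <- length(motifs) * (length(motifs) + 1) / 2
  .assert(n_pairs <= max_pairs,
          "%d pairs exceed the configured budget of %d", n_pairs, max_pairs)
  sub <- .unmasked(table)
  seqs <- .interval_seqs(sequence, seq_start, sub)
  counts <- sub$count_faxnil + sub$count_lonnil
  base <- fit_poisson(counts, sub$length, sub$side)
  dens <- vapply(motifs, function(m) {
    vapply(seqs, count_nonoverlapping, integer(1), motif = m) / sub$length
  }, numeric(nrow(sub)))
  rows <- list()
  for (i in seq_along(motifs)) for (j in i:length(motifs)) {
    collinear <- motifs[i] == motifs[j] ||
      isTRUE(all.equal(dens[, i], dens[, j]))
    covs <- if (collinear) cbind(d1 = dens[, i]) else
      cbind(d1 = dens[, i], d2 = dens[, j])
    if (all(apply(covs, 2, stats::sd) > 0)) {
      fit <- fit_poisson(counts, sub$length, sub$side, covariates = covs,
                         base_deviance = base$residual_deviance)
      drop_dev <- max(0, base$residual_deviance - fit$residual_deviance)
      rows[[length(rows) + 1]] <- data.frame(
        motif1 = motifs[i], motif2 = motifs[j],
        coef1 = unname(fit$coefficients["d1"]),
        coef2 = if (collinear) NA_real_ else unname(fit$coefficients["d2"]),
        residual_deviance = fit$residual_deviance,
        deviance_explained = deviance_explained(fit),
        nominal_p = stats::pchisq(drop_dev, df = if (collinear) 1 else 2,
                                  lower.tail = FALSE),
        collinear = collinear, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
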