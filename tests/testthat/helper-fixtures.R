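# Shared in-code fixtures for the test suite.

# A crossover table built directly from count/length vectors (one side by
# default), bypassing genotype calling.
toy_table <- function(count_faxnil, lengths, count_lonnil = 0,
                      side = "left", start0 = 0, masked = FALSE,
                      resolution = "full") {
  n <- length(count_faxnil)
  lengths <- rep_len(lengths, n)
  count_lonnil <- rep_len(count_lonnil, n)
  side <- rep_len(side, n)
  masked <- rep_len(masked, n)
  ends <- start0 + cumsum(lengths)
  starts <- c(start0, ends[-n]) + 1
  crossover_table(
    data.frame(start = starts, end = ends + 1, side = side,
               length = lengths, count_faxnil = count_faxnil,
               count_lonnil = count_lonnil, masked = masked),
    resolution = resolution)
}

# A two-sided table with the indel between the sides.
two_side_table <- function(fax_left, fax_right, lon_left, lon_right,
                           len = 1000) {
  n_l <- length(fax_left); n_r <- length(fax_right)
  ends_l <- cumsum(rep(len, n_l)); ends_r <- max(ends_l) + cumsum(rep(len, n_r))
  df <- data.frame(
    start = c(c(0, ends_l[-n_l]), c(max(ends_l), ends_r[-n_r])) + 1,
    end = c(ends_l, ends_r) + 1,
    side = rep(c("left", "right"), c(n_l, n_r)),
    length = len,
    count_faxnil = c(fax_left, fax_right),
    count_lonnil = c(lon_left, lon_right), masked = FALSE)
  crossover_table(df, resolution = "full",
                  indel_position = max(ends_l) + 0.5)
}

# Small study-like scenario for quick end-to-end runs (noise off unless
# overridden).
small_scenario <- function(seed = 1, missing_rate = 0, het_rate = 0,
                           double_recomb_rate = 0, ...) {
  synth_scenario(
    seed = seed, span = c(1e6, 1.24e6), n_markers = 49,
    totals = matrix(c(80, 50, 50, 50), 2, byrow = TRUE,
                    dimnames = list(c("FaxNIL", "LonNIL"),
                                    c("left", "right"))),
    missing_rate = missing_rate, het_rate = het_rate,
    double_recomb_rate = double_recomb_rate, ...)
}

# Independent segmentation oracle: exhaustive enumeration over all knot
# subsets, scoring each candidate segmentation with dpois directly.
brute_force_loglik <- function(cnt, len, K) {
  n <- length(cnt)
  seg_ll <- function(idx) {
    C <- sum(cnt[idx]); L <- sum(len[idx])
    rate <- C / L
    sum(dpois(cnt[idx], rate * len[idx], log = TRUE))
  }
  best <- -Inf
  cuts <- if (K == 1) list(integer(0)) else
    asplit(utils::combn(n - 1, K - 1), 2)
  for (cut in cuts) {
    starts <- c(1, cut + 1)
    ends <- c(cut, n)
    ll <- sum(vapply(seq_len(K), function(k) seg_ll(starts[k]:ends[k]),
                     numeric(1)))
    best <- max(best, ll)
  }
  best
}

# Genotype panel from explicit call strings, e.g. "AAABBB".
panel_from_strings <- function(calls, map, cross = "FaxNIL") {
  mat <- do.call(rbind, strsplit(calls, "", fixed = TRUE))
  genotype_panel(sprintf("s%d", seq_along(calls)),
                 rep_len(cross, length(calls)), mat, map)
}
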