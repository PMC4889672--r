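#' Construct a per-bin rate landscape
#'
#' A landscape holds a per-bin crossover rate (crossovers/bp); within a bin
#' the rate is constant. Landscapes drive the panel simulators.
#'
#' @param rates Numeric vector of non-negative per-bp rates, one per bin.
#' @param span Numeric length-2 `(start, end)` physical span in bp.
#' @param bin_size Bin width in bp (default 1000).
#' @param kind `"uniform"`, `"gamma"` or `"hotspot"`.
#' @return An object of class `rate_landscape`.
#' @export
rate_landscape <- function(rates, span, bin_size = 1000,
                           kind = c("uniform", "gamma", "hotspot")) {
  kind <- match.arg(kind)
  .assert(all(is.finite(rates)) && all(rates >= 0),
          "rates must be finite and non-negative")
  n_exp <- ceiling((span[2] - span[1]) / bin_size)
  .assert(length(rates) == n_exp,
          "expected %d bins for span/bin_size, got %d", n_exp, length(rates))
  structure(list(rates = rates, span = as.numeric(span), bin_size = bin_size,
                 kind = kind),
            class = "rate_landscape")
}

#' @export
print.rate_landscape <- function(x, ...) {
  cat(sprintf("rate_landscape (%s): %d bins of %d bp over %.0f-%.0f, expected total %.1f\n",
              x$kind, length(x$rates), x$bin_size, x$span[1], x$span[2],
              sum(x$rates) * x$bin_size))
  invisible(x)
}

#' Draw a gamma-distributed rate landscape
#'
#' Per-bin rates are drawn i.i.d. from a gamma distribution with the given
#' shape and rescaled so the expected total number of crossovers over the
#' landscape equals `total_rate`. Small shapes give hotspot-like landscapes
#' (shape 1 is exponential); as the shape grows the landscape approaches
#' uniformity (the gamma coefficient of variation is `1/sqrt(shape)`).
#'
#' @param shape Gamma shape parameter (> 0). Values above `1e6` are capped.
#' @param n_bins Number of 1-kb bins.
#' @param total_rate Expected total crossovers over the landscape.
#' @param seed Integer seed.
#' @param bin_size Bin width in bp.
#' @param start Physical start coordinate of the landscape.
#' @return A `rate_landscape` of kind `"gamma"`.
#' @export
draw_gamma_landscape <- function(shape, n_bins, total_rate, seed = 1,
                                 bin_size = 1000, start = 1) {
  .assert(shape > 0, "gamma shape must be positive")
  .assert(n_bins >= 1, "need at least one bin")
  shape <- min(shape, 1e6)
  set.seed(seed)
  raw <- stats::rgamma(n_bins, shape = shape, rate = 1)
  rates <- raw / sum(raw * bin_size) * total_rate
  rate_landscape(rates, span = c(start, start + n_bins * bin_size),
                 bin_size = bin_size, kind = "gamma")
}

#' Simulate a crossover panel from a rate landscape
#'
#' Draws `n_crossovers` positions with density proportional to the landscape
#' (bin chosen proportionally to rate x bin width, position uniform within
#' the bin), then assigns each position to the inter-marker interval
#' containing it. Positions falling in the gap straddling the indel, or
#' outside the marker span, go to the nearest terminal interval so counts
#' are conserved.
#'
#' @param landscape A `rate_landscape` covering the map span.
#' @param map A `marker_map`.
#' @param n_crossovers Total crossovers to place.
#' @param seed Integer seed.
#' @param cross Which cross the counts are booked under.
#' @return A full-resolution `crossover_table`.
#' @export
simulate_panel <- function(landscape, map, n_crossovers, seed = 1,
                           cross = c("FaxNIL", "LonNIL")) {
  cross <- match.arg(cross)
  .assert(landscape$span[1] <= map$shared_span[1] &&
            landscape$span[2] >= map$shared_span[2],
          "landscape span does not cover the marker map")
  w <- landscape$rates * landscape$bin_size
  .assert(sum(w) > 0, "landscape has all-zero rates")
  set.seed(seed)
  # multinomial bin totals + uniform positions within bins (equivalent to
  # drawing each crossover's bin independently, and much faster)
  bin_cnt <- as.integer(stats::rmultinom(1, n_crossovers, w))
  pos <- landscape$span[1] +
    (rep(seq_along(w), bin_cnt) - 1) * landscape$bin_size +
    stats::runif(n_crossovers) * landscape$bin_size
  counts <- .assign_positions(pos, map)
  iv <- .marker_intervals(map)
  iv$count_faxnil <- if (cross == "FaxNIL") counts else 0L
  iv$count_lonnil <- if (cross == "LonNIL") counts else 0L
  iv$masked <- FALSE
  crossover_table(iv, resolution = "full", shared_span = map$shared_span,
                  indel_position = map$indel_position)
}

# Assign physical positions to within-side inter-marker intervals; indel-gap
# and out-of-span positions fall to the nearest terminal interval.
.assign_positions <- function(pos, map) {
  iv <- .marker_intervals(map)
  idx <- findInterval(pos, iv$start, rightmost.closed = FALSE)
  idx[idx < 1] <- 1L
  # findInterval over starts: a position in the indel gap or past an end maps
  # to the previous interval row unless it is beyond that row's end, in which
  # case it stays there (terminal-interval rule); positions past the last end
  # also clamp to the last row.
  idx[idx > nrow(iv)] <- nrow(iv)
  # positions in the indel gap but on the right of the indel -> first right interval
  first_right <- which(iv$side == "right")[1]
  last_left_end <- iv$end[first_right - 1]
  in_gap_right <- pos >= last_left_end & pos < iv$start[first_right] &
    pos >= map$indel_position
  idx[in_gap_right] <- first_right
  tabulate(idx, nbins = nrow(iv))
}

#' Distribution of the Gini coefficient under a gamma rate landscape
#'
#' For each simulation a fresh gamma landscape is drawn over the map span,
#' `n_crossovers` crossovers are placed, binned into the marker intervals,
#' and the Gini coefficient computed. Summarizes the mean and the
#' 2.5/50/97.5% quantiles.
#'
#' @param shape Gamma shape parameter.
#' @param map A `marker_map`.
#' @param n_crossovers Crossovers per simulated panel.
#' @param n_sims Number of simulations (>= 100).
#' @param seed Integer seed.
#' @param side Side selector for the Gini computation.
#' @param bin_size Landscape bin width in bp.
#' @return List with `mean`, `quantiles` (2.5/50/97.5%), `ginis`, `shape`.
#' @export
gini_envelope <- function(shape, map, n_crossovers, n_sims = 5000, seed = 1,
                          side = "both", bin_size = 1000) {
  .assert(n_sims >= 100, "n_sims must be at least 100")
  iv <- .marker_intervals(map)
  if (side != "both") iv <- iv[iv$side == side, , drop = FALSE]
  # the landscape covers exactly the span being scored, so no probability
  # mass is clamped onto terminal intervals from outside it
  span <- c(min(iv$start), max(iv$end))
  n_bins <- ceiling((span[2] - span[1]) / bin_size)
  shape <- min(shape, 1e6)
  set.seed(seed)
  ginis <- vapply(seq_len(n_sims), function(s) {
    raw <- stats::rgamma(n_bins, shape = shape, rate = 1)
    bin_cnt <- as.integer(stats::rmultinom(1, n_crossovers, raw))
    pos <- span[1] + (rep(seq_len(n_bins), bin_cnt) - 1) * bin_size +
      stats::runif(n_crossovers) * bin_size
    idx <- findInterval(pos, iv$start)
    idx[idx < 1] <- 1L
    idx[idx > nrow(iv)] <- nrow(iv)
    cnt <- tabulate(idx, nbins = nrow(iv))
    ord <- order(cnt / iv$length)
    phys <- c(0, cumsum(iv$length[ord]) / sum(iv$length))
    gen <- c(0, cumsum(cnt[ord]) / sum(cnt))
    1 - 2 * .trapz(phys, gen)
  }, numeric(1))
  list(mean = mean(ginis),
       quantiles = stats::quantile(ginis, c(0.025, 0.5, 0.975)),
       ginis = ginis, shape = shape)
}

#' Expected maximum per-bin rate as a multiple of the mean rate
#'
#' Monte-Carlo estimate of `E[max of n_bins i.i.d. gamma(shape) draws]`
#' divided by the distribution mean. Used to translate a fitted gamma shape
#' into a statement about the hottest kilobase of the landscape.
#'
#' @param shape Gamma shape parameter.
#' @param n_bins Number of bins (e.g. the side span in kb).
#' @param n_reps Monte-Carlo replicates (a warning below 100).
#' @param seed Integer seed.
#' @return The expected max/mean ratio (a scalar).
#' @examples
#' max_rate_multiple(1.70, 820, n_reps = 2000, seed = 1)
#' @export
max_rate_multiple <- function(shape, n_bins, n_reps = 10000, seed = 1) {
  .assert(shape > 0, "gamma shape must be positive")
  .assert(n_bins >= 1, "need at least one bin")
  if (n_reps < 100) warning("fewer than 100 replicates; estimate will be noisy")
  set.seed(seed)
  chunk <- max(1, floor(2e6 / n_bins))
  done <- 0
  acc <- 0
  while (done < n_reps) {
    m <- min(chunk, n_reps - done)
    draws <- matrix(stats::rgamma(m * n_bins, shape = shape, rate = 1), m, n_bins)
    mx <- if (n_bins == 1) draws[, 1] else
      draws[cbind(seq_len(m), max.col(draws, ties.method = "first"))]
    acc <- acc + sum(mx)
    done <- done + m
  }
  (acc / n_reps) / shape
}

#' Fit a gamma shape parameter to an observed Gini coefficient
#'
#' Bisection on the shape until the mean simulated Gini (via
#' [gini_envelope()]) matches the observed Gini within `tol`; the mean
#' simulated Gini is monotone decreasing in the shape. The 95% CI is the
#' range of shapes, scanned on a grid, whose simulated 2.5-97.5% Gini
#' interval covers the observed value.
#'
#' @param observed A `gini_result` (or a bare Gini value in (0,1)).
#' @param map A `marker_map`.
#' @param n_crossovers Crossovers per simulated panel (match the observed
#'   side total).
#' @param n_sims Simulations per shape evaluation.
#' @param seed Integer seed.
#' @param side Side selector.
#' @param tol Bisection tolerance on the mean Gini.
#' @param bracket Initial shape bracket.
#' @param ci_step Grid step (in shape units) for the CI scan.
#' @return An object of class `gamma_fit`: list with `shape`, `ci95`,
#'   `observed_gini`, `n_sims_per_eval`, `seed`.
#' @export
fit_shape_to_gini <- function(observed, map, n_crossovers, n_sims = 1000,
                              seed = 1, side = "both", tol = 0.002,
                              bracket = c(0.05, 64), ci_step = 0.05) {
  g_obs <- if (inherits(observed, "gini_result")) observed$gini else observed
  .assert(g_obs > 0 && g_obs < 1, "observed Gini must be in (0,1)")
  eval_gini <- function(k) {
    gini_envelope(k, map, n_crossovers, n_sims = n_sims,
                  seed = .stage_seed(seed, sprintf("shape-%.6f", k)),
                  side = side)
  }
  lo <- bracket[1]; hi <- bracket[2]
  g_lo <- eval_gini(lo)$mean  # largest achievable mean gini
  g_hi <- eval_gini(hi)$mean  # smallest
  .assert(g_obs <= g_lo && g_obs >= g_hi,
          "observed Gini %.3f outside achievable range [%.3f, %.3f] for shapes [%g, %g]",
          g_obs, g_hi, g_lo, lo, hi)
  k_mid <- NA
  for (it in seq_len(40)) {
    k_mid <- sqrt(lo * hi)  # bisect on log scale: shape spans decades
    g_mid <- eval_gini(k_mid)$mean
    if (abs(g_mid - g_obs) < tol || (hi - lo) < 1e-3) break
    if (g_mid > g_obs) lo <- k_mid else hi <- k_mid
  }
  # CI: scan outward from the point estimate until the envelope no longer
  # covers the observed Gini
  covers <- function(k) {
    q <- eval_gini(k)$quantiles
    g_obs >= q[1] && g_obs <= q[3]
  }
  k_lo <- k_mid
  while (k_lo - ci_step >= bracket[1] && covers(k_lo - ci_step))
    k_lo <- k_lo - ci_step
  k_hi <- k_mid
  while (k_hi + ci_step <= bracket[2] && covers(k_hi + ci_step))
    k_hi <- k_hi + ci_step
  structure(list(shape = k_mid, ci95 = c(k_lo, k_hi), observed_gini = g_obs,
                 n_sims_per_eval = n_sims, seed = seed, side = side),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("gamma_fit: shape %.3f (95%% CI %.3f-%.3f) for observed Gini %.3f\n",
              x$shape, x$ci95[1], x$ci95[2], x$observed_gini))
  invisible(x)
}
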