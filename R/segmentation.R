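# Exact ML piecewise-constant Poisson segmentation.
#
# Core solver works on raw count/length vectors; the exported functions wrap
# crossover tables around it. Within a domain the ML rate is pooled count /
# pooled length, so dynamic programming over knot placements at interval
# boundaries gives the exact optimum for every K.

# Pooled-domain log-likelihood matrix and DP solve. Returns log-likelihood,
# boundary indices (last interval of each domain but the final one) and the
# saturated log-likelihood.
.seg_core <- function(cnt, len, K, want_path = TRUE) {
  n <- length(cnt)
  pc <- c(0, cumsum(cnt))
  pl <- c(0, cumsum(len))
  base_terms <- cnt * log(len) - lgamma(cnt + 1)
  pb <- c(0, cumsum(base_terms))
  # cost[i, j]: log-likelihood of pooling intervals i..j into one domain
  cost <- matrix(-Inf, n, n)
  for (i in seq_len(n)) {
    j <- i:n
    C <- pc[j + 1] - pc[i]
    L <- pl[j + 1] - pl[i]
    B <- pb[j + 1] - pb[i]
    v <- B
    pos <- C > 0
    v[pos] <- v[pos] + C[pos] * log(C[pos] / L[pos]) - C[pos]
    cost[i, j] <- v
  }
  dp <- matrix(-Inf, K, n)
  bt <- if (want_path) matrix(NA_integer_, K, n) else NULL
  dp[1, ] <- cost[1, ]
  if (K > 1) {
    for (k in 2:K) {
      for (j in k:n) {
        prev <- (k - 1):(j - 1)
        cand <- dp[k - 1, prev] + cost[prev + 1, j]
        best <- which.max(cand)
        dp[k, j] <- cand[best]
        if (want_path) bt[k, j] <- prev[best]
      }
    }
  }
  bounds <- integer(0)
  if (want_path && K > 1) {
    j <- n
    for (k in K:2) { j <- bt[k, j]; bounds <- c(j, bounds) }
  }
  sat <- sum(ifelse(cnt > 0, cnt * log(cnt / len) - cnt, 0) + base_terms)
  list(log_likelihood = dp[K, n], bounds = bounds, saturated = sat)
}

#' Exact maximum-likelihood piecewise-constant rate segmentation
#'
#' Fits `K` constant-rate domains to one side's unmasked interval counts by
#' dynamic programming over all knot placements at marker boundaries. Within
#' a domain the maximum-likelihood rate is the pooled count divided by the
#' pooled length, so the optimum over knot placements is exact — no spline
#' approximation is involved.
#'
#' @param table A `crossover_table`.
#' @param side `"left"`, `"right"` or `"both"`.
#' @param K Number of constant-rate domains (1..number of unmasked intervals).
#' @return An object of class `segmentation`: list with `side`, `knots`
#'   (interior boundary positions), `segment_rates` (crossovers/bp),
#'   `segments` (data.frame of domain spans, pooled counts and rates),
#'   `log_likelihood`, `saturated_log_likelihood`, `K`.
#' @export
fit_segmentation <- function(table, side = c("left", "right", "both"), K) {
  side <- match.arg(side)
  sub <- .unmasked(table, side)
  n <- nrow(sub)
  .assert(K >= 1 && K <= n, "K must be between 1 and %d (unmasked intervals)", n)
  cnt <- sub$count_faxnil + sub$count_lonnil
  len <- sub$length
  core <- .seg_core(cnt, len, K)
  starts <- c(1, core$bounds + 1)
  ends <- c(core$bounds, n)
  segs <- data.frame(
    start = sub$start[starts], end = sub$end[ends],
    n_intervals = ends - starts + 1,
    count = vapply(seq_len(K), function(k) sum(cnt[starts[k]:ends[k]]), numeric(1)),
    length = vapply(seq_len(K), function(k) sum(len[starts[k]:ends[k]]), numeric(1)))
  segs$rate <- segs$count / segs$length
  structure(list(side = side, knots = sub$end[core$bounds],
                 segment_rates = segs$rate, segments = segs,
                 log_likelihood = core$log_likelihood,
                 saturated_log_likelihood = core$saturated, K = K),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation (%s side): %d domains, logLik %.3f (saturated %.3f)\n",
              x$side, x$K, x$log_likelihood, x$saturated_log_likelihood))
  print(x$segments)
  invisible(x)
}

#' Minimal number of constant-rate domains adequate for the data
#'
#' For each `K` (ascending) the likelihood-ratio statistic of the K-domain
#' fit against the saturated per-interval model is compared to a null
#' distribution from a parametric bootstrap: `n_sims` tables are drawn from
#' the fitted K-domain model (multinomial, conditioning on the observed side
#' total) and each is refitted at the same `K`. The minimal adequate `K` is
#' the smallest whose add-one Monte-Carlo p-value is at least `alpha`.
#'
#' @param table A `crossover_table`.
#' @param side Side selector.
#' @param alpha Rejection level.
#' @param K_max Largest number of domains examined.
#' @param n_sims Parametric-bootstrap replicates per `K` (>= 99).
#' @param seed Integer seed.
#' @return An object of class `domain_test`: list with `per_K` (data.frame
#'   `K`, `log_likelihood`, `lrt`, `p`), `minimal_adequate_K` (NA if none
#'   adequate up to `K_max`), `alpha`, `n_sims`, `seed`.
#' @export
min_adequate_domains <- function(table, side = c("left", "right", "both"),
                                 alpha = 0.05, K_max = 40, n_sims = 999,
                                 seed = 1) {
  side <- match.arg(side)
  .assert(n_sims >= 99, "n_sims must be at least 99")
  sub <- .unmasked(table, side)
  K_max <- min(K_max, nrow(sub))
  len <- sub$length
  total <- sum(sub$count_faxnil + sub$count_lonnil)
  rows <- list()
  minimal <- NA_integer_
  set.seed(seed)
  for (K in seq_len(K_max)) {
    fit <- fit_segmentation(table, side, K)
    lrt <- 2 * (fit$saturated_log_likelihood - fit$log_likelihood)
    # expected per-interval probabilities under the fitted K-domain model
    rate_per_iv <- rep(fit$segment_rates, fit$segments$n_intervals)
    pr <- rate_per_iv * len
    pr <- if (sum(pr) > 0) pr / sum(pr) else rep(1 / length(len), length(len))
    sims <- stats::rmultinom(n_sims, total, pr)
    null_lrt <- vapply(seq_len(n_sims), function(s) {
      core <- .seg_core(sims[, s], len, K, want_path = FALSE)
      2 * (core$saturated - core$log_likelihood)
    }, numeric(1))
    p <- .mc_pvalue(null_lrt, lrt, "upper")
    rows[[K]] <- data.frame(K = K, log_likelihood = fit$log_likelihood,
                            lrt = lrt, p = p)
    if (p >= alpha) {
      minimal <- K
      break
    }
  }
  structure(list(per_K = do.call(rbind, rows), minimal_adequate_K = minimal,
                 alpha = alpha, n_sims = n_sims, seed = seed, side = side),
            class = "domain_test")
}

#' @export
print.domain_test <- function(x, ...) {
  cat(sprintf("domain_test (%s side): minimal adequate K = %s (alpha %.3f, %d sims)\n",
              x$side, ifelse(is.na(x$minimal_adequate_K), "none",
                             x$minimal_adequate_K), x$alpha, x$n_sims))
  print(x$per_K)
  invisible(x)
}
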