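#' Lorenz curve and Gini coefficient of a crossover map
#'
#' Intervals are ordered by per-bp crossover rate (ascending, ties kept in
#' physical order); the Lorenz curve relates cumulative physical fraction to
#' cumulative genetic (crossover) fraction. The Gini coefficient is twice
#' the area between the curve and the diagonal: 0 means a uniform rate,
#' values near 1 mean all crossovers concentrated in one interval.
#'
#' @param table A `crossover_table`.
#' @param side `"both"`, `"left"` or `"right"`.
#' @return An object of class `gini_result`: list with `gini`,
#'   `lorenz_points` (data.frame `phys`, `gen`) and `side`.
#' @examples
#' tab <- crossover_table(data.frame(
#'   start = c(0, 1000, 2000, 3000) + 1, end = c(1000, 2000, 3000, 4000) + 1,
#'   side = "left", length = 1000,
#'   count_faxnil = c(0, 0, 0, 4), count_lonnil = 0, masked = FALSE))
#' lorenz_gini(tab, "left")$gini  # 0.75
#' @export
lorenz_gini <- function(table, side = c("both", "left", "right")) {
  side <- match.arg(side)
  sub <- .unmasked(table, side)
  counts <- sub$count_faxnil + sub$count_lonnil
  .assert(nrow(sub) >= 2, "need at least 2 unmasked intervals")
  .assert(sum(counts) > 0, "zero total crossover count on side '%s'", side)
  ord <- order(counts / sub$length)   # stable: ties stay in physical order
  len <- sub$length[ord]
  cnt <- counts[ord]
  phys <- c(0, cumsum(len) / sum(len))
  gen <- c(0, cumsum(cnt) / sum(cnt))
  gini <- 1 - 2 * .trapz(phys, gen)
  structure(list(gini = gini,
                 lorenz_points = data.frame(phys = phys, gen = gen),
                 side = side),
            class = "gini_result")
}

#' @export
print.gini_result <- function(x, ...) {
  cat(sprintf("Gini coefficient (%s side): %.4f over %d intervals\n",
              x$side, x$gini, nrow(x$lorenz_points) - 1))
  invisible(x)
}

#' @method plot gini_result
#' @export
plot.gini_result <- function(x, ...) {
  graphics::plot(x$lorenz_points$phys, x$lorenz_points$gen, type = "l",
                 xlab = "cumulative physical fraction",
                 ylab = "cumulative genetic fraction",
                 main = sprintf("Lorenz curve (%s), Gini = %.3f", x$side,
                                x$gini), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate the design-conditioned uniform-rate null ensemble
#'
#' For each cross and side independently, the observed total crossover count
#' is redistributed across that side's unmasked intervals multinomially with
#' probabilities proportional to interval length. Per-side totals are fixed
#' by the sampling design (equal numbers of strains genotyped per side), so
#' the null conditions on them rather than drawing Poisson totals.
#'
#' @param table A `crossover_table`.
#' @param n_sims Number of simulated tables.
#' @param seed Integer seed; the ensemble is reproducible from it.
#' @return An object of class `uniform_null_ensemble`: list with count
#'   matrices (`n_sims` x unmasked intervals) per cross, the unmasked
#'   interval skeleton, `n_sims` and `seed`.
#' @export
simulate_uniform_null <- function(table, n_sims, seed = 1) {
  .assert(n_sims >= 1, "n_sims must be at least 1")
  sub <- .unmasked(table)
  set.seed(seed)
  sim_fax <- matrix(0L, n_sims, nrow(sub))
  sim_lon <- matrix(0L, n_sims, nrow(sub))
  for (sd in unique(sub$side)) {
    idx <- which(sub$side == sd)
    pr <- sub$length[idx] / sum(sub$length[idx])
    tot_f <- sum(sub$count_faxnil[idx])
    tot_l <- sum(sub$count_lonnil[idx])
    if (tot_f > 0)
      sim_fax[, idx] <- t(stats::rmultinom(n_sims, tot_f, pr))
    if (tot_l > 0)
      sim_lon[, idx] <- t(stats::rmultinom(n_sims, tot_l, pr))
  }
  structure(list(skeleton = sub, count_faxnil = sim_fax,
                 count_lonnil = sim_lon, n_sims = n_sims, seed = seed),
            class = "uniform_null_ensemble")
}

#' Test rate uniformity against the simulation null
#'
#' The offset+side Poisson model is fitted to the observed per-interval
#' totals and to each simulated table; the Monte-Carlo p-value is the
#' add-one fraction of simulations whose residual deviance is at least the
#' observed one.
#'
#' @param table The observed `crossover_table`.
#' @param ensemble A matching `uniform_null_ensemble`.
#' @return List with `p`, `observed_deviance`, `null_deviances`.
#' @export
uniformity_test <- function(table, ensemble) {
  sub <- .unmasked(table)
  .assert(nrow(sub) == nrow(ensemble$skeleton) &&
            all(sub$start == ensemble$skeleton$start),
          "ensemble was built from a different interval structure")
  obs_fit <- fit_poisson(sub$count_faxnil + sub$count_lonnil, sub$length,
                         sub$side)
  .assert(obs_fit$converged, "model did not converge on observed data")
  null_dev <- vapply(seq_len(ensemble$n_sims), function(i) {
    fit_poisson(ensemble$count_faxnil[i, ] + ensemble$count_lonnil[i, ],
                sub$length, sub$side)$residual_deviance
  }, numeric(1))
  list(p = .mc_pvalue(null_dev, obs_fit$residual_deviance, "upper"),
       observed_deviance = obs_fit$residual_deviance,
       null_deviances = null_dev)
}

#' Compare crossover distributions between crosses (Kolmogorov-Smirnov)
#'
#' Crossover positions are interval-censored, so each event is placed at its
#' interval's right boundary and the two-sample two-sided asymptotic KS test
#' compares the FaxNIL and LonNIL position distributions.
#'
#' @param table A `crossover_table`.
#' @param side `"left"` or `"right"` (or `"both"`).
#' @return List with `D` and `p`.
#' @export
ks_compare <- function(table, side = c("left", "right", "both")) {
  side <- match.arg(side)
  sub <- .unmasked(table, side)
  x <- rep(sub$end, sub$count_faxnil)
  y <- rep(sub$end, sub$count_lonnil)
  .assert(length(x) > 0 && length(y) > 0,
          "both crosses need at least one crossover on side '%s'", side)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Down-sampled Gini comparison against a reference map
#'
#' Repeatedly subsamples the reference map's crossovers (without
#' replacement) to the event count the target map yields per `window_bp` of
#' physical span, recomputes the reference Gini each time, and reports the
#' two-sided Monte-Carlo probability of a reference Gini at least as extreme
#' as the target's. Used to ask whether a map's heterogeneity differs from a
#' reference region once sample sizes are equalized.
#'
#' @param reference_table Reference `crossover_table` (the denser map).
#' @param target_table Target `crossover_table`.
#' @param window_bp Window size defining the target's per-window event count.
#' @param n_perm Number of subsampling permutations.
#' @param seed Integer seed.
#' @param target_side Side selector for the target Gini.
#' @return List with `p`, `target_gini`, `n_subsample`, `ginis`.
#' @export
gini_downsample_compare <- function(reference_table, target_table,
                                    window_bp, n_perm = 1000, seed = 1,
                                    target_side = "both") {
  ref <- .unmasked(reference_table)
  tgt <- .unmasked(target_table, target_side)
  tgt_counts <- tgt$count_faxnil + tgt$count_lonnil
  n_sub <- round(window_bp * sum(tgt_counts) / sum(tgt$length))
  ref_counts <- ref$count_faxnil + ref$count_lonnil
  .assert(n_sub <= sum(ref_counts),
          "target per-window count (%d) exceeds reference total (%d)",
          n_sub, sum(ref_counts))
  target_gini <- lorenz_gini(target_table, target_side)$gini
  events <- rep(seq_len(nrow(ref)), ref_counts)
  set.seed(seed)
  ginis <- vapply(seq_len(n_perm), function(i) {
    keep <- sample(events, n_sub)
    cnt <- tabulate(keep, nbins = nrow(ref))
    ord <- order(cnt / ref$length)
    phys <- c(0, cumsum(ref$length[ord]) / sum(ref$length))
    gen <- c(0, cumsum(cnt[ord]) / sum(cnt))
    1 - 2 * .trapz(phys, gen)
  }, numeric(1))
  p_lo <- .mc_pvalue(ginis, target_gini, "lower")
  p_hi <- .mc_pvalue(ginis, target_gini, "upper")
  list(p = min(1, 2 * min(p_lo, p_hi)), target_gini = target_gini,
       n_subsample = n_sub, ginis = ginis)
}
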