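# Internal helpers shared across modules.

# Deterministic stage seed derived from a master seed and a stage label.
# Kept strictly below 2^31 so it is always a valid R integer seed.
.stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 48271 + h) %% 2147483647L)
}

# Add-one (Davison-Hinkley) Monte-Carlo p-value: #{null >= obs} with the
# observed statistic counted as one of the draws.
.mc_pvalue <- function(null_stats, observed, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  n <- length(null_stats)
  hits <- if (tail == "upper") sum(null_stats >= observed) else sum(null_stats <= observed)
  (1 + hits) / (n + 1)
}

# Trapezoidal area under a curve given ordered x, y.
.trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Reverse complement of plain character DNA strings (IUPAC-aware).
.revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                   "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Greedy left-to-right count of non-overlapping occupancy given all (sorted)
# match start positions of a length-k pattern.
.greedy_count <- function(positions, k) {
  n <- length(positions)
  if (n < 2) return(n)
  if (!any(positions[-1L] - positions[-n] < k)) return(n)  # no overlaps
  n_hit <- 0L
  last <- -k
  for (p in positions) {
    if (p >= last + k) {
      n_hit <- n_hit + 1L
      last <- p
    }
  }
  n_hit
}

# Minimal Poisson IRLS with log link and offset: the scan modules refit
# thousands of small models, where stats::glm.fit's fixed overhead
# dominates. Agreement with glm.fit is covered by tests.
.fast_poisson <- function(X, y, off, maxit = 100, tol = 1e-10) {
  mu <- y + 0.5
  eta <- log(mu)
  dev <- Inf
  beta <- NULL
  pos <- which(y > 0)
  ypos <- y[pos]
  ylogy <- sum(ypos * log(ypos))
  ytot <- sum(y)
  for (it in seq_len(maxit)) {
    z <- eta - off + (y - mu) / mu
    XtW <- t(X * mu)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) {
      return(list(coefficients = rep(NA_real_, ncol(X)), deviance = Inf,
                  converged = FALSE))
    }
    eta <- off + drop(X %*% beta_new)
    eta[eta > 30] <- 30
    eta[eta < -30] <- -30
    mu <- exp(eta)
    dev_new <- 2 * (ylogy - sum(ypos * eta[pos]) - ytot + sum(mu))
    beta <- beta_new
    if (is.finite(dev) && abs(dev - dev_new) < tol * (abs(dev_new) + 0.1)) {
      dev <- dev_new
      return(list(coefficients = drop(beta), deviance = dev, converged = TRUE))
    }
    dev <- dev_new
  }
  list(coefficients = drop(beta), deviance = dev, converged = FALSE)
}

# All (possibly overlapping) start positions of fixed string `pat` in `seq`.
.all_positions <- function(seq, pat) {
  hits <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}
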