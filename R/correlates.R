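# Genomic-correlate aggregation and univariate Poisson scans.

#' Per-interval GC content
#'
#' `(G+C)/(A+C+G+T)` for each interval's sequence; `N` bases are excluded
#' from the denominator. Intervals that are entirely `N` get `NA` and are
#' flagged.
#'
#' @param sequence DNA string covering the shared span.
#' @param table A `crossover_table`.
#' @param seq_start Physical coordinate of the first base of `sequence`.
#' @return Numeric vector aligned with the unmasked intervals (attribute
#'   `flagged` marks all-N intervals).
#' @export
gc_content <- function(sequence, table,
                       seq_start = attr(table, "shared_span")[1]) {
  sub <- .unmasked(table)
  seqs <- .interval_seqs(sequence, seq_start, sub)
  dss <- Biostrings::DNAStringSet(seqs)
  freq <- Biostrings::letterFrequency(dss, c("A", "C", "G", "T"))
  denom <- rowSums(freq)
  gc <- (freq[, "G"] + freq[, "C"]) / denom
  flagged <- denom == 0
  if (any(flagged)) warning(sprintf("%d interval(s) are entirely N", sum(flagged)))
  structure(as.numeric(gc), flagged = flagged)
}

#' Read a genomic feature track (BED / bedGraph)
#'
#' Thin wrapper over [rtracklayer::import()]; coordinates are converted to
#' the package's 1-based half-open convention (`start` = BED start + 1,
#' `end` = BED end + 1).
#'
#' @param path Path to the track file.
#' @param name Track name (defaults to the file name).
#' @param format Passed to `rtracklayer::import` (guessed from the
#'   extension when `NULL`).
#' @return An object of class `feature_track`: data.frame `start`, `end`,
#'   `value` with attributes `name` and `kind` (`"signal"` when values vary,
#'   else `"annotation"`).
#' @export
read_track <- function(path, name = basename(path), format = NULL) {
  gr <- if (is.null(format)) rtracklayer::import(path) else
    rtracklayer::import(path, format = format)
  df <- as.data.frame(gr)
  value <- if ("score" %in% names(df)) df$score else rep(1, nrow(df))
  feature_track(data.frame(start = df$start, end = df$end + 1, value = value),
                name = name)
}

#' @rdname read_track
#' @param df data.frame with 1-based half-open `start`, `end` and `value`.
#' @param kind `"signal"` or `"annotation"`; guessed when `NULL`.
#' @export
feature_track <- function(df, name = "track", kind = NULL) {
  .assert(all(c("start", "end") %in% names(df)), "track needs start and end")
  if (is.null(df$value)) df$value <- 1
  .assert(all(is.finite(df$value)), "track values must be finite")
  df <- df[order(df$start), c("start", "end", "value")]
  .assert(all(df$start[-1] >= df$end[-nrow(df)]) || nrow(df) < 2,
          "track spans must not overlap")
  if (is.null(kind)) {
    kind <- if (length(unique(df$value)) > 1) "signal" else "annotation"
  }
  structure(df, class = c("feature_track", "data.frame"), name = name,
            kind = kind)
}

#' Aggregate a feature track over table intervals
#'
#' `mean`: length-weighted mean of overlapping signal (with the covered
#' fraction reported when the track does not span an interval fully).
#' `density`: overlap-prorated feature count per interval bp (a feature
#' straddling a boundary contributes its overlap fraction to each side).
#' `coverage`: fraction of interval bp covered by track spans.
#'
#' @param track A `feature_track`.
#' @param table A `crossover_table`.
#' @param stat `"mean"`, `"density"` or `"coverage"`.
#' @return Numeric vector aligned with the unmasked intervals; attribute
#'   `coverage` carries the per-interval covered fraction for `stat="mean"`.
#' @export
aggregate_track <- function(track, table,
                            stat = c("mean", "density", "coverage")) {
  stat <- match.arg(stat)
  sub <- .unmasked(table)
  out <- numeric(nrow(sub))
  cov <- numeric(nrow(sub))
  for (i in seq_len(nrow(sub))) {
    s <- sub$start[i]; e <- sub$end[i]
    ovl <- pmin(track$end, e) - pmax(track$start, s)
    hit <- ovl > 0
    if (!any(hit)) {
      out[i] <- if (stat == "mean") NA_real_ else 0
      next
    }
    o <- ovl[hit]
    cov[i] <- sum(o) / (e - s)
    out[i] <- switch(stat,
      mean = sum(track$value[hit] * o) / sum(o),
      density = sum(o / (track$end[hit] - track$start[hit])) / (e - s),
      coverage = cov[i])
  }
  if (stat == "mean" && any(cov < 1 & cov > 0)) {
    structure(out, coverage = cov)
  } else {
    structure(out, coverage = cov)
  }
}

#' Univariate Poisson scan of interval features
#'
#' Each feature enters an offset+side Poisson model on its own; reported
#' per feature: coefficient, percent deviance explained over the base model
#' (or over base+control when a control covariate is given — the control is
#' then included alongside the feature and only the increment is credited),
#' and the nominal 1-df chi-square p-value, uncorrected. A Bonferroni
#' column is appended for convenience.
#'
#' @param features data.frame of numeric per-interval covariates, aligned
#'   with the table's unmasked intervals.
#' @param table A `crossover_table`.
#' @param control Optional named numeric control covariate (e.g. an IgG
#'   binding control for nucleosome occupancy), same length as intervals.
#' @return data.frame with one row per non-degenerate feature.
#' @export
univariate_scan <- function(features, table, control = NULL) {
  sub <- .unmasked(table)
  counts <- sub$count_faxnil + sub$count_lonnil
  .assert(nrow(features) == nrow(sub),
          "features must align with the %d unmasked intervals", nrow(sub))
  base_cov <- NULL
  if (!is.null(control)) {
    control <- as.numeric(control)
    .assert(length(control) == nrow(sub), "control must align with intervals")
    base_cov <- cbind(control = control)
  }
  base <- fit_poisson(counts, sub$length, sub$side, covariates = base_cov)
  rows <- list()
  for (nm in names(features)) {
    f <- as.numeric(features[[nm]])
    if (any(!is.finite(f)) || stats::sd(f) == 0) {
      warning(sprintf("feature '%s' is degenerate (constant or non-finite); skipped", nm))
      next
    }
    covs <- cbind(base_cov, feature = f)
    fit <- fit_poisson(counts, sub$length, sub$side, covariates = covs,
                       base_deviance = base$residual_deviance)
    drop_dev <- max(0, base$residual_deviance - fit$residual_deviance)
    rows[[nm]] <- data.frame(
      feature = nm, coefficient = unname(fit$coefficients["feature"]),
      deviance_explained = deviance_explained(fit),
      p = stats::pchisq(drop_dev, df = 1, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}

#' Correlation matrix and clustering of interval features
#'
#' Pearson correlations of features across intervals, hierarchically
#' clustered with average linkage on `1 - r`. Zero-variance features are
#' excluded with a warning. Significance stars from a univariate scan can
#' be attached for display.
#'
#' @param features data.frame of numeric per-interval covariates.
#' @param scan Optional result of [univariate_scan()] on the same features.
#' @return List with `cor` (correlation matrix in clustered order),
#'   `order` (feature names), `hclust`, and optionally `stars`.
#' @export
correlation_cluster <- function(features, scan = NULL) {
  .assert(ncol(features) >= 2, "need at least 2 features")
  keep <- vapply(features, function(f) stats::sd(as.numeric(f)) > 0, logical(1))
  if (any(!keep)) {
    warning(sprintf("excluding zero-variance feature(s): %s",
                    paste(names(features)[!keep], collapse = ", ")))
    features <- features[keep]
  }
  cm <- stats::cor(as.matrix(features))
  hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
  ord <- colnames(cm)[hc$order]
  out <- list(cor = cm[ord, ord], order = ord, hclust = hc)
  if (!is.null(scan)) {
    stars <- ifelse(scan$p < 0.01, "**", ifelse(scan$p < 0.05, "*", ""))
    out$stars <- stats::setNames(stars, scan$feature)[ord]
  }
  out
}

#' Gene-annotation derived promoter proxies
#'
#' From a simplified gene table (`gene_id`, `start`, `end`, `strand`),
#' computes per-interval gene density (transcription start sites per bp)
#' and the bp fraction of intergenic DNA lying between nonconvergently
#' transcribed gene pairs, plus the intronic-proxy fraction of genic bp.
#'
#' @param genes data.frame with columns `gene_id`, `start`, `end`, `strand`
#'   (1-based inclusive gene spans, strand `+`/`-`).
#' @param table A `crossover_table`.
#' @return data.frame with columns `gene_density`,
#'   `intergenic_fraction`, `genic_fraction` aligned with unmasked intervals.
#' @export
gene_features <- function(genes, table) {
  .assert(all(c("gene_id", "start", "end", "strand") %in% names(genes)),
          "genes need columns gene_id, start, end, strand")
  genes <- genes[order(genes$start), ]
  sub <- .unmasked(table)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  gene_density <- vapply(seq_len(nrow(sub)), function(i) {
    sum(tss >= sub$start[i] & tss < sub$end[i]) / sub$length[i]
  }, numeric(1))
  # intergenic gaps between consecutive genes; a gap is "nonconvergent"
  # unless the upstream gene is + and the downstream gene is - (their 3'
  # ends face each other and neither promoter lies in the gap)
  gaps <- NULL
  if (nrow(genes) >= 2) {
    gs <- genes$end[-nrow(genes)]
    ge <- genes$start[-1]
    conv <- genes$strand[-nrow(genes)] == "+" & genes$strand[-1] == "-"
    ok <- ge > gs & !conv
    gaps <- data.frame(start = gs[ok], end = ge[ok])
  }
  intergenic <- vapply(seq_len(nrow(sub)), function(i) {
    if (is.null(gaps) || nrow(gaps) == 0) return(0)
    ovl <- pmin(gaps$end, sub$end[i]) - pmax(gaps$start, sub$start[i])
    sum(ovl[ovl > 0]) / sub$length[i]
  }, numeric(1))
  genic <- vapply(seq_len(nrow(sub)), function(i) {
    ovl <- pmin(genes$end, sub$end[i]) - pmax(genes$start, sub$start[i])
    sum(ovl[ovl > 0]) / sub$length[i]
  }, numeric(1))
  data.frame(gene_density = gene_density, intergenic_fraction = intergenic,
             genic_fraction = pmin(1, genic))
}
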