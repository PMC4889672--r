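# Synthetic-data generator: every input the pipeline consumes can be
# produced here, with a truth record, so all stages are testable without
# external data. The default scenario mirrors the study design the package
# targets: a ~1.48 Mb focal span genotyped at 277 markers (median gap
# ~4.4 kb), two reciprocal crosses sampled equally per side of a sorting
# indel despite unequal underlying side totals, ~36% GC, and gamma-rate
# landscapes per side.

#' Define a synthetic study scenario
#'
#' @param seed Master seed for the generator.
#' @param span Physical span `(start, end)` in bp.
#' @param n_markers Number of genotyped markers.
#' @param gap_sdlog Log-sd of the lognormal inter-marker gap distribution
#'   (0 gives equal spacing; the default reproduces a ~4.4 kb median gap
#'   against a ~5.4 kb mean).
#' @param indel_frac Position of the sorting indel as a fraction of the span.
#' @param totals 2x2 matrix of crossover totals: rows `FaxNIL`, `LonNIL`,
#'   columns `left`, `right`. The default reproduces the unequal left/right
#'   sampling of the two-cross design.
#' @param landscape List describing the rate landscape: `kind` `"uniform"`
#'   or `"gamma"`, with per-side shapes `shape_left`, `shape_right`.
#' @param gc Genome GC fraction.
#' @param missing_rate Per-call probability of an `N`.
#' @param het_rate Per-strain probability of an injected heterozygous run.
#' @param double_recomb_rate Per-strain probability of a second crossover
#'   (strains that quality control should discard).
#' @param planted Optional list of planted motif effects, each a list with
#'   `motif`, `windows` (2-column matrix of spans) and `per_kb` density.
#' @param masks Optional data.frame of regions to mask downstream.
#' @return An object of class `synthetic_scenario`.
#' @export
synth_scenario <- function(seed = 1,
                           span = c(3280000, 4760000),
                           n_markers = 277,
                           gap_sdlog = 0.64,
                           indel_frac = 0.556,
                           totals = matrix(c(387, 243, 244, 241), 2,
                                           byrow = TRUE,
                                           dimnames = list(c("FaxNIL", "LonNIL"),
                                                           c("left", "right"))),
                           landscape = list(kind = "gamma",
                                            shape_left = 1.70,
                                            shape_right = 3.57),
                           gc = 0.36,
                           missing_rate = 0.002,
                           het_rate = 0.002,
                           double_recomb_rate = 0.01,
                           planted = list(),
                           masks = NULL) {
  .assert(n_markers >= 4, "need at least 4 markers")
  .assert(all(totals > 0), "crossover totals must be positive")
  .assert(gc > 0 && gc < 1, "GC must be in (0,1)")
  .assert(span[2] - span[1] >= n_markers * 10,
          "span too small for %d markers", n_markers)
  structure(list(seed = seed, span = as.numeric(span), n_markers = n_markers,
                 gap_sdlog = gap_sdlog, indel_frac = indel_frac,
                 totals = totals, landscape = landscape, gc = gc,
                 missing_rate = missing_rate, het_rate = het_rate,
                 double_recomb_rate = double_recomb_rate, planted = planted,
                 masks = masks),
            class = "synthetic_scenario")
}

#' Generate a marker map for a scenario
#'
#' Inter-marker gaps are lognormal (right-skewed, like real array designs);
#' positions are rescaled to tile the span exactly and the sorting indel is
#' placed at `indel_frac` of the span, between two markers.
#'
#' @param scenario A `synthetic_scenario`.
#' @return A `marker_map`.
#' @export
synth_marker_map <- function(scenario) {
  set.seed(.stage_seed(scenario$seed, "marker_map"))
  n <- scenario$n_markers
  width <- scenario$span[2] - scenario$span[1]
  gaps <- if (scenario$gap_sdlog == 0) rep(1, n - 1) else
    stats::rlnorm(n - 1, meanlog = 0, sdlog = scenario$gap_sdlog)
  gaps <- gaps / sum(gaps) * width
  pos <- round(scenario$span[1] + c(0, cumsum(gaps)))
  for (j in seq_len(n)[-1]) {       # repair rounding collisions
    if (pos[j] <= pos[j - 1]) pos[j] <- pos[j - 1] + 1
  }
  pos[n] <- max(pos[n], scenario$span[1] + width)
  indel <- scenario$span[1] + scenario$indel_frac * width
  # the indel must fall strictly between two markers
  i <- findInterval(indel, pos)
  i <- min(max(i, 2), n - 2)
  indel <- (pos[i] + pos[i + 1]) / 2
  sides <- ifelse(pos < indel, "left", "right")
  marker_map(pos, sides, indel_position = indel)
}

#' Generate a genome sequence for a scenario
#'
#' I.i.d. bases at the target GC fraction; optional planted motifs are
#' written in at the requested per-kb density within designated windows
#' (non-overlapping placement).
#'
#' @param scenario A `synthetic_scenario`.
#' @return A list with `sequence` (character) and `seq_start` (physical
#'   coordinate of base 1).
#' @export
synth_genome <- function(scenario) {
  set.seed(.stage_seed(scenario$seed, "genome"))
  width <- scenario$span[2] - scenario$span[1]
  p <- c(A = (1 - scenario$gc) / 2, C = scenario$gc / 2,
         G = scenario$gc / 2, T = (1 - scenario$gc) / 2)
  seq <- paste(sample(names(p), width, replace = TRUE, prob = p),
               collapse = "")
  for (pl in scenario$planted) {
    seq <- .plant_motif(seq, scenario$span[1], pl$motif, pl$windows, pl$per_kb)
  }
  list(sequence = seq, seq_start = scenario$span[1])
}

# Overwrite non-overlapping copies of `motif` into `sequence` at `per_kb`
# density within each window (physical coordinates).
.plant_motif <- function(sequence, seq_start, motif, windows, per_kb) {
  windows <- as.matrix(windows)
  k <- nchar(motif)
  for (w in seq_len(nrow(windows))) {
    a <- windows[w, 1] - seq_start + 1
    b <- windows[w, 2] - seq_start
    n_copies <- round((b - a + 1) / 1000 * per_kb)
    .assert(n_copies * k <= (b - a + 1) / 2,
            "planted density %.1f/kb infeasible for motif '%s'", per_kb, motif)
    placed <- integer(0)
    tries <- 0
    while (length(placed) < n_copies && tries < n_copies * 200) {
      tries <- tries + 1
      s <- sample(a:(b - k + 1), 1)
      if (!any(abs(s - placed) < k)) {
        substr(sequence, s, s + k - 1) <- motif
        placed <- c(placed, s)
      }
    }
    .assert(length(placed) == n_copies,
            "could not place %d copies of '%s' without overlap", n_copies, motif)
  }
  sequence
}

#' Generate a two-cross NIL genotype panel with a truth record
#'
#' For each cross and side, the scenario's crossover total fixes the number
#' of strains (one crossover each), reproducing the design's unequal
#' left/right sampling. Crossover positions are drawn from the landscape
#' restricted to the side's marker span; genotype vectors are written
#' around each breakpoint, then missing calls, heterozygous runs and
#' double-recombinant strains are injected at the scenario rates. The truth
#' record stores every generated breakpoint for recovery testing.
#'
#' @param scenario A `synthetic_scenario`.
#' @param map A `marker_map` (from [synth_marker_map()]).
#' @param landscape Optional `rate_landscape`; generated from the scenario
#'   when `NULL`.
#' @return List with `panel` (a `genotype_panel`), `truth` (data.frame of
#'   true breakpoints and injected-noise flags) and `landscape`.
#' @export
synth_panel <- function(scenario, map, landscape = NULL) {
  if (is.null(landscape)) landscape <- synth_landscape(scenario, map)
  .assert(landscape$span[1] <= map$shared_span[1] &&
            landscape$span[2] >= map$shared_span[2],
          "landscape does not cover the map")
  set.seed(.stage_seed(scenario$seed, "panel"))
  pos <- map$markers$position
  n_mark <- length(pos)
  bin_lo <- landscape$span[1] + (seq_along(landscape$rates) - 1) * landscape$bin_size
  bin_hi <- bin_lo + landscape$bin_size
  strains <- list(); truths <- list()
  sid <- 0
  for (cross in rownames(scenario$totals)) {
    for (side in colnames(scenario$totals)) {
      n_cs <- scenario$totals[cross, side]
      smark <- pos[map$markers$side == side]
      lo <- min(smark); hi <- max(smark)
      # restrict landscape weight to the side's marker span
      w <- (pmin(bin_hi, hi) - pmax(bin_lo, lo))
      w <- pmax(w, 0) * landscape$rates
      .assert(sum(w) > 0, "landscape has zero rate over the %s side", side)
      bins <- sample.int(length(w), n_cs, replace = TRUE, prob = w)
      u <- stats::runif(n_cs)
      xo <- pmax(bin_lo[bins], lo) + u * (pmin(bin_hi[bins], hi) - pmax(bin_lo[bins], lo))
      for (x in xo) {
        sid <- sid + 1
        left_geno <- if (cross == "FaxNIL") "A" else "B"
        right_geno <- if (left_geno == "A") "B" else "A"
        calls <- ifelse(pos <= x, left_geno, right_geno)
        i <- findInterval(x, pos)
        truth_row <- data.frame(
          strain_id = sprintf("S%04d", sid), cross = cross, side = side,
          position = x, interval_start = pos[i], interval_end = pos[i + 1],
          double_recombinant = FALSE, het_injected = FALSE,
          stringsAsFactors = FALSE)
        if (stats::runif(1) < scenario$double_recomb_rate) {
          # second crossover: flip the genotype tail beyond another marker
          j <- sample(setdiff(seq_len(n_mark - 1), i), 1)
          flip <- (j + 1):n_mark
          calls[flip] <- ifelse(calls[flip] == "A", "B", "A")
          truth_row$double_recombinant <- TRUE
        }
        if (stats::runif(1) < scenario$het_rate) {
          run <- sample(1:3, 1)
          at <- sample(seq_len(n_mark - run + 1), 1)
          calls[at:(at + run - 1)] <- "H"
          truth_row$het_injected <- TRUE
        }
        miss <- stats::runif(n_mark) < scenario$missing_rate
        calls[miss] <- "N"
        strains[[sid]] <- calls
        truths[[sid]] <- truth_row
      }
    }
  }
  calls <- do.call(rbind, strains)
  truth <- do.call(rbind, truths)
  panel <- genotype_panel(truth$strain_id, truth$cross, calls, map)
  list(panel = panel, truth = truth, landscape = landscape)
}

#' Build the scenario's rate landscape
#'
#' Uniform, or per-side gamma with the scenario's shape parameters (rates
#' drawn in 1-kb bins, each side normalized to its share of the total).
#'
#' @param scenario A `synthetic_scenario`.
#' @param map A `marker_map`.
#' @return A `rate_landscape` covering the scenario span.
#' @export
synth_landscape <- function(scenario, map) {
  set.seed(.stage_seed(scenario$seed, "landscape"))
  bin_size <- 1000
  span_end <- max(scenario$span[2], map$shared_span[2])
  n_bins <- ceiling((span_end - scenario$span[1]) / bin_size)
  bin_mid <- scenario$span[1] + (seq_len(n_bins) - 0.5) * bin_size
  total <- sum(scenario$totals)
  if (identical(scenario$landscape$kind, "uniform")) {
    rates <- rep(total / (n_bins * bin_size), n_bins)
    return(rate_landscape(rates, c(scenario$span[1], scenario$span[1] + n_bins * bin_size), bin_size, kind = "uniform"))
  }
  left <- bin_mid < map$indel_position
  rates <- numeric(n_bins)
  rates[left] <- stats::rgamma(sum(left), shape = scenario$landscape$shape_left,
                               rate = 1)
  rates[!left] <- stats::rgamma(sum(!left), shape = scenario$landscape$shape_right,
                                rate = 1)
  tot_left <- sum(scenario$totals[, "left"])
  tot_right <- sum(scenario$totals[, "right"])
  rates[left] <- rates[left] / sum(rates[left] * bin_size) * tot_left
  rates[!left] <- rates[!left] / sum(rates[!left] * bin_size) * tot_right
  rate_landscape(rates, c(scenario$span[1], scenario$span[1] + n_bins * bin_size), bin_size, kind = "gamma")
}

#' Write all scenario outputs to a directory
#'
#' Writes `map.tsv`, `panel.tsv`, `region.fa` and `truth.json` so the
#' pipeline can be exercised from files.
#'
#' @param scenario A `synthetic_scenario`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
synth_write_fixtures <- function(scenario, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  map <- synth_marker_map(scenario)
  genome <- synth_genome(scenario)
  pan <- synth_panel(scenario, map)
  write_marker_map(map, file.path(outdir, "map.tsv"))
  write_genotypes(pan$panel, file.path(outdir, "panel.tsv"))
  dss <- Biostrings::DNAStringSet(genome$sequence)
  names(dss) <- sprintf("region:%d-%d", scenario$span[1], scenario$span[2])
  Biostrings::writeXStringSet(dss, file.path(outdir, "region.fa"))
  jsonlite::write_json(pan$truth, file.path(outdir, "truth.json"),
                       digits = NA)
  invisible(list(map = map, genome = genome, panel = pan$panel,
                 truth = pan$truth, landscape = pan$landscape))
}
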