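# Whole-pipeline driver: breakpoint calling through heterogeneity,
# segmentation, gamma-compatibility and scan stages, with per-stage seeds
# derived deterministically from one master seed and reports written as
# TSV/JSON.

#' Build a run configuration
#'
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it deterministically.
#' @param markers,genotypes Paths to the marker map and genotype TSVs.
#' @param fasta Optional path to the focal-region FASTA (enables the motif
#'   and GC stages).
#' @param seq_start Physical coordinate of the FASTA's first base; parsed
#'   from a `name:start-end` FASTA header when `NULL`.
#' @param masks Optional data.frame of regions to mask.
#' @param alpha Level for the segmentation adequacy test.
#' @param n_sims Named list of simulation counts per stage.
#' @param k_range Motif lengths for the scan stage.
#' @param stages Character vector of stages to run.
#' @param max_missing Passed to [call_breakpoints()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, markers, genotypes, fasta = NULL,
                       seq_start = NULL, masks = NULL, alpha = 0.05,
                       n_sims = list(uniformity = 1000, segmentation = 199,
                                     gamma = 500, motif_perms = 99),
                       k_range = 4:6,
                       stages = c("fisher", "ks", "gini", "uniformity",
                                  "segmentation", "gamma", "motifs"),
                       max_missing = 2) {
  structure(list(seed = seed, markers = markers, genotypes = genotypes,
                 fasta = fasta, seq_start = seq_start, masks = masks,
                 alpha = alpha, n_sims = n_sims, k_range = k_range,
                 stages = stages, max_missing = max_missing),
            class = "run_config")
}

#' Run the full crossover-landscape analysis
#'
#' Executes, in order: breakpoint calling, tabulation, masking, 25 kb
#' re-binning, then the requested stages — the side-by-cross Fisher exact
#' test, KS cross comparison, Lorenz/Gini, uniformity simulation test (full
#' and 25 kb), constant-rate-domain segmentation, gamma-shape fitting, and
#' (with a sequence) the motif scan with permutation control. One TSV/JSON
#' report per stage is written under `outdir`, plus `report.json` bundling
#' the statistics, the configuration echo and every derived seed.
#'
#' @param config A `run_config`.
#' @param outdir Output directory.
#' @return Invisibly, the report list.
#' @export
run_full_analysis <- function(config, outdir) {
  .assert(inherits(config, "run_config"), "config must be a run_config")
  .assert(file.exists(config$markers), "marker file not found: %s", config$markers)
  .assert(file.exists(config$genotypes), "genotype file not found: %s",
          config$genotypes)
  if ("motifs" %in% config$stages) {
    .assert(!is.null(config$fasta) && file.exists(config$fasta),
            "motif_scan stage requires a FASTA sequence (config$fasta)")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = config[setdiff(names(config), "")], seeds = list())
  stage_seed <- function(stage) {
    s <- .stage_seed(config$seed, stage)
    report$seeds[[stage]] <<- s
    s
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  map <- run_stage("read", read_marker_map(config$markers))
  panel <- run_stage("read", read_genotypes(config$genotypes, map))
  called <- run_stage("call", call_breakpoints(panel, map,
                                               max_missing = config$max_missing))
  utils::write.table(called$qc$excluded, file.path(outdir, "qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- run_stage("tabulate", tabulate_crossovers(called$crossovers, map))
  if (!is.null(config$masks)) tab <- mask_intervals(tab, config$masks)
  tab25 <- run_stage("rebin", rebin_25kb(tab))
  write_crossover_table(tab, file.path(outdir, "table_full.tsv"))
  write_crossover_table(tab25, file.path(outdir, "table_25kb.tsv"))
  report$qc <- list(n_retained = called$qc$n_retained,
                    n_input = called$qc$n_input,
                    excluded = as.list(table(called$qc$excluded$reason)))

  if ("fisher" %in% config$stages) {
    m <- side_cross_totals(tab)
    ft <- stats::fisher.test(m)
    report$fisher <- list(table = m, p = ft$p.value,
                          odds_ratio = unname(ft$estimate))
  }
  if ("ks" %in% config$stages) {
    report$ks <- lapply(c(left = "left", right = "right"), function(sd) {
      run_stage("ks", ks_compare(tab, sd)[c("D", "p")])
    })
  }
  if ("gini" %in% config$stages) {
    report$gini <- lapply(c(left = "left", right = "right"), function(sd) {
      run_stage("gini", lorenz_gini(tab, sd)$gini)
    })
  }
  if ("uniformity" %in% config$stages) {
    report$uniformity <- lapply(list(full = tab, `25kb` = tab25), function(tt) {
      ens <- simulate_uniform_null(tt, config$n_sims$uniformity,
                                   seed = stage_seed(paste0("uniformity-",
                                                            attr(tt, "resolution"))))
      ut <- run_stage("uniformity", uniformity_test(tt, ens))
      list(p = ut$p, observed_deviance = ut$observed_deviance)
    })
  }
  if ("segmentation" %in% config$stages) {
    report$segmentation <- lapply(c(left = "left", right = "right"),
                                  function(sd) {
      dt <- run_stage("segmentation", min_adequate_domains(
        tab, sd, alpha = config$alpha, n_sims = config$n_sims$segmentation,
        seed = stage_seed(paste0("segmentation-", sd))))
      utils::write.table(dt$per_K,
                         file.path(outdir, sprintf("segmentation_%s.tsv", sd)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(minimal_adequate_K = dt$minimal_adequate_K)
    })
  }
  if ("gamma" %in% config$stages) {
    report$gamma <- lapply(c(left = "left", right = "right"), function(sd) {
      g <- lorenz_gini(tab, sd)
      sub <- .unmasked(tab, sd)
      gf <- run_stage("gamma", fit_shape_to_gini(
        g, map, n_crossovers = sum(sub$count_faxnil + sub$count_lonnil),
        n_sims = config$n_sims$gamma,
        seed = stage_seed(paste0("gamma-", sd)), side = sd))
      list(shape = gf$shape, ci95 = gf$ci95, observed_gini = gf$observed_gini)
    })
  }
  if ("motifs" %in% config$stages) {
    fa <- read_region_fasta(config$fasta, seq_start = config$seq_start)
    scan <- run_stage("motifs", scan_motifs(tab25, fa$sequence,
                                            seq_start = fa$seq_start,
                                            k_range = config$k_range))
    null <- run_stage("motifs", permutation_null(
      tab25, fa$sequence, seq_start = fa$seq_start, k_range = config$k_range,
      n_perm = config$n_sims$motif_perms, seed = stage_seed("motif-perms")))
    rep_df <- motif_test_report(scan, null)
    utils::write.table(rep_df, file.path(outdir, "motif_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    top <- rep_df[order(rep_df$permutation_p, rep_df$residual_deviance), ]
    report$motifs <- list(n_motifs = nrow(rep_df),
                          top = utils::head(top[c("motif", "k",
                                                  "effect_direction",
                                                  "deviance_explained",
                                                  "permutation_p")], 10))
  }
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

#' Side-by-cross crossover totals
#'
#' The 2x2 table of crossover totals (crosses x sides) whose Fisher exact
#' test quantifies the cross-by-side skew of the sampling design.
#'
#' @param table A `crossover_table`.
#' @return 2x2 integer matrix, rows FaxNIL/LonNIL, columns left/right.
#' @export
side_cross_totals <- function(table) {
  m <- rbind(
    FaxNIL = c(sum(table$count_faxnil[table$side == "left"]),
               sum(table$count_faxnil[table$side == "right"])),
    LonNIL = c(sum(table$count_lonnil[table$side == "left"]),
               sum(table$count_lonnil[table$side == "right"])))
  colnames(m) <- c("left", "right")
  m
}

#' Read a region FASTA
#'
#' Reads a single-record FASTA with [Biostrings::readDNAStringSet()]. The
#' physical coordinate of the first base is taken from `seq_start`, or
#' parsed from a `name:start-end` header.
#'
#' @param path FASTA path.
#' @param seq_start Optional explicit start coordinate.
#' @return List with `sequence` (character) and `seq_start`.
#' @export
read_region_fasta <- function(path, seq_start = NULL) {
  dss <- Biostrings::readDNAStringSet(path)
  .assert(length(dss) >= 1, "FASTA contains no sequence")
  if (is.null(seq_start)) {
    nm <- names(dss)[1]
    m <- regmatches(nm, regexec("[:]([0-9]+)-[0-9]+", nm))[[1]]
    seq_start <- if (length(m) == 2) as.numeric(m[2]) else 1
  }
  list(sequence = as.character(dss[[1]]), seq_start = seq_start)
}
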