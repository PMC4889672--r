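#' Construct a genotype panel
#'
#' Per-strain marker genotypes for the NIL panel. Calls are `A` (recipient
#' background, e.g. N2), `B` (donor, e.g. CB4856), `H` (heterozygous) and
#' `N` (missing).
#'
#' @param strain_id Character vector of strain identifiers.
#' @param cross Character vector, `"FaxNIL"` or `"LonNIL"` per strain.
#' @param calls Character matrix, rows = strains, columns = markers (in map
#'   order), entries in `A/B/H/N`.
#' @param map The `marker_map` the calls conform to.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(strain_id, cross, calls, map) {
  calls <- as.matrix(calls)
  .assert(nrow(calls) == length(strain_id), "one row of calls per strain required")
  .assert(ncol(calls) == nrow(map$markers),
          "calls have %d columns but map has %d markers", ncol(calls), nrow(map$markers))
  .assert(all(calls %in% c("A", "B", "H", "N")), "calls must be in {A,B,H,N}")
  .assert(all(cross %in% c("FaxNIL", "LonNIL")), "cross must be FaxNIL or LonNIL")
  rownames(calls) <- strain_id
  structure(list(strain_id = as.character(strain_id), cross = as.character(cross),
                 calls = calls),
            class = "genotype_panel")
}

#' Read a genotype panel from TSV
#'
#' Expects columns `strain_id`, `cross`, then one call column per marker in
#' map order.
#'
#' @param path Path to the TSV file.
#' @param map The corresponding `marker_map`.
#' @return A `genotype_panel`.
#' @export
read_genotypes <- function(path, map) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  .assert(all(c("strain_id", "cross") %in% names(df)[1:2]),
          "genotype file must start with columns 'strain_id', 'cross'")
  calls <- as.matrix(df[, -(1:2), drop = FALSE])
  genotype_panel(df$strain_id, df$cross, calls, map)
}

#' Write a genotype panel to TSV
#' @param panel A `genotype_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path) {
  df <- data.frame(strain_id = panel$strain_id, cross = panel$cross,
                   panel$calls, stringsAsFactors = FALSE, check.names = FALSE)
  colnames(df) <- c("strain_id", "cross",
                    paste0("m", seq_len(ncol(panel$calls))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d strains (%d FaxNIL, %d LonNIL), %d markers\n",
              length(x$strain_id), sum(x$cross == "FaxNIL"),
              sum(x$cross == "LonNIL"), ncol(x$calls)))
  invisible(x)
}

#' Call crossover breakpoints from a genotype panel
#'
#' For each strain the single A/B transition is located; its breakpoint
#' interval runs from the last informative (non-missing) marker before the
#' transition to the first informative marker after it. Strains failing
#' quality control are excluded with a reason code:
#' \describe{
#'   \item{multiple_failures}{more than `max_missing` missing (`N`) calls}
#'   \item{het_stretch}{any heterozygous (`H`) call}
#'   \item{non_recombinant}{no transition (all-A or all-B within the span)}
#'   \item{double_recombinant}{two or more transitions}
#'   \item{ambiguous_at_breakpoint}{with `missing_rule = "drop"`, a
#'     breakpoint whose span covers more than one inter-marker interval}
#' }
#'
#' @param panel A `genotype_panel`.
#' @param map The `marker_map`.
#' @param max_missing Maximum tolerated number of `N` calls per strain.
#' @param missing_rule How breakpoints spanning missing calls are handled
#'   downstream: `"midpoint"` keeps the strain (the crossover is later
#'   assigned by span midpoint), `"drop"` excludes it.
#' @return A list with `crossovers` (data.frame `strain_id`, `cross`,
#'   `left_bound`, `right_bound`, `orientation`) and `qc` (a `qc_report`:
#'   data.frame `excluded` with reason codes and the count `n_retained`).
#' @examples
#' map <- marker_map(c(10, 20, 30, 40, 50, 60),
#'                   c("left", "left", "left", "right", "right", "right"), 35)
#' panel <- genotype_panel("s1", "FaxNIL",
#'                         matrix(c("A","A","A","B","B","B"), 1), map)
#' call_breakpoints(panel, map)$crossovers
#' @export
call_breakpoints <- function(panel, map, max_missing = 2,
                             missing_rule = c("midpoint", "drop")) {
  missing_rule <- match.arg(missing_rule)
  .assert(length(panel$strain_id) > 0, "empty genotype panel")
  pos <- map$markers$position
  res <- vector("list", length(panel$strain_id))
  excl <- list()
  for (i in seq_along(panel$strain_id)) {
    calls <- panel$calls[i, ]
    reason <- NULL
    if (sum(calls == "N") > max_missing) {
      reason <- "multiple_failures"
    } else if (any(calls == "H")) {
      reason <- "het_stretch"
    } else {
      obs <- which(calls %in% c("A", "B"))
      ab <- calls[obs]
      trans <- which(ab[-1] != ab[-length(ab)])
      if (length(trans) == 0) {
        reason <- "non_recombinant"
      } else if (length(trans) > 1) {
        reason <- "double_recombinant"
      } else {
        li <- obs[trans]        # last informative marker before transition
        ri <- obs[trans + 1]    # first informative marker after
        if (missing_rule == "drop" && ri - li > 1) {
          reason <- "ambiguous_at_breakpoint"
        } else {
          res[[i]] <- data.frame(
            strain_id = panel$strain_id[i], cross = panel$cross[i],
            left_bound = pos[li], right_bound = pos[ri],
            orientation = if (ab[1] == "A") "A->B" else "B->A",
            stringsAsFactors = FALSE)
        }
      }
    }
    if (!is.null(reason)) {
      excl[[length(excl) + 1]] <- data.frame(
        strain_id = panel$strain_id[i], reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  crossovers <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(crossovers)) {
    crossovers <- data.frame(strain_id = character(), cross = character(),
                             left_bound = numeric(), right_bound = numeric(),
                             orientation = character(), stringsAsFactors = FALSE)
  }
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(strain_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  qc <- structure(list(excluded = excluded, n_retained = nrow(crossovers),
                       n_input = length(panel$strain_id)),
                  class = "qc_report")
  list(crossovers = crossovers, qc = qc)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d/%d strains retained\n", x$n_retained, x$n_input))
  if (nrow(x$excluded)) print(table(x$excluded$reason))
  invisible(x)
}
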