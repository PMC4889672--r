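#' Construct a crossover count table
#'
#' The central analysis object: per inter-marker interval, the number of
#' crossover breakpoints observed in each of the two reciprocal crosses.
#' Intervals are 1-based half-open `[start, end)` spans between consecutive
#' same-side markers.
#'
#' @param df data.frame with columns `start`, `end`, `side`, `length`,
#'   `count_faxnil`, `count_lonnil`, `masked`.
#' @param resolution `"full"` or `"25kb"`.
#' @param shared_span Numeric length-2 `(start, end)` of the genotyped span.
#' @param indel_position Physical position of the sorting indel.
#' @return An object of class `crossover_table` (a data.frame with
#'   attributes `resolution`, `shared_span`, `indel_position`).
#' @export
crossover_table <- function(df, resolution = c("full", "25kb"),
                            shared_span = c(min(df$start), max(df$end)),
                            indel_position = NA_real_) {
  resolution <- match.arg(resolution)
  need <- c("start", "end", "side", "length", "count_faxnil", "count_lonnil",
            "masked")
  .assert(all(need %in% names(df)), "crossover table needs columns: %s",
          paste(need, collapse = ", "))
  df <- df[need]
  .assert(all(df$end > df$start), "interval end must exceed start")
  .assert(all(df$length == df$end - df$start), "length must equal end - start")
  .assert(all(df$count_faxnil >= 0) && all(df$count_lonnil >= 0),
          "counts must be non-negative")
  for (sd in unique(df$side)) {
    sub <- df[df$side == sd, ]
    sub <- sub[order(sub$start), ]
    .assert(all(sub$start[-1] == sub$end[-nrow(sub)]) || nrow(sub) < 2,
            "intervals must be contiguous within side '%s'", sd)
  }
  df$masked <- as.logical(df$masked)
  structure(df, class = c("crossover_table", "data.frame"),
            resolution = resolution,
            shared_span = as.numeric(shared_span),
            indel_position = as.numeric(indel_position))
}

#' @export
print.crossover_table <- function(x, ...) {
  cat(sprintf(
    "crossover_table [%s]: %d intervals (%d masked), FaxNIL %d + LonNIL %d crossovers\n",
    attr(x, "resolution"), nrow(x), sum(x$masked),
    sum(x$count_faxnil), sum(x$count_lonnil)))
  NextMethod()
}

#' Tabulate called crossovers into inter-marker interval counts
#'
#' Each crossover increments exactly one interval count for its cross. A
#' breakpoint spanning several intervals (because of missing calls) is
#' assigned to the single interval containing the span midpoint; a midpoint
#' falling in the gap straddling the indel is assigned to the terminal
#' interval of the side containing it.
#'
#' @param crossovers data.frame from [call_breakpoints()].
#' @param map The `marker_map`.
#' @return A `crossover_table` at full resolution.
#' @export
tabulate_crossovers <- function(crossovers, map) {
  pos <- map$markers$position
  bad <- !(crossovers$left_bound %in% pos) | !(crossovers$right_bound %in% pos)
  if (any(bad)) {
    stop(sprintf("breakpoint bound not in map for strain %s",
                 crossovers$strain_id[which(bad)[1]]), call. = FALSE)
  }
  iv <- .marker_intervals(map)
  iv$count_faxnil <- 0L
  iv$count_lonnil <- 0L
  if (nrow(crossovers)) {
    mid <- (crossovers$left_bound + crossovers$right_bound) / 2
    for (j in seq_along(mid)) {
      side <- if (mid[j] < map$indel_position) "left" else "right"
      rows <- which(iv$side == side)
      hit <- rows[iv$start[rows] <= mid[j] & mid[j] < iv$end[rows]]
      if (length(hit) == 0) {
        # midpoint in the indel gap (or at the side boundary): terminal interval
        hit <- if (side == "left") rows[which.max(iv$end[rows])] else
          rows[which.min(iv$start[rows])]
      }
      col <- if (crossovers$cross[j] == "FaxNIL") "count_faxnil" else "count_lonnil"
      iv[hit[1], col] <- iv[hit[1], col] + 1L
    }
  }
  iv$masked <- FALSE
  crossover_table(iv, resolution = "full",
                  shared_span = map$shared_span,
                  indel_position = map$indel_position)
}

#' Mask intervals overlapping given regions
#'
#' Masked intervals stay in the table but are excluded from every model fit
#' downstream (uniformity tests, segmentation, Gini, scans). Typical use:
#' tandem-repeat tracts and large strain-specific indels.
#'
#' @param table A `crossover_table`.
#' @param regions data.frame (or 2-column matrix) of `start`, `end` regions,
#'   1-based half-open, all within the table's shared span.
#' @return The table with the `masked` flag updated.
#' @export
mask_intervals <- function(table, regions) {
  if (is.null(regions) || NROW(regions) == 0) return(table)
  regions <- as.data.frame(regions)
  names(regions)[1:2] <- c("start", "end")
  span <- attr(table, "shared_span")
  .assert(all(regions$start >= span[1]) && all(regions$end <= span[2]),
          "mask region outside shared span [%.0f, %.0f]", span[1], span[2])
  for (r in seq_len(nrow(regions))) {
    hit <- table$start < regions$end[r] & table$end > regions$start[r]
    table$masked <- table$masked | hit
  }
  table
}

#' Re-bin a full-resolution table into ~25 kb bins
#'
#' Greedy merge by length: consecutive unmasked intervals within a side are
#' pooled until the cumulative length reaches `target_bp`; a trailing short
#' bin is merged backward. Bins with fewer than `min_events` total crossover
#' events are then merged with their smaller neighbour. Masked intervals
#' break contiguity and are carried through as their own masked bins. Bin
#' boundaries always fall on marker positions.
#'
#' @param table A full-resolution `crossover_table`.
#' @param target_bp Target bin size in bp.
#' @param min_events Minimum total events per bin.
#' @return A `crossover_table` with resolution `"25kb"`.
#' @export
rebin_25kb <- function(table, target_bp = 25000, min_events = 3) {
  .assert(attr(table, "resolution") == "full",
          "rebinning expects a full-resolution table")
  out <- list()
  for (sd in unique(table$side)) {
    sub <- table[table$side == sd, ]
    sub <- sub[order(sub$start), ]
    if (sum(sub$length[!sub$masked]) < target_bp) {
      warning(sprintf("side '%s' has less than %d unmasked bp; single bin", sd,
                      target_bp))
    }
    # split into contiguous unmasked runs, interleaved with masked bins
    run_id <- cumsum(c(TRUE, diff(sub$masked) != 0))
    for (rid in unique(run_id)) {
      blk <- sub[run_id == rid, ]
      if (blk$masked[1]) {
        out[[length(out) + 1]] <- .pool_bins(blk, seq_len(nrow(blk)), masked = TRUE)
        next
      }
      bins <- .greedy_bins(blk$length, target_bp)
      bins <- .enforce_min_events(bins, blk$count_faxnil + blk$count_lonnil,
                                  blk$length, min_events)
      for (b in bins) out[[length(out) + 1]] <- .pool_bins(blk, b, masked = FALSE)
    }
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start), ]
  rownames(df) <- NULL
  crossover_table(df, resolution = "25kb",
                  shared_span = attr(table, "shared_span"),
                  indel_position = attr(table, "indel_position"))
}

# Pool a set of rows of a table block into one bin row.
.pool_bins <- function(blk, idx, masked) {
  data.frame(start = min(blk$start[idx]), end = max(blk$end[idx]),
             side = blk$side[1], length = sum(blk$length[idx]),
             count_faxnil = sum(blk$count_faxnil[idx]),
             count_lonnil = sum(blk$count_lonnil[idx]),
             masked = masked, stringsAsFactors = FALSE)
}

# Greedy accumulation of interval lengths into bins of >= target_bp, the
# trailing short bin merged backward. Returns a list of index vectors.
.greedy_bins <- function(lengths, target_bp) {
  bins <- list()
  cur <- integer(0)
  acc <- 0
  for (i in seq_along(lengths)) {
    cur <- c(cur, i)
    acc <- acc + lengths[i]
    if (acc >= target_bp) {
      bins[[length(bins) + 1]] <- cur
      cur <- integer(0)
      acc <- 0
    }
  }
  if (length(cur)) {
    if (length(bins)) {
      bins[[length(bins)]] <- c(bins[[length(bins)]], cur)
    } else {
      bins[[1]] <- cur
    }
  }
  bins
}

# Merge bins with < min_events total events into the smaller (by pooled
# length) adjacent bin, repeating until all bins qualify or one bin remains.
.enforce_min_events <- function(bins, events, lengths, min_events) {
  repeat {
    ev <- vapply(bins, function(b) sum(events[b]), numeric(1))
    ln <- vapply(bins, function(b) sum(lengths[b]), numeric(1))
    low <- which(ev < min_events)
    if (length(low) == 0 || length(bins) == 1) return(bins)
    i <- low[1]
    nb <- c(if (i > 1) i - 1L, if (i < length(bins)) i + 1L)
    j <- nb[which.min(ln[nb])]
    a <- min(i, j); b <- max(i, j)
    bins[[a]] <- c(bins[[a]], bins[[b]])
    bins[[b]] <- NULL
  }
}

#' Read / write crossover count tables
#'
#' TSV with header
#' `start end side length count_faxnil count_lonnil masked` (tab-separated).
#' A pre-binned table (e.g. a supplementary 25 kb table) can be read
#' directly with `resolution = "25kb"`, bypassing [rebin_25kb()].
#'
#' @param path Path to the TSV file.
#' @param resolution Resolution label of the stored table.
#' @param indel_position Optional indel position; inferred as the boundary
#'   between the last left and first right interval when `NA`.
#' @return A `crossover_table`.
#' @export
read_crossover_table <- function(path, resolution = c("full", "25kb"),
                                 indel_position = NA_real_) {
  resolution <- match.arg(resolution)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$masked <- as.logical(df$masked)
  if (is.na(indel_position) && all(c("left", "right") %in% df$side)) {
    indel_position <- (max(df$end[df$side == "left"]) +
                         min(df$start[df$side == "right"])) / 2
  }
  crossover_table(df, resolution = resolution,
                  indel_position = indel_position)
}

#' @rdname read_crossover_table
#' @param table A `crossover_table` to write.
#' @export
write_crossover_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Unmasked rows of a table, optionally restricted to one side, in physical
# order. Used by every model-fitting stage.
.unmasked <- function(table, side = c("both", "left", "right")) {
  side <- match.arg(side)
  sub <- table[!table$masked, , drop = FALSE]
  if (side != "both") sub <- sub[sub$side == side, , drop = FALSE]
  sub[order(sub$start), , drop = FALSE]
}
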