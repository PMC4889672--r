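#' Construct a marker map
#'
#' A marker map holds the ordered physical positions of the genotyping SNPs,
#' the side of the sorting indel each marker lies on, and the indel position
#' itself. Crossover breakpoints are localized to the intervals between
#' consecutive same-side markers.
#'
#' @param positions Integer vector of 1-based physical marker positions,
#'   strictly increasing.
#' @param sides Character vector, one of `"left"`/`"right"` per marker.
#' @param indel_position Physical position of the sorting indel. If `NULL`,
#'   the midpoint of the gap between the last left and first right marker.
#' @return An object of class `marker_map`: a list with elements `markers`
#'   (data.frame `position`, `side`), `indel_position` and `shared_span`.
#' @examples
#' marker_map(c(100, 200, 900), c("left", "left", "right"), indel_position = 500)
#' @export
marker_map <- function(positions, sides, indel_position = NULL) {
  .assert(length(positions) == length(sides), "positions and sides differ in length")
  .assert(all(sides %in% c("left", "right")), "sides must be 'left' or 'right'")
  positions <- as.numeric(positions)
  .assert(all(is.finite(positions)) && all(positions > 0),
          "marker positions must be positive numbers")
  bad <- which(diff(positions) <= 0)
  if (length(bad)) {
    stop(sprintf("positions not increasing at row %d (%.0f >= %.0f)",
                 bad[1] + 1, positions[bad[1]], positions[bad[1] + 1]), call. = FALSE)
  }
  .assert(sum(sides == "left") >= 2 && sum(sides == "right") >= 2,
          "need at least 2 markers on each side of the indel")
  max_left <- max(positions[sides == "left"])
  min_right <- min(positions[sides == "right"])
  .assert(max_left < min_right, "left-side markers must all precede right-side markers")
  if (is.null(indel_position)) {
    indel_position <- (max_left + min_right) / 2
  }
  .assert(indel_position > max_left && indel_position < min_right,
          "side labels inconsistent with indel position %.0f", indel_position)
  structure(
    list(
      markers = data.frame(position = positions, side = sides,
                           stringsAsFactors = FALSE),
      indel_position = as.numeric(indel_position),
      shared_span = c(start = positions[1], end = positions[length(positions)])
    ),
    class = "marker_map"
  )
}

#' Read a marker map from a TSV file
#'
#' Expects a header `position<TAB>side`. Coordinates are 1-based physical
#' positions.
#'
#' @param path Path to the TSV file.
#' @param indel_position Optional indel position (see [marker_map()]).
#' @return A `marker_map`.
#' @export
read_marker_map <- function(path, indel_position = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("position", "side") %in% names(df)),
          "marker map file must have columns 'position' and 'side'")
  marker_map(df$position, df$side, indel_position = indel_position)
}

#' Write a marker map to TSV
#' @param map A `marker_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(map$markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("marker_map: %d markers (%d left, %d right), span %.0f-%.0f, indel %.0f\n",
              nrow(x$markers), sum(x$markers$side == "left"),
              sum(x$markers$side == "right"),
              x$shared_span[1], x$shared_span[2], x$indel_position))
  invisible(x)
}

# Inter-marker intervals between consecutive same-side markers, 1-based
# half-open [start, end), in physical order.
.marker_intervals <- function(map) {
  out <- lapply(c("left", "right"), function(sd) {
    p <- map$markers$position[map$markers$side == sd]
    if (length(p) < 2) return(NULL)
    data.frame(start = p[-length(p)], end = p[-1], side = sd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$length <- out$end - out$start
  out
}
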