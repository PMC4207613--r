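#' Bin nuclei into consecutive columns along the gonad axis
#'
#' Gonad scoring proceeds column-by-column: consecutive equal-width bins
#' from the start of the span. Each record falls in exactly one column
#' (half-open bins, last bin closed at the span end).
#'
#' @param axial_pos numeric vector of positions (any consistent axial unit).
#' @param column_width bin width in the same unit.
#' @param span numeric length-2 `(start, end)`; defaults to `c(0, 1)` for
#'   normalised positions.
#' @return list with `column` (1-based index per record), `n_columns`,
#'   `left`/`right` (column edges), `centre` (column centres).
#' @export
columnize <- function(axial_pos, column_width, span = c(0, 1)) {
  stopifnot(length(span) == 2L, span[2] > span[1], column_width > 0)
  if (any(axial_pos < span[1]) || any(axial_pos > span[2]))
    stop("positions outside the span", call. = FALSE)
  n_col <- max(1L, ceiling((span[2] - span[1]) / column_width - 1e-9))
  col <- pmin(floor((axial_pos - span[1]) / column_width), n_col - 1) + 1L
  left <- span[1] + (seq_len(n_col) - 1) * column_width
  right <- pmin(left + column_width, span[2])
  list(column = col, n_columns = n_col, left = left, right = right,
       centre = (left + right) / 2)
}

#' Strict-majority marker state per column
#'
#' A column is positive when more than half of its nuclei are positive for
#' the marker (a tie is not a majority). Columns with no nuclei inherit the
#' state of the previous column; a leading empty column is negative.
#'
#' @param column integer column index per record (from [columnize()]).
#' @param marker logical marker state per record.
#' @param n_columns total number of columns.
#' @return logical vector, one state per column.
#' @export
column_majority <- function(column, marker, n_columns) {
  stopifnot(length(column) == length(marker))
  state <- logical(n_columns)
  prev <- FALSE
  for (j in seq_len(n_columns)) {
    in_col <- column == j
    n <- sum(in_col)
    state[j] <- if (n == 0) prev else sum(marker[in_col]) > n / 2
    prev <- state[j]
  }
  state
}

#' Extent of a marker-positive region as a percentage of meiotic length
#'
#' Measures the marker-positive span by the column rule: the region starts
#' at the first positive column and ends with the first contiguous run of
#' positive columns; its length is divided by the meiotic length, from the
#' start point to the beginning of cellularization. When a dedicated start
#' point (e.g. transition-zone entry) exists it overrides the first
#' positive column. Later positive runs (marker reappearing proximally) do
#' not extend the measured span but are recorded in `later_runs`.
#'
#' @param per_column logical vector of per-column marker states.
#' @param left,right column edges (same axial unit), as from [columnize()].
#' @param cellularization_pos axial position where cellularization begins.
#' @param start_pos optional start point overriding the first positive
#'   column's left edge.
#' @return an object of class `progression_result`: `start_pos`,
#'   `end_pos`, `cellularization_pos`, `fraction` (percent of meiotic
#'   length), `per_column`, `later_runs` (data frame of additional runs).
#' @export
extent_fraction <- function(per_column, left, right, cellularization_pos,
                            start_pos = NULL) {
  stopifnot(length(per_column) == length(left),
            length(left) == length(right))
  pos_cols <- which(per_column)
  if (length(pos_cols) == 0) {
    start <- if (is.null(start_pos)) left[1] else start_pos
    if (cellularization_pos <= start)
      stop("cellularization precedes the start point", call. = FALSE)
    res <- list(start_pos = start, end_pos = start,
                cellularization_pos = cellularization_pos, fraction = 0,
                per_column = per_column,
                later_runs = data.frame(from = numeric(), to = numeric()))
    class(res) <- "progression_result"
    return(res)
  }
  first <- pos_cols[1]
  run_end <- first
  while (run_end < length(per_column) && per_column[run_end + 1]) {
    run_end <- run_end + 1
  }
  start <- if (is.null(start_pos)) left[first] else start_pos
  end <- right[run_end]
  if (cellularization_pos <= start)
    stop("cellularization precedes the start point", call. = FALSE)
  end <- min(end, cellularization_pos)
  frac <- 100 * (end - start) / (cellularization_pos - start)

  # record any positive runs beyond the measured span
  later <- data.frame(from = numeric(), to = numeric())
  j <- run_end + 1
  while (j <= length(per_column)) {
    if (per_column[j]) {
      k <- j
      while (k < length(per_column) && per_column[k + 1]) k <- k + 1
      later <- rbind(later, data.frame(from = left[j], to = right[k]))
      j <- k + 1
    } else j <- j + 1
  }
  res <- list(start_pos = start, end_pos = end,
              cellularization_pos = cellularization_pos,
              fraction = frac, per_column = per_column, later_runs = later)
  class(res) <- "progression_result"
  res
}

#' @export
print.progression_result <- function(x, ...) {
  cat(sprintf(
    "Marker-positive extent: %.1f%% of meiotic length (%.3g to %.3g, cellularization at %.3g)\n",
    x$fraction, x$start_pos, x$end_pos, x$cellularization_pos))
  if (nrow(x$later_runs) > 0)
    cat("  note:", nrow(x$later_runs),
        "additional positive run(s) beyond the measured span\n")
  invisible(x)
}

#' Marker-positive extent from per-nucleus records
#'
#' Convenience wrapper: columnize the records, apply the strict-majority
#' rule to the named marker column, and measure the extent.
#'
#' @param records data frame with `axial_pos` and a logical marker column.
#' @param marker name of the marker column (e.g. `"sun1_ser8p"` or
#'   `"crescent_morphology"`).
#' @param column_width column width in axial units.
#' @param cellularization_pos axial position of cellularization onset.
#' @param span axial span of the gonad, default `c(0, 1)`.
#' @param start_pos optional start override (transition-zone entry).
#' @return a `progression_result` (see [extent_fraction()]).
#' @export
progression_extent <- function(records, marker, column_width,
                               cellularization_pos = 1, span = c(0, 1),
                               start_pos = NULL) {
  stopifnot(is.data.frame(records), marker %in% names(records),
            "axial_pos" %in% names(records))
  cols <- columnize(records$axial_pos, column_width, span)
  state <- column_majority(cols$column, as.logical(records[[marker]]),
                           cols$n_columns)
  extent_fraction(state, cols$left, cols$right, cellularization_pos,
                  start_pos)
}
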