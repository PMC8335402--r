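#' RR-interval series
#'
#' Construct a validated series of inter-beat (RR) intervals in
#' milliseconds. All HRV metrics in the package operate on this class.
#'
#' @param intervals Numeric vector of inter-beat intervals, ms. Every value
#'   must be finite and strictly positive.
#' @param subject_id Opaque subject label (scalar, coerced to character).
#' @param recorded_at Optional timestamp (kept as-is, not interpreted).
#'
#' @return An object of class `rr_series`: the numeric interval vector with
#'   `subject_id` and `recorded_at` attributes.
#' @examples
#' rr <- rr_series(c(800, 810, 790, 820, 800), subject_id = "s01")
#' avnn(rr)
#' @export
rr_series <- function(intervals, subject_id = "unknown", recorded_at = NULL) {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0L) {
    stop("empty series: an rr_series needs at least one interval", call. = FALSE)
  }
  if (anyNA(intervals) || any(!is.finite(intervals))) {
    stop("all RR intervals must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (any(intervals <= 0)) {
    stop("all RR intervals must be > 0 ms", call. = FALSE)
  }
  structure(intervals,
            subject_id = as.character(subject_id)[1],
            recorded_at = recorded_at,
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> subject=%s  n=%d  mean=%.1f ms\n",
              attr(x, "subject_id"), length(x), mean(unclass(x))))
  invisible(x)
}

#' Remove physiologically implausible RR intervals
#'
#' Keeps only the intervals inside the plausibility window `[lo, hi]`
#' (both ends inclusive) and records how many were removed. Artifact
#' handling beyond this window filter (ectopic-beat interpolation etc.)
#' is deliberately out of scope.
#'
#' @param rr An [rr_series()].
#' @param lo,hi Window bounds in ms. Defaults 300 and 2000 ms.
#' @return The filtered `rr_series` with an integer attribute `n_removed`.
#'   Errors if every interval is removed.
#' @examples
#' rr <- rr_series(c(800, 810, 5000, 790))
#' cleaned <- clean_rr(rr)
#' attr(cleaned, "n_removed")  # 1
#' @export
clean_rr <- function(rr, lo = 300, hi = 2000) {
  stopifnot(inherits(rr, "rr_series"), lo > 0, hi > lo)
  x <- unclass(rr)
  keep <- x >= lo & x <= hi
  if (!any(keep)) {
    stop("empty series: cleaning removed all intervals", call. = FALSE)
  }
  out <- rr_series(x[keep],
                   subject_id = attr(rr, "subject_id"),
                   recorded_at = attr(rr, "recorded_at"))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Read an RR series from plain text
#'
#' One interval (ms, integer or decimal) per line; lines starting with `#`
#' and blank lines are ignored.
#'
#' @param path File path.
#' @param subject_id Subject label; defaults to the file name without
#'   extension.
#' @return An [rr_series()].
#' @export
read_rr <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("RR file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    stop("non-numeric RR value in ", path, " (line ",
         which(is.na(vals))[1], " of data lines)", call. = FALSE)
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  rr_series(vals, subject_id = subject_id)
}

#' Read an RR series from a CSV column
#'
#' @param path CSV file with a header row.
#' @param column Name of the column holding intervals in ms.
#' @param subject_id Subject label; defaults to the file name.
#' @return An [rr_series()].
#' @export
read_rr_csv <- function(path, column = "rr_ms", subject_id = NULL) {
  if (!file.exists(path)) stop("RR file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!column %in% names(df)) {
    stop("column '", column, "' not found in ", path, call. = FALSE)
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  rr_series(df[[column]], subject_id = subject_id)
}

#' Write an RR series as plain text
#'
#' @param rr An [rr_series()].
#' @param path Output path, one interval per line.
#' @export
write_rr <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  writeLines(format(unclass(rr), trim = TRUE, scientific = FALSE), path)
  invisible(path)
}
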