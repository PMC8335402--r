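#' Age-referenced SDNN normative table
#'
#' Holds the "theoretical SDNN by age" used to score the SDNN deviation.
#' Bands are half-open `[age_lo, age_hi)`; the final band is closed so the
#' configured support is fully covered. The normative values themselves
#' are data, not constants: the package ships only a clearly labelled
#' synthetic default (see `inst/extdata/sdnn_norms_synthetic.yaml`) that
#' an operator must confirm or replace against their chosen normative
#' reference before interpreting deviations.
#'
#' @param entries Data frame with columns `age_lo`, `age_hi`,
#'   `sdnn_norm_ms` (years, years, ms). Bands must be non-overlapping,
#'   contiguous and have positive norms.
#' @param source_label Free-text provenance label recording where the
#'   values come from.
#' @return A `norm_table` object.
#' @export
norm_table <- function(entries, source_label = "unspecified") {
  need <- c("age_lo", "age_hi", "sdnn_norm_ms")
  if (!all(need %in% names(entries))) {
    stop("norm table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  entries <- entries[order(entries$age_lo), need]
  if (any(entries$sdnn_norm_ms <= 0)) {
    stop("normative SDNN values must be > 0", call. = FALSE)
  }
  if (any(entries$age_hi <= entries$age_lo)) {
    stop("each band needs age_hi > age_lo", call. = FALSE)
  }
  if (nrow(entries) > 1L &&
      any(abs(entries$age_lo[-1] - entries$age_hi[-nrow(entries)]) > 1e-9)) {
    stop("age bands must be contiguous and non-overlapping", call. = FALSE)
  }
  structure(list(entries = entries, source_label = source_label),
            class = "norm_table")
}

#' @export
print.norm_table <- function(x, ...) {
  cat(sprintf("<norm_table> %d band(s), source: %s\n",
              nrow(x$entries), x$source_label))
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Load a normative table from YAML
#'
#' Expected layout:
#' ```yaml
#' source_label: "..."
#' bands:
#'   - {age_lo: 17, age_hi: 30, sdnn_norm_ms: 52}
#'   - {age_lo: 30, age_hi: 70, sdnn_norm_ms: 44}
#' ```
#'
#' @param path YAML file path.
#' @return A [norm_table()]; coverage and positivity are validated.
#' @export
load_norm_table <- function(path) {
  if (!file.exists(path)) stop("norm table not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$bands)) stop("norm table YAML needs a 'bands' list", call. = FALSE)
  entries <- do.call(rbind, lapply(raw$bands, function(b) {
    data.frame(age_lo = as.numeric(b$age_lo), age_hi = as.numeric(b$age_hi),
               sdnn_norm_ms = as.numeric(b$sdnn_norm_ms))
  }))
  norm_table(entries, source_label = raw$source_label %||% "unspecified")
}

#' The package's bundled synthetic default normative table
#'
#' A placeholder table spanning ages 17-70. Its values are synthetic
#' round numbers in the physiological ballpark, not a published norm;
#' replace them with the normative reference your study uses.
#'
#' @return A [norm_table()].
#' @export
default_norm_table <- function() {
  load_norm_table(system.file("extdata", "sdnn_norms_synthetic.yaml",
                              package = "hrvfatigue", mustWork = TRUE))
}

#' Look up the normative SDNN for an age
#'
#' @param age Age in years, inside the table's support.
#' @param table A [norm_table()].
#' @return Normative SDNN in ms. Ages outside the support raise an
#'   explicit error; there is no extrapolation.
#' @export
sdnn_norm <- function(age, table) {
  stopifnot(inherits(table, "norm_table"))
  e <- table$entries
  lo <- e$age_lo[1]; hi <- e$age_hi[nrow(e)]
  if (!is.finite(age) || age < lo || age > hi) {
    stop(sprintf("no normative value: age %s outside table support [%s, %s]",
                 format(age), format(lo), format(hi)), call. = FALSE)
  }
  # bands closed on the left, open on the right; final band closed
  i <- findInterval(age, e$age_lo)
  if (age == hi) i <- nrow(e)
  e$sdnn_norm_ms[i]
}

#' SDNN deviation from the age norm
#'
#' Observed SDNN minus the normative SDNN for the subject's age; positive
#' values mean higher-than-expected global HRV.
#'
#' @param sdnn Observed SDNN, ms.
#' @param age Age in years.
#' @param table A [norm_table()].
#' @return Deviation in ms.
#' @export
sdnn_deviation <- function(sdnn, age, table) {
  sdnn - sdnn_norm(age, table)
}

#' Classify the SDNN deviation
#'
#' Deviations strictly above zero are "high"; everything else is "low".
#' A deviation of exactly zero therefore falls to "low" (only positive
#' deviations qualify as high); set `zero_as = "high"` to flip that
#' convention.
#'
#' @param deviation SDNN deviation in ms (finite).
#' @param zero_as Label for a deviation of exactly 0 (default `"low"`).
#' @return `"high"` or `"low"` (vectorized).
#' @export
classify_sdnn <- function(deviation, zero_as = c("low", "high")) {
  zero_as <- match.arg(zero_as)
  if (any(!is.finite(deviation))) stop("deviation must be finite", call. = FALSE)
  out <- ifelse(deviation > 0, "high", "low")
  if (zero_as == "high") out[deviation == 0] <- "high"
  out
}
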