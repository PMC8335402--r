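#' Fatigue quadrant labels
#'
#' The four joint categories of Stroop speed (fast/slow at the 500 ms
#' mean-RT cutoff) and SDNN level (high/low versus the age norm), in
#' canonical order: fast_low is category 1.
#'
#' @return Character vector of the four level codes in canonical order.
#' @export
quadrant_levels <- function() {
  c("fast_low", "fast_high", "slow_low", "slow_high")
}

#' Display names for the quadrants
#'
#' @return Named character vector mapping level codes to display names.
#' @export
quadrant_display <- function() {
  c(fast_low  = "Fast stroop - Low SDNN",
    fast_high = "Fast stroop - High SDNN",
    slow_low  = "Slow stroop - Low SDNN",
    slow_high = "Slow stroop - High SDNN")
}

#' Assign a fatigue quadrant
#'
#' @param speed `"fast"` or `"slow"` (from [classify_speed()]).
#' @param level `"high"` or `"low"` (from [classify_sdnn()]).
#' @return Factor with the four quadrant levels (vectorized; `NA` inputs
#'   propagate to `NA` labels).
#' @examples
#' assign_quadrant("fast", "low")   # fast_low
#' assign_quadrant("slow", "high")  # slow_high
#' @export
assign_quadrant <- function(speed, level) {
  ok_s <- speed %in% c("fast", "slow") | is.na(speed)
  ok_l <- level %in% c("high", "low") | is.na(level)
  if (!all(ok_s) || !all(ok_l)) {
    stop("speed must be fast/slow and level high/low", call. = FALSE)
  }
  code <- ifelse(is.na(speed) | is.na(level), NA_character_,
                 paste(speed, level, sep = "_"))
  factor(code, levels = quadrant_levels())
}

#' Quadrant frequency table
#'
#' Tabulates quadrant labels with valid and cumulative percentages in the
#' canonical order. Valid percentages are `100 * count / total` rounded
#' to one decimal. Cumulative percentages are computed from the raw
#' cumulative counts and then rounded (not by summing rounded row
#' percentages), so the running total stays faithful to the raw counts.
#' `NA` labels (sessions missing a Stroop or SDNN measurement) are
#' excluded from the table and surfaced in the `n_missing` attribute.
#'
#' @param labels Factor/character vector of quadrant labels (may contain
#'   `NA`), or `NULL` when `counts` is given.
#' @param counts Optional named or positional integer vector of the four
#'   per-quadrant counts in canonical order, as an alternative to raw
#'   labels.
#' @return Data frame with columns `quadrant`, `display`, `n`,
#'   `valid_pct`, `cum_pct`, plus attributes `total` and `n_missing`.
#' @examples
#' quadrant_table(counts = c(186, 370, 150, 169))
#' @export
quadrant_table <- function(labels = NULL, counts = NULL) {
  lev <- quadrant_levels()
  if (is.null(counts)) {
    if (is.null(labels) || length(labels) == 0L) {
      stop("empty input: no quadrant labels to tabulate", call. = FALSE)
    }
    labels <- factor(as.character(labels), levels = lev)
    n_missing <- sum(is.na(labels))
    counts <- as.integer(table(labels))
    if (sum(counts) == 0L) {
      stop("empty input: all labels missing", call. = FALSE)
    }
  } else {
    if (length(counts) != 4L) stop("counts must have length 4", call. = FALSE)
    if (!is.null(names(counts))) counts <- counts[lev]
    counts <- as.integer(counts)
    n_missing <- 0L
  }
  total <- sum(counts)
  cum_counts <- cumsum(counts)
  out <- data.frame(quadrant = lev,
                    display = unname(quadrant_display()[lev]),
                    n = counts,
                    valid_pct = round(100 * counts / total, 1),
                    cum_pct = round(100 * cum_counts / total, 1),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- total
  attr(out, "n_missing") <- n_missing
  out
}

#' Write a quadrant table as CSV
#'
#' Mirrors the frequency / valid % / cumulative % layout and appends a
#' footer row carrying the excluded (missing-label) count so attrition is
#' always visible alongside the tabulated total.
#'
#' @param tab Output of [quadrant_table()].
#' @param path CSV path.
#' @export
write_quadrant_table <- function(tab, path) {
  footer <- data.frame(quadrant = c("total", "missing"),
                       display = c("Total", "Excluded (missing measurement)"),
                       n = c(attr(tab, "total"), attr(tab, "n_missing")),
                       valid_pct = c(100.0, NA_real_),
                       cum_pct = c(NA_real_, NA_real_),
                       stringsAsFactors = FALSE)
  utils::write.csv(rbind(tab, footer), path, row.names = FALSE, na = "")
  invisible(path)
}
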