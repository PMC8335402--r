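#' Time-domain HRV metrics
#'
#' The five classical time-domain heart-rate-variability statistics
#' computed from an RR-interval series: AVNN (mean NN interval), SDNN
#' (standard deviation of NN intervals), RMSSD (root mean square of
#' successive differences), pNN50 (percentage of successive differences
#' exceeding 50 ms) and heart rate (60000 / AVNN).
#'
#' SDNN uses the sample (n-1) denominator by default; pNN50 counts
#' strictly greater than 50 ms over the n-1 successive differences. Both
#' conventions are the statistical defaults for short recordings.
#'
#' @param rr An [rr_series()].
#' @param sample Logical; `TRUE` (default) uses the n-1 denominator for
#'   SDNN, `FALSE` the population n denominator.
#' @return A numeric scalar (ms for `avnn`/`sdnn`/`rmssd`, percent for
#'   `pnn50`, beats/min for `heart_rate`).
#' @examples
#' rr <- rr_series(c(800, 810, 790, 820, 800))
#' avnn(rr)   # 804
#' rmssd(rr)  # sqrt((10^2 + 20^2 + 30^2 + 20^2) / 4)
#' @name hrv_metrics
NULL

#' @rdname hrv_metrics
#' @export
avnn <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  mean(unclass(rr))
}

#' @rdname hrv_metrics
#' @export
sdnn <- function(rr, sample = TRUE) {
  stopifnot(inherits(rr, "rr_series"))
  x <- unclass(rr)
  n <- length(x)
  if (n < 2L) stop("sdnn needs at least 2 intervals", call. = FALSE)
  ss <- sum((x - mean(x))^2)
  sqrt(ss / (if (sample) n - 1L else n))
}

#' @rdname hrv_metrics
#' @export
rmssd <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  x <- unclass(rr)
  if (length(x) < 2L) stop("rmssd needs at least 2 intervals", call. = FALSE)
  d <- diff(x)
  sqrt(mean(d^2))
}

#' @rdname hrv_metrics
#' @export
pnn50 <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  x <- unclass(rr)
  if (length(x) < 2L) stop("pnn50 needs at least 2 intervals", call. = FALSE)
  d <- abs(diff(x))
  100 * sum(d > 50) / length(d)
}

#' @rdname hrv_metrics
#' @export
heart_rate <- function(rr) {
  m <- avnn(rr)
  if (m <= 0) stop("heart rate undefined: mean interval <= 0", call. = FALSE)
  60000 / m
}

#' Baevsky-type stress index
#'
#' Histogram-based sympathetic-tone index AMo / (2 * VR * Mo). Intervals
#' are binned into fixed-width bins whose left edges sit at multiples of
#' `bin_width` starting from 0. Mo is the midpoint of the modal bin in
#' seconds (modal-bin ties resolve to the lowest bin); AMo is the
#' percentage of intervals falling in the modal bin; VR is the
#' variational range max - min in seconds.
#'
#' @param rr An [rr_series()].
#' @param bin_width Histogram bin width in ms (default 50).
#' @return A list with components `amo` (percent), `mo` (s), `vr` (s) and
#'   `stress` (dimensionless).
#' @examples
#' set.seed(1)
#' rr <- rr_series(round(rnorm(300, 800, 60)))
#' baevsky_stress(rr)$stress
#' @export
baevsky_stress <- function(rr, bin_width = 50) {
  stopifnot(inherits(rr, "rr_series"))
  x <- unclass(rr)
  if (length(x) < 2L) stop("stress index needs at least 2 intervals", call. = FALSE)
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  vr_ms <- max(x) - min(x)
  if (vr_ms == 0) {
    stop("undefined stress index: variational range is 0 (constant series)",
         call. = FALSE)
  }
  bins <- floor(x / bin_width)                # left edge anchored at 0
  counts <- table(bins)
  modal_bin <- as.numeric(names(counts)[which.max(counts)])  # ties -> lowest
  amo <- 100 * max(counts) / length(x)
  mo_s <- (modal_bin * bin_width + bin_width / 2) / 1000
  vr_s <- vr_ms / 1000
  list(amo = amo, mo = mo_s, vr = vr_s,
       stress = amo / (2 * vr_s * mo_s))
}

#' Full HRV summary for one RR series
#'
#' Computes all time-domain metrics plus the stress-index components.
#' When the stress index is undefined (constant series), its components
#' are returned as `NA` rather than raising.
#'
#' @param rr An [rr_series()].
#' @param bin_width Stress-index histogram bin width in ms.
#' @return One-row data frame with columns `subject_id`, `n_intervals`,
#'   `avnn_ms`, `sdnn_ms`, `rmssd_ms`, `pnn50_pct`, `hr_bpm`, `amo_pct`,
#'   `mo_s`, `vr_s`, `stress`.
#' @export
hrv_summary <- function(rr, bin_width = 50) {
  stopifnot(inherits(rr, "rr_series"))
  if (length(rr) < 2L) stop("HRV summary needs at least 2 intervals", call. = FALSE)
  st <- tryCatch(baevsky_stress(rr, bin_width = bin_width),
                 error = function(e) list(amo = NA_real_, mo = NA_real_,
                                          vr = NA_real_, stress = NA_real_))
  data.frame(subject_id = attr(rr, "subject_id"),
             n_intervals = length(rr),
             avnn_ms = avnn(rr),
             sdnn_ms = sdnn(rr),
             rmssd_ms = rmssd(rr),
             pnn50_pct = pnn50(rr),
             hr_bpm = heart_rate(rr),
             amo_pct = st$amo,
             mo_s = st$mo,
             vr_s = st$vr,
             stress = st$stress,
             stringsAsFactors = FALSE)
}

#' Write HRV summaries to CSV
#'
#' One row per subject, fixed header matching [hrv_summary()].
#'
#' @param summaries Data frame of stacked [hrv_summary()] rows.
#' @param path Output CSV path.
#' @export
write_hrv_summary <- function(summaries, path) {
  expected <- c("subject_id", "n_intervals", "avnn_ms", "sdnn_ms",
                "rmssd_ms", "pnn50_pct", "hr_bpm", "amo_pct", "mo_s",
                "vr_s", "stress")
  if (!all(expected %in% names(summaries))) {
    stop("summary frame is missing columns: ",
         paste(setdiff(expected, names(summaries)), collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(summaries[expected], path, row.names = FALSE)
  invisible(path)
}
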