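#' Default Stroop color palette
#'
#' @return Character vector of the four stimulus colors.
#' @export
stroop_palette <- function() c("red", "green", "blue", "yellow")

#' Generate a Stroop stimulus schedule
#'
#' Builds `n` color-word stimuli with a controlled proportion of congruent
#' trials (word and ink color match). Incongruent trials pair a word with
#' a different ink color. The schedule is shuffled; given the same seed it
#' is fully reproducible.
#'
#' @param n Number of stimuli (default 35).
#' @param congruent_prop Fraction of congruent trials in `[0, 1]`;
#'   `round(n * congruent_prop)` trials are congruent.
#' @param palette Character vector of at least 2 colors.
#' @param seed Integer seed.
#' @return Data frame with columns `index`, `word`, `ink`, `congruent`.
#' @examples
#' stim <- generate_stroop_stimuli(35, congruent_prop = 0.8, seed = 1)
#' sum(stim$congruent)  # 28
#' @export
generate_stroop_stimuli <- function(n = 35, congruent_prop = 0.8,
                                    palette = stroop_palette(), seed) {
  if (length(palette) < 2L) stop("palette needs at least 2 colors", call. = FALSE)
  if (congruent_prop < 0 || congruent_prop > 1) {
    stop("congruent_prop must be in [0, 1]", call. = FALSE)
  }
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (missing(seed)) stop("seed is required for a reproducible schedule", call. = FALSE)
  set.seed(as.integer(seed))
  n_con <- round(n * congruent_prop)
  word <- sample(palette, n, replace = TRUE)
  ink <- character(n)
  is_con <- sample(rep(c(TRUE, FALSE), c(n_con, n - n_con)))
  for (i in seq_len(n)) {
    ink[i] <- if (is_con[i]) word[i] else sample(setdiff(palette, word[i]), 1)
  }
  data.frame(index = seq_len(n), word = word, ink = ink,
             congruent = word == ink, stringsAsFactors = FALSE)
}

#' Assemble a Stroop session from stimuli and responses
#'
#' @param stimuli Data frame from [generate_stroop_stimuli()] (columns
#'   `index`, `word`, `ink`, `congruent`).
#' @param answer Character vector of chosen colors, one per stimulus.
#' @param rt Numeric vector of reaction times in ms, all > 0.
#' @param n_stimuli Expected session length (default 35); a session with a
#'   different number of responses is rejected as incomplete.
#' @return A `stroop_session` data frame with columns `index`, `word`,
#'   `ink`, `congruent`, `answer`, `rt_ms`, `correct` and a logical
#'   `anticipation` flag for responses under 100 ms (flagged, never
#'   excluded).
#' @export
stroop_session <- function(stimuli, answer, rt, n_stimuli = 35) {
  if (nrow(stimuli) != n_stimuli) {
    stop(sprintf("incomplete session: %d stimuli, expected %d (missing %d)",
                 nrow(stimuli), n_stimuli, n_stimuli - nrow(stimuli)),
         call. = FALSE)
  }
  stopifnot(length(answer) == nrow(stimuli), length(rt) == nrow(stimuli))
  if (any(!is.finite(rt)) || any(rt <= 0)) {
    stop("all reaction times must be finite and > 0 ms", call. = FALSE)
  }
  out <- data.frame(index = stimuli$index, word = stimuli$word,
                    ink = stimuli$ink, congruent = stimuli$congruent,
                    answer = answer, rt_ms = as.numeric(rt),
                    correct = answer == stimuli$ink,
                    anticipation = rt < 100,
                    stringsAsFactors = FALSE)
  class(out) <- c("stroop_session", "data.frame")
  attr(out, "n_stimuli") <- n_stimuli
  out
}

check_session <- function(session) {
  if (!inherits(session, "stroop_session")) {
    stop("expected a stroop_session", call. = FALSE)
  }
  n_expected <- attr(session, "n_stimuli") %||% 35
  if (nrow(session) != n_expected) {
    stop(sprintf("incomplete session: %d responses, expected %d (missing %d)",
                 nrow(session), n_expected, n_expected - nrow(session)),
         call. = FALSE)
  }
  invisible(session)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean reaction time of a Stroop session
#'
#' Error trials are included in the mean by default: the published metric
#' is the plain average click time over all 35 stimuli, and weighting by
#' accuracy is explicitly left as future work. `correct_only = TRUE`
#' gives the optional accuracy-filtered mean.
#'
#' @param session A [stroop_session()].
#' @param correct_only Average only the correct trials (default `FALSE`).
#' @return Mean reaction time in ms.
#' @export
mean_rt <- function(session, correct_only = FALSE) {
  check_session(session)
  rt <- if (correct_only) session$rt_ms[session$correct] else session$rt_ms
  if (length(rt) == 0L) stop("no trials to average", call. = FALSE)
  mean(rt)
}

#' Stroop accuracy
#'
#' @param session A [stroop_session()].
#' @return Fraction of correct responses in `[0, 1]`.
#' @export
stroop_accuracy <- function(session) {
  check_session(session)
  sum(session$correct) / nrow(session)
}

#' Per-congruency mean reaction times
#'
#' The quadrant rule uses only the overall mean; the congruent and
#' incongruent means are reported as additional descriptives.
#'
#' @param session A [stroop_session()].
#' @return Named numeric vector `c(congruent = ..., incongruent = ...)`
#'   (`NaN` where a trial type is absent).
#' @export
mean_rt_by_congruency <- function(session) {
  check_session(session)
  c(congruent = mean(session$rt_ms[session$congruent]),
    incongruent = mean(session$rt_ms[!session$congruent]))
}

#' Classify Stroop speed against the 500 ms cutoff
#'
#' Mean reaction times under the cutoff are "fast"; times at or above it
#' are "slow" (the boundary value itself is slow).
#'
#' @param mean_rt Mean reaction time, ms, > 0.
#' @param cutoff Cutoff in ms (default 500).
#' @return `"fast"` or `"slow"`.
#' @examples
#' classify_speed(499.9)  # fast
#' classify_speed(500.0)  # slow
#' @export
classify_speed <- function(mean_rt, cutoff = 500) {
  if (any(!is.finite(mean_rt)) || any(mean_rt <= 0)) {
    stop("mean_rt must be finite and > 0", call. = FALSE)
  }
  ifelse(mean_rt < cutoff, "fast", "slow")
}

#' Read / write a Stroop session log
#'
#' CSV with columns `index`, `word`, `ink`, `congruent`, `answer`,
#' `rt_ms`, `correct`. The reader validates the session invariants
#' (congruency consistent with word/ink, correctness consistent with
#' answer/ink, positive RTs); the writer round-trips exactly.
#'
#' @param path CSV path.
#' @param n_stimuli Expected session length.
#' @return `read_stroop_csv` returns a [stroop_session()];
#'   `write_stroop_csv` returns `path` invisibly.
#' @export
read_stroop_csv <- function(path, n_stimuli = 35) {
  if (!file.exists(path)) stop("session file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "word", "ink", "congruent", "answer", "rt_ms", "correct")
  if (!all(need %in% names(df))) {
    stop("session CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  if (!all(as.logical(df$congruent) == (df$word == df$ink))) {
    stop("invalid session log: congruent flag inconsistent with word/ink",
         call. = FALSE)
  }
  if (!all(as.logical(df$correct) == (df$answer == df$ink))) {
    stop("invalid session log: correct flag inconsistent with answer/ink",
         call. = FALSE)
  }
  stroop_session(df[c("index", "word", "ink", "congruent")],
                 answer = df$answer, rt = df$rt_ms, n_stimuli = n_stimuli)
}

#' @rdname read_stroop_csv
#' @param session A [stroop_session()] to write.
#' @export
write_stroop_csv <- function(session, path) {
  check_session(session)
  cols <- c("index", "word", "ink", "congruent", "answer", "rt_ms", "correct")
  utils::write.csv(as.data.frame(session)[cols], path, row.names = FALSE)
  invisible(path)
}

#' Summarize a Stroop session
#'
#' @param session A [stroop_session()].
#' @param cutoff Fast/slow cutoff in ms.
#' @return One-row data frame: `n_stimuli`, `mean_rt_ms`, `accuracy`,
#'   `speed`, `mean_rt_congruent_ms`, `mean_rt_incongruent_ms`,
#'   `n_anticipations`.
#' @export
stroop_summary <- function(session, cutoff = 500) {
  check_session(session)
  m <- mean_rt(session)
  bycon <- mean_rt_by_congruency(session)
  data.frame(n_stimuli = nrow(session),
             mean_rt_ms = m,
             accuracy = stroop_accuracy(session),
             speed = classify_speed(m, cutoff),
             mean_rt_congruent_ms = bycon[["congruent"]],
             mean_rt_incongruent_ms = bycon[["incongruent"]],
             n_anticipations = sum(session$anticipation),
             stringsAsFactors = FALSE)
}
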