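#' Deterministic seed splitting
#'
#' All cohort-level randomness flows from one master seed; per-unit seeds
#' are derived with a fixed linear-congruential scramble so that any
#' sub-stream (one participant's RR series, one Stroop session) is
#' reproducible in isolation. Derived seeds stay below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param index Non-negative stream index.
#' @return Integer sub-seed.
#' @export
split_seed <- function(seed, index) {
  m <- 2147483647
  s <- as.double(seed) %% m
  as.integer(((s * 69069) %% m + as.double(index) * 7919) %% m)
}

#' Simulate an RR-interval series
#'
#' Stationary first-order autoregressive Gaussian series with the
#' requested marginal mean and standard deviation: the marginal SD is the
#' expected SDNN, and the expected RMSSD is `sd * sqrt(2 * (1 - lag1))`,
#' so the lag-1 autocorrelation decouples short-term from global
#' variability. Values falling outside the plausibility window are
#' redrawn, so simulated series always pass default cleaning. This is a
#' statistical emulator of RR structure, not a physiological simulator.
#'
#' @param n Number of beats (>= 2).
#' @param mean Marginal mean, ms.
#' @param sd Marginal standard deviation (target SDNN), ms; `sd = 0`
#'   gives a constant series.
#' @param lag1 Lag-1 autocorrelation, in (-1, 1).
#' @param seed Integer seed.
#' @param window Redraw window `c(lo, hi)` in ms.
#' @param subject_id Label for the resulting series.
#' @return An [rr_series()].
#' @examples
#' rr <- simulate_rr(500, mean = 800, sd = 50, lag1 = 0.5, seed = 7)
#' sdnn(rr)
#' @export
simulate_rr <- function(n, mean = 844.7, sd = 55.2, lag1 = 0.5, seed,
                        window = c(300, 2000), subject_id = "synthetic") {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (abs(lag1) >= 1) stop("lag1 must be in (-1, 1)", call. = FALSE)
  if (n < 2) stop("need n >= 2 beats", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  if (sd == 0) {
    return(rr_series(rep(mean, n), subject_id = subject_id))
  }
  innov_sd <- sd * sqrt(1 - lag1^2)
  x <- numeric(n)
  draw <- function(mu, s) {
    v <- stats::rnorm(1, mu, s)
    tries <- 0L
    while (v < window[1] || v > window[2]) {
      v <- stats::rnorm(1, mu, s)
      tries <- tries + 1L
      if (tries > 1000L) stop("infeasible window for requested mean/sd", call. = FALSE)
    }
    v
  }
  x[1] <- draw(mean, sd)
  for (i in 2:n) {
    x[i] <- draw(mean + lag1 * (x[i - 1] - mean), innov_sd)
  }
  rr_series(x, subject_id = subject_id)
}

#' Simulate a Stroop session
#'
#' Lognormal reaction times over a generated stimulus schedule, with
#' Bernoulli correctness; wrong answers pick a different palette color
#' uniformly.
#'
#' @param n_stimuli Session length (default 35).
#' @param rt_log_mean Mean of log reaction time (log-ms).
#' @param rt_log_sd SD of log reaction time; 0 gives identical RTs
#'   `exp(rt_log_mean)`.
#' @param accuracy_p Probability of a correct response, in `[0, 1]`.
#' @param seed Integer seed.
#' @param congruent_prop Proportion of congruent trials.
#' @param palette Stimulus colors.
#' @return A [stroop_session()].
#' @export
simulate_stroop <- function(n_stimuli = 35, rt_log_mean = log(480),
                            rt_log_sd = 0.25, accuracy_p = 0.95, seed,
                            congruent_prop = 0.8,
                            palette = stroop_palette()) {
  if (accuracy_p < 0 || accuracy_p > 1) {
    stop("accuracy_p must be in [0, 1]", call. = FALSE)
  }
  if (rt_log_sd < 0) stop("rt_log_sd must be >= 0", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stim <- generate_stroop_stimuli(n_stimuli, congruent_prop, palette,
                                  seed = split_seed(seed, 1))
  set.seed(split_seed(seed, 2))
  rt <- exp(stats::rnorm(n_stimuli, rt_log_mean, rt_log_sd))
  correct <- stats::runif(n_stimuli) < accuracy_p
  answer <- stim$ink
  for (i in which(!correct)) {
    answer[i] <- sample(setdiff(palette, stim$ink[i]), 1)
  }
  stroop_session(stim, answer = answer, rt = rt, n_stimuli = n_stimuli)
}

#' Specification of a synthetic cohort
#'
#' Default values describe the emulated study conditions: 63 participants
#' using the app 10-20 times each (about 940 sessions in total), RR
#' series with mean 844.7 ms and SDNN target 55.2 ms at lag-1
#' autocorrelation 0.5 (so expected RMSSD equals the SDNN target),
#' session mean reaction times straddling the 500 ms cutoff, and
#' covariates spanning age 17-69, BMI 16.4-31.4, 0-10 hours awake,
#' Epworth 0-14 and a 1-5 perceived food-quality score.
#'
#' @param n_participants Number of participants.
#' @param uses_range Integer range `c(min, max)` of app uses per
#'   participant.
#' @param rr_n Beats per RR recording.
#' @param rr_mean Cohort-level marginal RR mean, ms; each use draws its
#'   own mean normally around it with SD `rr_mean_spread`, truncated to
#'   `rr_mean_window`, so heart rate and AVNN vary between sessions the
#'   way resting recordings do.
#' @param rr_mean_spread Between-use SD of the RR mean, ms.
#' @param rr_mean_window Truncation window for per-use RR means, ms.
#' @param rr_sd_target Cohort-level SDNN target, ms; per-use SDNN varies
#'   lognormally around it (`rr_sd_spread` on the log scale).
#' @param rr_sd_spread Log-scale SD of per-use SDNN variation.
#' @param rr_lag1 Lag-1 autocorrelation of the RR series: either a fixed
#'   scalar or a range `c(lo, hi)` drawn uniformly per use (the default);
#'   session-to-session variation in short-term vagal structure keeps
#'   RMSSD from being a deterministic multiple of SDNN across the cohort.
#' @param rt_log_mean,rt_log_sd Session-level lognormal RT parameters;
#'   per-use `rt_log_mean` itself varies normally with SD
#'   `rt_session_spread`.
#' @param rt_session_spread SD of per-use log-mean RT.
#' @param accuracy_p Stroop accuracy probability.
#' @param age_range,bmi_range,hours_awake_range,epworth_range,alimentation_range
#'   Covariate ranges (uniform draws; Epworth, alimentation and hours
#'   awake are rounded to integers).
#' @param prop_female Proportion of female participants.
#' @param true_beta Optional coefficient matrix ((p+1) x 3, rows
#'   intercept + the [quadrant_design()] columns, columns non-reference
#'   quadrants) for model-based label generation; `NULL` (default) labels
#'   each use through the measurement pipeline (SDNN deviation + mean
#'   RT).
#' @param reference Reference quadrant for `true_beta` labels.
#' @param norms Normative table for pipeline-mode labeling.
#' @param seed Master seed (mandatory).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_participants = 63,
                        uses_range = c(10, 20),
                        rr_n = 300,
                        rr_mean = 844.7,
                        rr_mean_spread = 150,
                        rr_mean_window = c(560, 1400),
                        rr_sd_target = 55.2,
                        rr_sd_spread = 0.35,
                        rr_lag1 = c(0.05, 0.9),
                        rt_log_mean = log(480),
                        rt_log_sd = 0.25,
                        rt_session_spread = 0.12,
                        accuracy_p = 0.95,
                        age_range = c(17, 69),
                        bmi_range = c(16.4, 31.4),
                        hours_awake_range = c(0, 10),
                        epworth_range = c(0, 14),
                        alimentation_range = c(1, 5),
                        prop_female = 20 / 63,
                        true_beta = NULL,
                        reference = "fast_high",
                        norms = NULL,
                        seed) {
  if (missing(seed)) stop("seed is mandatory in a cohort spec", call. = FALSE)
  stopifnot(n_participants >= 1, uses_range[1] >= 1,
            uses_range[2] >= uses_range[1], rr_n >= 2)
  if (!is.null(true_beta)) {
    true_beta <- as.matrix(true_beta)
    if (nrow(true_beta) != length(design_columns) + 2L || ncol(true_beta) != 3L) {
      stop("true_beta must be (n predictors + intercept) x 3; predictors: ",
           "intercept + ", paste(design_columns, collapse = ", "),
           " (age contributes two dummy rows)", call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "cohort_spec")
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Simulate a full synthetic cohort
#'
#' Draws participants with fixed covariates, then per app use simulates
#' an RR series and a Stroop session, computes the HRV and Stroop
#' features end-to-end, and assigns a fatigue quadrant either by running
#' the measurement pipeline (SDNN deviation against the normative table
#' plus the 500 ms rule) or, when `spec$true_beta` is given, by sampling
#' from the multinomial model's softmax probabilities. Fully reproducible
#' from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param keep_raw Keep the per-use `rr_series` and `stroop_session`
#'   objects (default `FALSE`; they are rebuilt on demand from the seed).
#' @return List of class `synthetic_cohort` with `features` (one row per
#'   use: ids, covariates, HRV metrics, Stroop summaries, quadrant
#'   pieces), `labels` (factor), `participants`, `spec`, and optionally
#'   `rr`/`stroop` lists.
#' @export
simulate_cohort <- function(spec, keep_raw = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  norms <- spec$norms %||% default_norm_table()
  set.seed(split_seed(spec$seed, 0))
  np <- spec$n_participants
  participants <- data.frame(
    participant_id = sprintf("p%03d", seq_len(np)),
    age = round(runif_range(np, spec$age_range)),
    female = as.numeric(stats::runif(np) < spec$prop_female),
    bmi = round(runif_range(np, spec$bmi_range), 1),
    epworth = round(runif_range(np, spec$epworth_range)),
    alimentation = round(runif_range(np, spec$alimentation_range)),
    n_uses = round(runif_range(np, spec$uses_range)),
    stringsAsFactors = FALSE)

  rows <- list(); rr_list <- list(); stroop_list <- list()
  use_counter <- 0L
  for (i in seq_len(np)) {
    for (u in seq_len(participants$n_uses[i])) {
      use_counter <- use_counter + 1L
      use_id <- sprintf("%s_u%02d", participants$participant_id[i], u)
      s_use <- split_seed(spec$seed, use_counter * 4L)
      set.seed(s_use)
      sd_use <- spec$rr_sd_target *
        exp(stats::rnorm(1, -spec$rr_sd_spread^2 / 2, spec$rr_sd_spread))
      mu_rt <- stats::rnorm(1, spec$rt_log_mean, spec$rt_session_spread)
      hours_awake <- round(runif_range(1, spec$hours_awake_range))
      lag1_use <- if (length(spec$rr_lag1) == 2L) {
        runif_range(1, spec$rr_lag1)
      } else spec$rr_lag1
      mean_use <- min(max(stats::rnorm(1, spec$rr_mean, spec$rr_mean_spread),
                          spec$rr_mean_window[1]), spec$rr_mean_window[2])

      rr <- simulate_rr(spec$rr_n, mean = mean_use, sd = sd_use,
                        lag1 = lag1_use,
                        seed = split_seed(spec$seed, use_counter * 4L + 1L),
                        subject_id = use_id)
      ses <- simulate_stroop(rt_log_mean = mu_rt,
                             rt_log_sd = spec$rt_log_sd,
                             accuracy_p = spec$accuracy_p,
                             seed = split_seed(spec$seed, use_counter * 4L + 2L))
      h <- hrv_summary(rr)
      st <- stroop_summary(ses)
      dev <- sdnn_deviation(h$sdnn_ms, participants$age[i], norms)
      rows[[use_counter]] <- data.frame(
        use_id = use_id,
        participant_id = participants$participant_id[i],
        age = participants$age[i],
        female = participants$female[i],
        bmi = participants$bmi[i],
        epworth = participants$epworth[i],
        alimentation = participants$alimentation[i],
        hours_awake = hours_awake,
        sdnn = h$sdnn_ms, rmssd = h$rmssd_ms, avnn = h$avnn_ms,
        pnn50 = h$pnn50_pct, hr = h$hr_bpm, stress = h$stress,
        mean_rt_ms = st$mean_rt_ms, accuracy = st$accuracy,
        sdnn_deviation = dev,
        stringsAsFactors = FALSE)
      if (keep_raw) {
        rr_list[[use_id]] <- rr
        stroop_list[[use_id]] <- ses
      }
    }
  }
  features <- do.call(rbind, rows)

  if (is.null(spec$true_beta)) {
    labels <- assign_quadrant(classify_speed(features$mean_rt_ms),
                              classify_sdnn(features$sdnn_deviation))
  } else {
    X <- quadrant_design(features)
    nonref <- setdiff(quadrant_levels(), spec$reference)
    B <- spec$true_beta
    dimnames(B) <- list(c("(Intercept)", colnames(X)), nonref)
    eta <- cbind(1, X) %*% B
    full <- matrix(0, nrow(X), 4, dimnames = list(NULL, quadrant_levels()))
    full[, nonref] <- eta
    pr <- exp(full - apply(full, 1, max))
    pr <- pr / rowSums(pr)
    set.seed(split_seed(spec$seed, 1L))
    lab <- apply(pr, 1, function(p) sample(quadrant_levels(), 1, prob = p))
    labels <- factor(lab, levels = quadrant_levels())
  }
  out <- list(features = features, labels = labels,
              participants = participants, spec = spec)
  if (keep_raw) {
    out$rr <- rr_list
    out$stroop <- stroop_list
  }
  structure(out, class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Writes `features.csv`, `labels.csv`, `covariates.csv`, the resolved
#' spec as YAML (seed included), and — when the cohort was simulated with
#' `keep_raw = TRUE` — per-use RR text files under `rr/` and Stroop
#' session CSVs under `stroop/`, so the files can feed [run_pipeline()].
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(use_id = cohort$features$use_id,
                              quadrant = as.character(cohort$labels)),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  cov_cols <- c("use_id", "participant_id", "age", "female", "bmi",
                "epworth", "alimentation", "hours_awake")
  utils::write.csv(cohort$features[cov_cols],
                   file.path(dir, "covariates.csv"), row.names = FALSE)
  spec <- cohort$spec
  spec_out <- lapply(spec[setdiff(names(spec), c("true_beta", "norms"))],
                     function(v) if (is.numeric(v)) as.numeric(v) else v)
  yaml::write_yaml(spec_out, file.path(dir, "spec_resolved.yaml"))
  if (!is.null(cohort$rr)) {
    dir.create(file.path(dir, "rr"), showWarnings = FALSE)
    dir.create(file.path(dir, "stroop"), showWarnings = FALSE)
    for (id in names(cohort$rr)) {
      write_rr(cohort$rr[[id]], file.path(dir, "rr", paste0(id, ".txt")))
      write_stroop_csv(cohort$stroop[[id]],
                       file.path(dir, "stroop", paste0(id, ".csv")))
    }
  }
  invisible(dir)
}
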