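#' Pipeline configuration
#'
#' Every tunable of the batch pipeline in one validated list with
#' documented defaults. The configuration round-trips unchanged through
#' YAML ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param rr_clean List: `enabled` (default `FALSE` — series are used as
#'   recorded), `lo`, `hi` (plausibility window, ms).
#' @param stroop List: `cutoff_ms` (fast/slow boundary, default 500),
#'   `n_stimuli` (default 35), `include_errors` (error trials in the mean
#'   RT, default `TRUE`).
#' @param norms Path to a normative-table YAML, or `NULL` for the bundled
#'   synthetic placeholder.
#' @param mlr List: `reference`, `ridge`, `tol`, `max_iter`.
#' @param seed Integer seed for any randomized step.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(rr_clean = list(enabled = FALSE, lo = 300, hi = 2000),
                            stroop = list(cutoff_ms = 500, n_stimuli = 35,
                                          include_errors = TRUE),
                            norms = NULL,
                            mlr = list(reference = "fast_high", ridge = 0,
                                       tol = 1e-8, max_iter = 100),
                            seed = 1L) {
  defaults <- formals(pipeline_config)
  rr_clean <- utils::modifyList(eval(defaults$rr_clean), rr_clean)
  stroop <- utils::modifyList(eval(defaults$stroop), stroop)
  mlr <- utils::modifyList(eval(defaults$mlr), mlr)
  stopifnot(rr_clean$hi > rr_clean$lo, stroop$cutoff_ms > 0,
            stroop$n_stimuli >= 1, mlr$ridge >= 0)
  structure(list(rr_clean = rr_clean, stroop = stroop, norms = norms,
                 mlr = mlr, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(rr_clean = raw$rr_clean %||% list(),
                  stroop = raw$stroop %||% list(),
                  norms = raw$norms,
                  mlr = raw$mlr %||% list(),
                  seed = raw$seed %||% 1L)
}

#' Run the full scoring pipeline on a batch of app uses
#'
#' For every row of the covariate table: read the matching RR file
#' (`<use_id>.txt` in `rr_dir`) and Stroop log (`<use_id>.csv` in
#' `stroop_dir`), compute the HRV summary and Stroop summary, score the
#' SDNN deviation against the age norm, and assign the fatigue quadrant.
#' Then tabulate the quadrant distribution and, when at least two
#' quadrants are populated, fit the multinomial quadrant model.
#'
#' Per-file parse failures are collected (with file names) rather than
#' aborting the batch; uses with missing covariates are excluded and
#' counted, so input N = analyzed N + excluded N always reconciles.
#'
#' @param config A [pipeline_config()].
#' @param rr_dir Directory of RR text files.
#' @param stroop_dir Directory of Stroop session CSVs.
#' @param covariates_csv CSV with columns `use_id`, `age`, `female`,
#'   `bmi`, `epworth`, `alimentation`, `hours_awake`.
#' @param out_dir Optional output directory; when given, writes
#'   `per_use.csv`, `quadrant_table.csv`, `coefficients.csv`,
#'   `classification_table.csv` and `fit.json`.
#' @return A `pipeline_report` list: `per_use`, `quadrant_table`,
#'   `model`, `report`, `errors`, `n_input`, `n_analyzed`, `n_excluded`.
#' @export
run_pipeline <- function(config, rr_dir, stroop_dir, covariates_csv,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(rr_dir)) stop("RR directory not found: ", rr_dir, call. = FALSE)
  if (!dir.exists(stroop_dir)) stop("Stroop directory not found: ", stroop_dir, call. = FALSE)
  if (!file.exists(covariates_csv)) {
    stop("covariate table not found: ", covariates_csv, call. = FALSE)
  }
  if (length(list.files(rr_dir)) == 0L) {
    stop("empty input directory: ", rr_dir, call. = FALSE)
  }
  covs <- utils::read.csv(covariates_csv, stringsAsFactors = FALSE)
  need <- c("use_id", "age", "female", "bmi", "epworth", "alimentation",
            "hours_awake")
  miss <- setdiff(need, names(covs))
  if (length(miss)) {
    stop("covariate table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  norms <- if (is.null(config$norms)) default_norm_table() else {
    load_norm_table(config$norms)
  }

  errors <- character(0)
  rows <- vector("list", nrow(covs))
  for (i in seq_len(nrow(covs))) {
    id <- covs$use_id[i]
    rr_path <- file.path(rr_dir, paste0(id, ".txt"))
    st_path <- file.path(stroop_dir, paste0(id, ".csv"))
    res <- tryCatch({
      rr <- read_rr(rr_path, subject_id = id)
      if (isTRUE(config$rr_clean$enabled)) {
        rr <- clean_rr(rr, config$rr_clean$lo, config$rr_clean$hi)
      }
      ses <- read_stroop_csv(st_path, n_stimuli = config$stroop$n_stimuli)
      h <- hrv_summary(rr)
      m_rt <- mean_rt(ses, correct_only = !isTRUE(config$stroop$include_errors))
      dev <- sdnn_deviation(h$sdnn_ms, covs$age[i], norms)
      speed <- classify_speed(m_rt, config$stroop$cutoff_ms)
      level <- classify_sdnn(dev)
      cbind(data.frame(use_id = id, stringsAsFactors = FALSE),
            h[-1],
            data.frame(rmssd = h$rmssd_ms, hr = h$hr_bpm, avnn = h$avnn_ms,
                       mean_rt_ms = m_rt, accuracy = stroop_accuracy(ses),
                       sdnn_deviation = dev, speed = speed, level = level,
                       quadrant = as.character(assign_quadrant(speed, level)),
                       age = covs$age[i], female = covs$female[i],
                       bmi = covs$bmi[i], epworth = covs$epworth[i],
                       alimentation = covs$alimentation[i],
                       hours_awake = covs$hours_awake[i],
                       stringsAsFactors = FALSE))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errors <- c(errors, sprintf("%s: %s", id, res))
      rows[[i]] <- NULL
    } else {
      rows[[i]] <- res
    }
  }
  per_use <- do.call(rbind, rows)
  if (is.null(per_use) || nrow(per_use) == 0L) {
    stop("no use could be scored; first error: ",
         if (length(errors)) errors[1] else "unknown", call. = FALSE)
  }
  # complete-case filter for the model covariates
  feat_cols <- c("stress", "age", "rmssd", "hr", "avnn", "alimentation",
                 "female", "epworth", "bmi", "hours_awake")
  complete <- stats::complete.cases(per_use[feat_cols]) &
    !is.na(per_use$quadrant)
  n_excluded <- nrow(covs) - sum(complete)
  qt <- quadrant_table(per_use$quadrant[complete])

  model <- NULL; report <- NULL
  if (length(unique(per_use$quadrant[complete])) >= 2L) {
    fit_try <- tryCatch({
      model <- fit_quadrant_model(per_use[complete, ],
                                  per_use$quadrant[complete],
                                  reference = config$mlr$reference,
                                  ridge = config$mlr$ridge,
                                  tol = config$mlr$tol,
                                  max_iter = config$mlr$max_iter)
      X <- quadrant_design(per_use[complete, ])
      report <- classification_report(model, X,
                                      per_use$quadrant[complete][attr(X, "kept")])
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(fit_try)) {
      model <- NULL; report <- NULL
      errors <- c(errors, sprintf("model fit: %s", fit_try))
    }
  }
  out <- structure(list(per_use = per_use, quadrant_table = qt,
                        model = model, report = report, errors = errors,
                        n_input = nrow(covs), n_analyzed = sum(complete),
                        n_excluded = n_excluded),
                   class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$per_use, file.path(out_dir, "per_use.csv"),
                   row.names = FALSE)
  write_quadrant_table(out$quadrant_table,
                       file.path(out_dir, "quadrant_table.csv"))
  if (!is.null(out$model)) {
    write_mlr_coefs(out$model, file.path(out_dir, "coefficients.csv"))
    utils::write.csv(as.data.frame.matrix(out$report$classification_table),
                     file.path(out_dir, "classification_table.csv"))
    fit <- list(nagelkerke = out$report$nagelkerke,
                success_rate = out$report$success_rate,
                n = out$report$n,
                n_input = out$n_input,
                n_analyzed = out$n_analyzed,
                n_excluded = out$n_excluded,
                reference = out$model$reference,
                loglik = out$model$loglik,
                loglik_null = out$model$loglik_null)
    writeLines(jsonlite::toJSON(fit, auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "fit.json"))
    save_mlr_model(out$model, file.path(out_dir, "model.json"))
  }
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> input=%d analyzed=%d excluded=%d parse errors=%d\n",
              x$n_input, x$n_analyzed, x$n_excluded, length(x$errors)))
  print(x$quadrant_table)
  if (!is.null(x$report)) {
    cat(sprintf("Nagelkerke R2=%.3f  success rate=%.1f%%\n",
                x$report$nagelkerke, 100 * x$report$success_rate))
  }
  invisible(x)
}
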