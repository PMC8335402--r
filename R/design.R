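#' Age bands used in the quadrant model
#'
#' Ages are grouped as 17-21, 22-30 and >30; the oldest band is the dummy
#' baseline, so the design matrix carries two indicator columns.
#'
#' @param age Numeric ages in years.
#' @return Factor with levels `">30"`, `"17-21"`, `"22-30"` (baseline
#'   first).
#' @export
age_band <- function(age) {
  if (any(!is.na(age) & age < 0)) stop("negative age", call. = FALSE)
  band <- ifelse(is.na(age), NA_character_,
                 ifelse(age <= 21, "17-21",
                        ifelse(age <= 30, "22-30", ">30")))
  factor(band, levels = c(">30", "17-21", "22-30"))
}

design_columns <- c("stress", "age", "rmssd", "hr", "avnn", "alimentation",
                    "female", "epworth", "bmi", "hours_awake")

#' Build the quadrant-model design matrix
#'
#' Converts a participant feature frame into the predictor matrix for the
#' multinomial quadrant model: stress index, two age-band dummies
#' (baseline >30), RMSSD (ms), heart rate (bpm), AVNN (ms), perceived
#' food quality, female indicator, Epworth score, BMI and hours awake.
#' Continuous predictors enter untransformed. Rows with any missing
#' covariate are dropped (complete-case analysis) and counted.
#'
#' @param features Data frame with columns `stress`, `age` (years; or a
#'   ready-made `age_band` factor), `rmssd`, `hr`, `avnn`,
#'   `alimentation`, `female` (0/1), `epworth`, `bmi`, `hours_awake`.
#' @return Numeric matrix with a `"term"` attribute grouping the two age
#'   dummies under the single term `"age"`, and attributes `n_excluded`
#'   and `kept` (logical row filter) recording the complete-case drop.
#' @export
quadrant_design <- function(features) {
  need <- setdiff(design_columns, "age")
  if (!"age" %in% names(features) && !"age_band" %in% names(features)) {
    stop("features need an 'age' (or 'age_band') column", call. = FALSE)
  }
  miss <- setdiff(need, names(features))
  if (length(miss)) {
    stop("features missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  band <- if ("age_band" %in% names(features)) {
    factor(features$age_band, levels = c(">30", "17-21", "22-30"))
  } else {
    age_band(features$age)
  }
  X <- cbind(stress = as.numeric(features$stress),
             `age17_21` = as.numeric(band == "17-21"),
             `age22_30` = as.numeric(band == "22-30"),
             rmssd = as.numeric(features$rmssd),
             hr = as.numeric(features$hr),
             avnn = as.numeric(features$avnn),
             alimentation = as.numeric(features$alimentation),
             female = as.numeric(features$female),
             epworth = as.numeric(features$epworth),
             bmi = as.numeric(features$bmi),
             hours_awake = as.numeric(features$hours_awake))
  X[is.na(band), c("age17_21", "age22_30")] <- NA
  kept <- stats::complete.cases(X)
  out <- X[kept, , drop = FALSE]
  attr(out, "term") <- c("stress", "age", "age", "rmssd", "hr", "avnn",
                         "alimentation", "female", "epworth", "bmi",
                         "hours_awake")
  attr(out, "n_excluded") <- sum(!kept)
  attr(out, "kept") <- kept
  out
}

#' Fit the four-quadrant fatigue model
#'
#' Convenience wrapper: builds the design matrix with
#' [quadrant_design()], aligns the labels to the complete cases and fits
#' the multinomial model. The default reference category is `fast_high` —
#' the quadrant that carries no coefficient panel in the reported layout;
#' it is configurable because reference-category choice only relabels the
#' log-odds, never the fitted probabilities.
#'
#' @param features Feature frame (see [quadrant_design()]).
#' @param labels Quadrant labels (factor/character on
#'   [quadrant_levels()]); rows with missing labels are excluded too.
#' @param reference Reference quadrant (default `"fast_high"`).
#' @param ridge Ridge penalty passed to [mlr_fit()].
#' @param ... Further arguments to [mlr_fit()].
#' @return An `mlr_model` with an extra `n_excluded` element.
#' @export
fit_quadrant_model <- function(features, labels, reference = "fast_high",
                               ridge = 0, ...) {
  X <- quadrant_design(features)
  labels <- factor(as.character(labels), levels = quadrant_levels())
  labels <- labels[attr(X, "kept")]
  ok <- !is.na(labels)
  n_excluded <- attr(X, "n_excluded") + sum(!ok)
  Xok <- X[ok, , drop = FALSE]
  attr(Xok, "term") <- attr(X, "term")   # lost by subsetting
  model <- mlr_fit(Xok, labels[ok],
                   reference = reference, ridge = ridge, ...)
  model$n_excluded <- n_excluded
  model
}

#' Write the coefficient panels as CSV
#'
#' One panel per non-reference quadrant, each row a predictor with its
#' log-odds estimate, standard error, odds ratio `exp(beta)` and
#' three-decimal significance. The standard error and the odds ratio are
#' emitted as distinct, unambiguously named columns.
#'
#' @param model An `mlr_model` from [fit_quadrant_model()].
#' @param path Output CSV path.
#' @export
write_mlr_coefs <- function(model, path) {
  w <- wald_tests(model)
  out <- data.frame(panel = w$class, term = w$term,
                    beta = round(w$estimate, 3),
                    se = round(w$se, 3),
                    odds_ratio = round(w$odds_ratio, 2),
                    sig = format_p(w$p),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a fitted quadrant model as JSON
#'
#' Persists the coefficient matrix and fit metadata so `classify` runs
#' can score new feature files without refitting.
#'
#' @param model An `mlr_model`.
#' @param path JSON path.
#' @return `load_mlr_model` returns an `mlr_model` sufficient for
#'   prediction and odds-ratio reporting (the variance matrix is also
#'   stored).
#' @export
save_mlr_model <- function(model, path) {
  stopifnot(inherits(model, "mlr_model"))
  obj <- list(beta = model$beta, vcov = model$vcov,
              loglik = model$loglik, loglik_null = model$loglik_null,
              n = model$n, levels = model$levels,
              reference = model$reference,
              terms_map = as.list(model$terms_map),
              ridge = model$ridge,
              beta_rownames = rownames(model$beta),
              beta_colnames = colnames(model$beta))
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_mlr_model
#' @export
load_mlr_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  beta <- matrix(as.numeric(obj$beta), length(obj$beta_rownames),
                 length(obj$beta_colnames),
                 dimnames = list(obj$beta_rownames, obj$beta_colnames))
  structure(list(beta = beta, vcov = as.matrix(obj$vcov),
                 loglik = obj$loglik, loglik_null = obj$loglik_null,
                 n = obj$n, levels = obj$levels, reference = obj$reference,
                 terms_map = unlist(obj$terms_map),
                 converged = TRUE, iterations = NA_integer_,
                 ridge = obj$ridge),
            class = "mlr_model")
}
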