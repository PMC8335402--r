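#' Multinomial logistic regression by Newton iteration
#'
#' Fits a softmax-link multinomial logistic model with a
#' reference-category constraint: the reference class's coefficients are
#' fixed at zero and every other class gets one coefficient vector
#' (intercept + slopes), so all effects are log-odds relative to the
#' reference. The penalized log-likelihood is maximized by full Newton
#' steps with step-halving, starting from zero, which makes the fit
#' deterministic.
#'
#' An optional ridge penalty (`ridge/2 * sum(slope^2)`, intercepts
#' unpenalized) stabilizes fits under complete or quasi-complete
#' separation; reported log-likelihoods are always the unpenalized ones.
#'
#' @param x Numeric predictor matrix, one row per observation, no
#'   intercept column (added internally). Column names are required. An
#'   optional `"term"` attribute (character, one entry per column) groups
#'   columns — e.g. dummy codes of one factor — into a single predictor
#'   for importance ranking.
#' @param y Factor (or coercible) of class labels; at least 2 classes
#'   must be present.
#' @param reference Reference class label; defaults to the first level.
#' @param ridge Non-negative ridge penalty on slopes (default 0).
#' @param tol Convergence tolerance on the maximum absolute score
#'   component (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 100).
#' @return An object of class `mlr_model`: list with `beta` (matrix,
#'   (p+1) x (K-1), one column per non-reference class), `vcov`,
#'   `loglik`, `loglik_null`, `n`, `levels`, `reference`, `terms_map`,
#'   `converged`, `iterations`, `ridge`.
#' @examples
#' set.seed(1)
#' x <- cbind(z = rnorm(300))
#' y <- factor(ifelse(x[, 1] + rnorm(300) > 0, "b", "a"))
#' fit <- mlr_fit(x, y, reference = "a")
#' coef(fit)
#' @export
mlr_fit <- function(x, y, reference = NULL, ridge = 0,
                    tol = 1e-8, max_iter = 100) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  terms_map <- attr(x, "term") %||% colnames(x)
  y <- droplevels(as.factor(y))
  lev <- levels(y)
  K <- length(lev)
  if (K < 2L) stop("need at least 2 classes present", call. = FALSE)
  if (nrow(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (ridge < 0) stop("ridge must be >= 0", call. = FALSE)
  if (is.null(reference)) reference <- lev[1]
  if (!reference %in% lev) {
    stop("reference class '", reference, "' not among observed labels",
         call. = FALSE)
  }
  nonref <- setdiff(lev, reference)
  n <- nrow(x)
  X <- cbind(`(Intercept)` = 1, x)
  p1 <- ncol(X)
  m <- p1 * (K - 1L)
  if (n < m) {
    stop("fewer observations than free parameters (", n, " < ", m, ")",
         call. = FALSE)
  }
  Y <- matrix(0, n, K - 1L, dimnames = list(NULL, nonref))
  for (k in seq_along(nonref)) Y[y == nonref[k], k] <- 1

  pen_mask <- rep(c(0, rep(1, p1 - 1L)), K - 1L)  # intercepts unpenalized
  probs_nonref <- function(B) {
    eta <- X %*% B
    # softmax with the reference class's implicit eta = 0
    mx <- pmax(apply(eta, 1, max), 0)
    ex <- exp(eta - mx)
    denom <- exp(-mx) + rowSums(ex)
    ex / denom
  }
  loglik_of <- function(B) {
    eta <- X %*% B
    mx <- pmax(apply(eta, 1, max), 0)
    lse <- mx + log(exp(-mx) + rowSums(exp(eta - mx)))
    sum(rowSums(Y * eta)) - sum(lse)
  }
  pen_loglik <- function(B) {
    loglik_of(B) - 0.5 * ridge * sum((as.vector(B) * pen_mask)^2)
  }

  B <- matrix(0, p1, K - 1L, dimnames = list(colnames(X), nonref))
  converged <- FALSE
  iter <- 0L
  H <- NULL
  repeat {
    iter <- iter + 1L
    P <- probs_nonref(B)
    G <- crossprod(X, Y - P) - ridge * (B * matrix(pen_mask, p1, K - 1L))
    g <- as.vector(G)
    # observed (= expected) information, block form
    H <- matrix(0, m, m)
    for (j in seq_len(K - 1L)) {
      for (k in seq_len(j)) {
        w <- if (j == k) P[, j] * (1 - P[, j]) else -P[, j] * P[, k]
        blk <- crossprod(X, X * w)
        ri <- (j - 1L) * p1 + seq_len(p1)
        ci <- (k - 1L) * p1 + seq_len(p1)
        H[ri, ci] <- blk
        H[ci, ri] <- t(blk)
      }
    }
    diag(H) <- diag(H) + ridge * pen_mask
    if (max(abs(g)) < tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) {
      bad <- collinear_columns(X)
      stop("singular information matrix; collinear columns: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    # step-halving on the penalized log-likelihood
    ll0 <- pen_loglik(B)
    lambda <- 1
    repeat {
      Bnew <- B + lambda * matrix(step, p1, K - 1L)
      if (pen_loglik(Bnew) >= ll0 - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    delta <- max(abs(Bnew - B))
    B <- Bnew
    if (delta < 1e-10) {
      converged <- max(abs(g)) < sqrt(tol)
      break
    }
    # Under complete/quasi-complete separation the unpenalized likelihood
    # has no finite maximizer and the linear predictors saturate; with
    # ridge > 0 a finite maximizer always exists, so no heuristic is used.
    if (ridge == 0 && max(abs(X %*% B)) > 20) {
      stop("diverging coefficients (likely complete separation); ",
           "refit with ridge > 0", call. = FALSE)
    }
    if (iter >= max_iter) break
  }
  if (!converged) {
    stop("Newton iteration did not converge in ", max_iter,
         " iterations; consider ridge > 0", call. = FALSE)
  }
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V)) {
    bad <- collinear_columns(X)
    stop("singular information matrix; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cn <- as.vector(outer(colnames(X), nonref, function(a, b) paste(b, a, sep = ":")))
  dimnames(V) <- list(cn, cn)

  counts <- table(y)
  ll_null <- sum(counts * log(counts / n))
  structure(list(beta = B, vcov = V,
                 loglik = loglik_of(B), loglik_null = ll_null,
                 n = n, levels = lev, reference = reference,
                 terms_map = stats::setNames(terms_map, colnames(x)),
                 converged = converged, iterations = iter, ridge = ridge),
            class = "mlr_model")
}

collinear_columns <- function(X) {
  q <- qr(X)
  if (q$rank == ncol(X)) return("<none identified>")
  colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
}

#' @export
coef.mlr_model <- function(object, ...) object$beta

#' @export
print.mlr_model <- function(x, ...) {
  cat(sprintf("<mlr_model> %d classes (reference: %s), n=%d, logLik=%.2f, iter=%d\n",
              length(x$levels), x$reference, x$n, x$loglik, x$iterations))
  print(round(x$beta, 4))
  invisible(x)
}

#' Predicted class probabilities
#'
#' Softmax of the linear predictors; the reference class uses a zero
#' linear predictor. Probabilities are returned for every class in the
#' original level order and sum to 1 per row.
#'
#' @param model An [mlr_fit()] model.
#' @param x Predictor matrix with the model's columns (no intercept).
#' @return Matrix of probabilities, one column per class level.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "mlr_model"))
  x <- as.matrix(x)
  pnames <- rownames(model$beta)[-1]
  if (!is.null(colnames(x))) {
    missing_cols <- setdiff(pnames, colnames(x))
    if (length(missing_cols)) {
      stop("x is missing predictor columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    x <- x[, pnames, drop = FALSE]
  } else if (ncol(x) != length(pnames)) {
    stop("x has ", ncol(x), " columns; model expects ", length(pnames),
         call. = FALSE)
  }
  X <- cbind(1, x)
  eta <- matrix(0, nrow(X), length(model$levels),
                dimnames = list(NULL, model$levels))
  eta[, colnames(model$beta)] <- X %*% model$beta
  mx <- apply(eta, 1, max)
  ex <- exp(eta - mx)
  ex / rowSums(ex)
}

#' Odds ratios
#'
#' Elementwise `exp(beta)`: the multiplicative change in the odds of each
#' class relative to the reference per unit increase of the predictor.
#'
#' @param model An [mlr_fit()] model, or a bare numeric vector/matrix of
#'   coefficients.
#' @return `exp(beta)` with the same shape and names.
#' @examples
#' odds_ratios(c(0.417, -0.922))  # 1.517..., 0.397...
#' @export
odds_ratios <- function(model) {
  if (inherits(model, "mlr_model")) exp(model$beta) else exp(model)
}

#' Nagelkerke pseudo-R-squared
#'
#' Cox-Snell `1 - exp((2/n) * (ll0 - ll))` rescaled by its maximum
#' `1 - exp((2/n) * ll0)` so the statistic is bounded in `[0, 1]`; 0 when
#' the model does not improve on the intercept-only fit and 1 in the
#' limit of a perfect fit.
#'
#' @param model An [mlr_fit()] model, or a list with elements `loglik`,
#'   `loglik_null`, `n`.
#' @return Numeric scalar in `[0, 1]`.
#' @export
nagelkerke <- function(model) {
  ll <- model$loglik; ll0 <- model$loglik_null; n <- model$n
  if (is.null(n) || n == 0) stop("n must be positive", call. = FALSE)
  cox_snell <- 1 - exp((2 / n) * (ll0 - ll))
  max_cs <- 1 - exp((2 / n) * ll0)
  cox_snell / max_cs
}

#' Wald tests per coefficient
#'
#' `z = beta / SE` with standard errors from the inverse observed
#' information; the Wald statistic is `z^2`, compared to a chi-squared
#' distribution with 1 df.
#'
#' @param model An [mlr_fit()] model.
#' @return Data frame with one row per coefficient: `class`, `term`,
#'   `estimate`, `se`, `odds_ratio`, `z`, `wald`, `p`.
#' @export
wald_tests <- function(model) {
  stopifnot(inherits(model, "mlr_model"))
  B <- model$beta
  se <- matrix(sqrt(diag(model$vcov)), nrow(B), ncol(B))
  dimnames(se) <- dimnames(B)
  z <- B / se
  data.frame(class = rep(colnames(B), each = nrow(B)),
             term = rep(rownames(B), ncol(B)),
             estimate = as.vector(B),
             se = as.vector(se),
             odds_ratio = as.vector(exp(B)),
             z = as.vector(z),
             wald = as.vector(z^2),
             p = as.vector(stats::pchisq(z^2, df = 1, lower.tail = FALSE)),
             stringsAsFactors = FALSE)
}

#' Classification report
#'
#' Assigns each observation to its highest-probability class (ties go to
#' the lowest category index) and cross-tabulates observed against
#' predicted classes.
#'
#' @param model An [mlr_fit()] model.
#' @param x Predictor matrix.
#' @param y Observed labels (factor on the model's levels).
#' @return Object of class `mlr_report`: list with
#'   `classification_table` (K x K, observed in rows), `success_rate`
#'   (trace / total), `nagelkerke`, `wald` (the [wald_tests()] frame),
#'   `odds_ratios`, `n`.
#' @export
classification_report <- function(model, x, y) {
  stopifnot(inherits(model, "mlr_model"))
  probs <- predict_proba(model, x)
  pred <- factor(model$levels[max.col(probs, ties.method = "first")],
                 levels = model$levels)
  obs <- factor(as.character(y), levels = model$levels)
  tab <- table(observed = obs, predicted = pred)
  structure(list(classification_table = tab,
                 success_rate = sum(diag(tab)) / sum(tab),
                 nagelkerke = nagelkerke(model),
                 wald = wald_tests(model),
                 odds_ratios = exp(model$beta),
                 n = sum(tab)),
            class = "mlr_report")
}

#' @export
print.mlr_report <- function(x, ...) {
  cat(sprintf("<mlr_report> n=%d  success rate=%.1f%%  Nagelkerke R2=%.3f\n",
              x$n, 100 * x$success_rate, x$nagelkerke))
  print(x$classification_table)
  invisible(x)
}

#' Rank predictors by importance
#'
#' Orders predictors by the maximum Wald statistic each attains across
#' the non-reference equations. Dummy columns belonging to one factor
#' (e.g. the two age-band indicators) are grouped and ranked as a single
#' predictor. The maximum-across-equations rule is this package's
#' documented summary choice for turning per-equation tests into one
#' global ordering; other summaries (mean, likelihood-ratio per
#' predictor) are possible and would order near-ties differently.
#'
#' @param report An [classification_report()] object or [mlr_fit()]
#'   model.
#' @param terms_map Optional named character vector mapping predictor
#'   columns to grouped term names (taken from the model when available).
#' @return Data frame `term`, `max_wald`, ordered by decreasing
#'   importance.
#' @export
rank_predictors <- function(report, terms_map = NULL) {
  if (inherits(report, "mlr_model")) {
    terms_map <- terms_map %||% report$terms_map
    wald <- wald_tests(report)
  } else if (inherits(report, "mlr_report")) {
    wald <- report$wald
  } else {
    stop("expected an mlr_model or mlr_report", call. = FALSE)
  }
  wald <- wald[wald$term != "(Intercept)", ]
  grp <- if (is.null(terms_map)) wald$term else {
    mapped <- unname(terms_map[wald$term])
    ifelse(is.na(mapped), wald$term, mapped)
  }
  mw <- tapply(wald$wald, grp, max)
  out <- data.frame(term = names(mw), max_wald = as.vector(mw),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$max_wald), ]
  rownames(out) <- NULL
  out
}

#' Format p-values for reporting
#'
#' Three decimals with a `0.000` floor, matching the convention of
#' printed significance columns.
#'
#' @param p Numeric p-values.
#' @return Character vector.
#' @export
format_p <- function(p) sprintf("%.3f", pmax(p, 0))
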