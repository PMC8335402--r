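# Independent brute-force oracles. Deliberately naive (explicit loops,
# no shared code with the package internals) so they can arbitrate.

o_mean <- function(x) {
  s <- 0
  for (xi in x) s <- s + xi
  s / length(x)
}

o_sd_sample <- function(x) {
  m <- o_mean(x)
  s <- 0
  for (xi in x) s <- s + (xi - m)^2
  sqrt(s / (length(x) - 1))
}

o_rmssd <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + (x[i] - x[i - 1])^2
  sqrt(s / (length(x) - 1))
}

o_pnn50 <- function(x) {
  cnt <- 0
  for (i in 2:length(x)) if (abs(x[i] - x[i - 1]) > 50) cnt <- cnt + 1
  100 * cnt / (length(x) - 1)
}

o_stress <- function(x, bin_width = 50) {
  # histogram by explicit counting over bins anchored at 0
  idx <- floor(x / bin_width)
  ids <- sort(unique(idx))
  counts <- vapply(ids, function(b) sum(idx == b), numeric(1))
  best <- ids[counts == max(counts)][1]          # tie -> lowest bin
  amo <- 100 * max(counts) / length(x)
  mo <- (best * bin_width + bin_width / 2) / 1000
  vr <- (max(x) - min(x)) / 1000
  list(amo = amo, mo = mo, vr = vr, stress = amo / (2 * vr * mo))
}

# --- independent multinomial-likelihood oracle (general-purpose optimizer) ---

oracle_mlr <- function(x, y, reference) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  lev <- levels(y)
  nonref <- setdiff(lev, reference)
  X1 <- cbind(1, x)
  p1 <- ncol(X1)
  Km1 <- length(nonref)
  Y <- sapply(nonref, function(l) as.numeric(y == l))
  nll <- function(th) {
    B <- matrix(th, p1, Km1)
    eta <- X1 %*% B
    lse <- log(1 + rowSums(exp(eta)))
    -(sum(Y * eta) - sum(lse))
  }
  gr <- function(th) {
    B <- matrix(th, p1, Km1)
    eta <- X1 %*% B
    P <- exp(eta) / (1 + rowSums(exp(eta)))
    as.vector(-crossprod(X1, Y - P))
  }
  opt <- stats::optim(rep(0, p1 * Km1), nll, gr, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  matrix(opt$par, p1, Km1, dimnames = list(c("(Intercept)", colnames(x)), nonref))
}

# simulate a labelled multinomial dataset from known coefficients
sim_multinom <- function(n, beta, levels_, reference) {
  p <- nrow(beta) - 1L
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  nonref <- setdiff(levels_, reference)
  eta <- cbind(1, x) %*% beta
  full <- matrix(0, n, length(levels_), dimnames = list(NULL, levels_))
  full[, nonref] <- eta
  pr <- exp(full - apply(full, 1, max))
  pr <- pr / rowSums(pr)
  y <- factor(apply(pr, 1, function(q) sample(levels_, 1, prob = q)),
              levels = levels_)
  list(x = x, y = y)
}

random_session <- function(seed, n = 35) {
  set.seed(seed)
  stim <- generate_stroop_stimuli(n, congruent_prop = runif(1), seed = seed + 1)
  correct <- runif(n) < 0.9
  answer <- stim$ink
  pal <- stroop_palette()
  for (i in which(!correct)) answer[i] <- setdiff(pal, stim$ink[i])[1]
  stroop_session(stim, answer = answer, rt = exp(rnorm(n, log(450), 0.3)),
                 n_stimuli = n)
}

tiny_norm_table <- function() {
  norm_table(data.frame(age_lo = c(17, 30), age_hi = c(30, 70),
                        sdnn_norm_ms = c(52, 44)),
             source_label = "test fixture")
}
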