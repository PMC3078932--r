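#' Harmonic-mean estimate of the log marginal likelihood
#'
#' The (smoothed-trace) harmonic-mean estimator computed wholly in log space:
#' `log m = log N - logsumexp(-loglik)`. The harmonic mean is a notoriously
#' high-variance, upward-biased estimator — it is provided because it is the
#' classic trace-based route for Bayes-factor model screening; treat the
#' bootstrap standard error as a lower bound on the real uncertainty and
#' prefer dedicated path-sampling tools for serious model comparison.
#'
#' @param loglik numeric vector of post-burn-in log-likelihood samples
#'   (at least 100).
#' @param bootstrap_reps number of bootstrap resamples for the standard
#'   error.
#' @return list with `estimate` and `se`.
#' @export
log_marginal_likelihood <- function(loglik, bootstrap_reps = 1000L) {
  loglik <- as.numeric(loglik)
  if (!length(loglik)) stop2("empty log-likelihood trace")
  if (length(loglik) < 100L)
    stop2("need at least 100 post-burn-in samples (got ", length(loglik), ")")
  n <- length(loglik)
  est <- log(n) - log_sum_exp(-loglik)
  boot <- vapply(seq_len(bootstrap_reps), function(i) {
    x <- loglik[sample.int(n, n, replace = TRUE)]
    log(n) - log_sum_exp(-x)
  }, 0)
  list(estimate = est, se = sd(boot))
}

#' log10 Bayes factor between two models
#'
#' `(log m_A - log m_B) / ln 10`, with the conventional interpretation bands
#' on the log10 scale: < 0.5 "none", 0.5-1 "substantial", 1-2 "strong",
#' > 2 "very strong".
#'
#' @param ml_a,ml_b log marginal likelihoods (natural log), either numbers or
#'   the lists returned by [log_marginal_likelihood()].
#' @return numeric log10 Bayes factor with attribute `band`, class
#'   `bayes_factor`.
#' @export
log10_bayes_factor <- function(ml_a, ml_b) {
  if (is.list(ml_a)) ml_a <- ml_a$estimate
  if (is.list(ml_b)) ml_b <- ml_b$estimate
  if (!is.finite(ml_a) || !is.finite(ml_b))
    stop2("marginal likelihood estimates must be finite")
  bf <- (ml_a - ml_b) / log(10)
  band <- bf_band(bf)
  structure(bf, band = band, class = "bayes_factor")
}

bf_band <- function(bf) {
  a <- abs(bf)
  if (a < 0.5) "none"
  else if (a < 1) "substantial"
  else if (a < 2) "strong"
  else "very strong"
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat(sprintf("log10 BF = %.4g (evidence: %s)\n", unclass(x), attr(x, "band")))
  invisible(x)
}
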