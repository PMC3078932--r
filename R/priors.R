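#' Uncorrelated lognormal relaxed-clock prior
#'
#' Branch rates are independent, identically distributed lognormal draws
#' parameterized by the real-space mean rate `M` (substitutions/site/Myr) and
#' log-space standard deviation `S`, so `meanlog = log(M) - S^2/2`. `S = 0`
#' is the strict-clock limit; a small floor (`s_min`) keeps the density
#' finite in that degenerate case.
#'
#' @param rates positive branch rates (the root entry, if present as `NA`,
#'   is ignored).
#' @param clock list with `M > 0` and `S >= 0` (see [clock_params()]).
#' @param s_min lower guard on `S`.
#' @return sum of the log densities; `-Inf` if any rate is non-positive.
#' @export
ucln_log_density <- function(rates, clock, s_min = 1e-6) {
  r <- rates[!is.na(rates)]
  if (any(r <= 0)) return(-Inf)
  S <- max(clock$S, s_min)
  sum(dlnorm(r, meanlog = log(clock$M) - S^2 / 2, sdlog = S, log = TRUE))
}

#' Clock and tree-prior parameter containers
#'
#' @param M mean branch rate in real space (substitutions/site/Myr), `> 0`.
#' @param S log-space standard deviation of branch rates, `>= 0`.
#' @return a list with validated fields.
#' @export
clock_params <- function(M, S) {
  if (M <= 0) stop2("M must be > 0")
  if (S < 0) stop2("S must be >= 0")
  list(M = M, S = S)
}

#' @rdname clock_params
#' @param r net diversification rate (speciation - extinction), per Myr,
#'   `> 0`.
#' @param a relative extinction (extinction/speciation), in `[0, 1)`.
#' @export
bd_params <- function(r, a) {
  if (r <= 0) stop2("r must be > 0")
  if (a < 0 || a >= 1) stop2("a must be in [0, 1)")
  list(r = r, a = a)
}

# per-age kernel of the conditioned reconstructed birth-death process
# (complete sampling, uniform prior on origin): node ages are iid with
# density g(t) = r (1-a) e^{-rt} / (1 - a e^{-rt})^2, CDF
# G(t) = (1 - e^{-rt}) / (1 - a e^{-rt}); Yule (a = 0): Exp(r).
bd_age_logpdf <- function(t, r, a) {
  e <- exp(-r * t)
  log(r) + log1p(-a) - r * t - 2 * log1p(-a * e)
}

bd_age_cdf <- function(t, r, a) {
  e <- exp(-r * t)
  (1 - e) / (1 - a * e)
}

bd_age_quantile <- function(p, r, a) {
  -log((1 - p) / (1 - a * p)) / r
}

#' Reconstructed birth-death prior on node ages
#'
#' Joint log density of the `n - 1` internal node ages of an ultrametric
#' tree under the conditioned reconstructed birth-death process with complete
#' sampling and a uniform prior on the time of origin. Under this process the
#' node ages are independent draws from a common age density, and the joint
#' density over the ranked age vector is `(n-1)!` times their product; the
#' value depends on the ages only, so it is invariant to leaf relabeling. At
#' `a = 0` it reduces to the Yule process (ages iid exponential with rate
#' `r`).
#'
#' @param tree a [time_tree()] with `n >= 2` leaves.
#' @param bd a [bd_params()] list (`r > 0`, `0 <= a < 1`).
#' @return log density of the internal node ages.
#' @export
birth_death_log_density <- function(tree, bd) {
  if (!is.list(bd) || is.null(bd$r) || is.null(bd$a))
    stop2("'bd' must be a bd_params() list")
  bd <- bd_params(bd$r, bd$a)   # revalidate bounds
  n <- tree$n_tip
  ages <- tree$age[(n + 1L):(2L * n - 1L)]
  bd_node_ages_logpdf(ages, bd$r, bd$a)
}

bd_node_ages_logpdf <- function(ages, r, a) {
  lfactorial(length(ages)) + sum(bd_age_logpdf(ages, r, a))
}

#' Default hyperpriors for the sampled scalar parameters
#'
#' Returns the log prior density of the model's scalar parameters: clock mean
#' `M` ~ lognormal(log 0.01, 1.5), clock sd `S` ~ Exp(rate 2), net
#' diversification `r` ~ lognormal(log 0.1, 1), relative extinction `a` ~
#' U(0, 1); when substitution parameters are estimated, gamma shape `alpha` ~
#' Exp(1), `kappa` and GTR exchangeabilities ~ lognormal(0, 1.25) and `p_inv`
#' ~ U(0, 1). These are deliberately diffuse desk-scale defaults; all are
#' overridable through the `hyperpriors` entry of [divtime_config()].
#'
#' @param name parameter name (e.g. `"clock.M"`, `"bd.r"`, `"alpha"`).
#' @param value parameter value.
#' @return log prior density.
#' @export
default_hyperprior <- function(name, value) {
  base <- sub("\\..*$", "", sub("^(clock|bd)\\.", "\\1_", name))
  switch(base,
    clock_M = dlnorm(value, log(0.01), 1.5, log = TRUE),
    clock_S = dexp(value, rate = 2, log = TRUE),
    bd_r = dlnorm(value, log(0.1), 1, log = TRUE),
    bd_a = dunif(value, 0, 1, log = TRUE),
    alpha = dexp(value, rate = 1, log = TRUE),
    kappa = dlnorm(value, 0, 1.25, log = TRUE),
    exch = dlnorm(value, 0, 1.25, log = TRUE),
    pinv = dunif(value, 0, 1, log = TRUE),
    relrate = 0,   # flat on the mean-one simplex
    0)
}
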