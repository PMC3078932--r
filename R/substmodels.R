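#' Nucleotide substitution models
#'
#' Constructs a time-reversible nucleotide substitution model of family K80,
#' HKY, TVM or GTR, optionally with discrete-gamma rate heterogeneity (`+G`,
#' `alpha` with `k` equal-probability categories) and a proportion of
#' invariant sites (`+I`, `p_inv`). The rate matrix is normalized so one unit
#' of branch length is one expected substitution per site at stationarity
#' after averaging over the gamma categories and the invariant class, i.e.
#' the scaling divides by `(1 - p_inv)` times the base rate.
#'
#' Exchangeabilities are in the order AC, AG, AT, CG, CT, GT relative to GT =
#' 1. K80 and HKY use a single transition/transversion ratio `kappa`
#' (AG = CT = kappa); TVM is GTR with the constraint AG = CT.
#'
#' @param family one of `"K80"`, `"HKY"`, `"TVM"`, `"GTR"`, or a spec string
#'   like `"HKY+I+G"` (flags set `alpha`/`p_inv` defaults when not supplied).
#' @param freq stationary frequencies (A, C, G, T), sum 1. Forced equal for
#'   K80.
#' @param kappa transition/transversion ratio for K80/HKY.
#' @param rates six exchangeabilities (AC, AG, AT, CG, CT, GT) for GTR/TVM.
#' @param alpha gamma shape (`NULL` for no rate heterogeneity).
#' @param k number of gamma categories.
#' @param p_inv proportion of invariant sites in `[0, 1)`.
#' @return object of class `subst_model` carrying the normalized rate matrix
#'   `Q`, its spectral decomposition, the category rates and all parameters.
#' @examples
#' m <- subst_model("HKY", kappa = 4, freq = c(.3, .2, .2, .3), alpha = 0.5)
#' rowSums(transition_matrix(m, 0.1))
#' @export
subst_model <- function(family = "HKY", freq = rep(0.25, 4), kappa = 2,
                        rates = rep(1, 6), alpha = NULL, k = 4L, p_inv = 0) {
  spec <- strsplit(family, "+", fixed = TRUE)[[1L]]
  family <- spec[1L]
  if (!family %in% c("K80", "HKY", "TVM", "GTR"))
    stop2("unknown model family: ", family)
  if ("G" %in% spec && is.null(alpha)) alpha <- 0.5
  if ("I" %in% spec && p_inv == 0) p_inv <- 0.1
  check_prob(p_inv, "p_inv")
  if (family == "K80") freq <- rep(0.25, 4)
  if (abs(sum(freq) - 1) > 1e-8 || any(freq <= 0))
    stop2("frequencies must be positive and sum to 1")
  freq <- freq / sum(freq)
  if (family %in% c("K80", "HKY")) {
    if (kappa <= 0) stop2("kappa must be positive")
    rates <- c(1, kappa, 1, 1, kappa, 1)
  } else {
    if (length(rates) != 6L || any(rates <= 0))
      stop2("need six positive exchangeabilities")
    if (family == "TVM") {
      if (abs(rates[2L] - rates[5L]) > 1e-12 * max(rates))
        stop2("TVM requires rate(AG) == rate(CT)")
    }
  }
  if (!is.null(alpha) && alpha <= 0) stop2("alpha must be positive")
  cat_rates <- if (is.null(alpha)) 1 else discretize_gamma(alpha, k)

  Q <- build_q(rates, freq)
  base_rate <- -sum(freq * diag(Q))
  Q <- Q / (base_rate * (1 - p_inv))
  dec <- q_spectral(Q, freq)
  structure(list(family = family, freq = freq, kappa = kappa, rates = rates,
                 alpha = alpha, k = as.integer(k), p_inv = p_inv,
                 cat_rates = cat_rates, Q = Q, decomp = dec),
            class = "subst_model")
}

# unnormalized GTR generator from exchangeabilities and frequencies
build_q <- function(rates, freq) {
  Q <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  idx <- rbind(c(1,2), c(1,3), c(1,4), c(2,3), c(2,4), c(3,4))
  for (e in seq_len(6)) {
    i <- idx[e, 1L]; j <- idx[e, 2L]
    Q[i, j] <- rates[e] * freq[j]
    Q[j, i] <- rates[e] * freq[i]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# spectral decomposition of a reversible Q via the symmetrization
# S = D^{1/2} Q D^{-1/2}; P(t) = A exp(L t) B with A = D^{-1/2} V, B = V' D^{1/2}
q_spectral <- function(Q, freq) {
  d <- sqrt(freq)
  S <- (Q * d) * rep(1 / d, each = 4)   # diag(d) Q diag(1/d)
  S <- (S + t(S)) / 2                                   # clean symmetry
  es <- eigen(S, symmetric = TRUE)
  list(A = es$vectors / d, lambda = es$values, B = t(es$vectors) * rep(d, each = 4))
}

#' Transition probability matrix
#'
#' `P(d) = exp(Q d)` computed from the cached spectral decomposition of the
#' reversible generator. `d` is an expected number of substitutions per site
#' (before gamma-category scaling; multiply by the category rate for `+G`).
#'
#' @param model a [subst_model()].
#' @param distance expected substitutions per site, `>= 0`.
#' @return a 4x4 row-stochastic matrix over (A, C, G, T).
#' @export
transition_matrix <- function(model, distance) {
  if (!is.numeric(distance) || length(distance) != 1L || is.na(distance) ||
      distance < 0)
    stop2("distance must be a single non-negative number")
  dec <- model$decomp
  P <- dec$A %*% (exp(dec$lambda * distance) * dec$B)
  # clip tiny negative round-off and renormalize rows
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Discrete-gamma rate categories
#'
#' Mean-preserving discretization of the gamma(shape = alpha, mean = 1) rate
#' distribution into `k` equal-probability categories; each category rate is
#' the conditional mean of its probability band, so the category mean is
#' exactly 1.
#'
#' @param alpha gamma shape, `> 0`.
#' @param k number of categories, `>= 1`.
#' @return numeric vector of `k` positive rates with mean 1.
#' @export
discretize_gamma <- function(alpha, k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1)
    stop2("k must be a positive integer")
  if (!is.numeric(alpha) || alpha <= 0) stop2("alpha must be positive")
  k <- as.integer(k)
  if (k == 1L) return(1)
  bounds <- qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  # E[X; a < X < b] for Gamma(alpha, alpha) = pgamma(b, alpha+1) - pgamma(a, alpha+1)
  cum <- pgamma(bounds, shape = alpha + 1, rate = alpha)
  r <- k * diff(cum)
  r / mean(r) # exact unit mean against floating error
}
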