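#' MCMC run configuration
#'
#' Desk-scale defaults: short chains, 10% burn-in (the original analysis
#' discarded 2M of 20M generations), two replicates, and an ESS warning
#' threshold of 200 (the published convergence gate was ESS > 1200 at
#' 400M total generations; at desk scale 200 is a practical floor).
#'
#' @param chain_length number of proposals per replicate; must be at least
#'   `10 * sample_every`.
#' @param sample_every sampling interval in generations.
#' @param burnin fraction of each replicate discarded, in `[0, 1)`.
#' @param replicates number of independent chains; replicate `i` is seeded
#'   with `seed + i`.
#' @param seed base random seed.
#' @param prior_only if `TRUE` the likelihood is switched off (prior
#'   sampling; the engine-correctness mode).
#' @param tree_prior `"birth_death"` (reconstructed birth-death on node ages)
#'   or `"none"` (flat; only sensible with proper calibrations).
#' @param estimate_substitution also sample substitution-model parameters
#'   (gamma shape, kappa / exchangeabilities, invariant proportion)?
#' @param estimate_relrates sample per-partition relative rates (kept at
#'   weighted mean 1)?
#' @param init named list of starting values (`M`, `S`, `r`, `a`).
#' @param operator_weights named numeric vector overriding default operator
#'   weights (defaults are proportional to the number of parameters each
#'   operator touches).
#' @param tune named list of proposal tuning constants (scale factors and
#'   slide windows).
#' @param ess_threshold warn (not fail) when any parameter's ESS falls below
#'   this after combining replicates.
#' @param hyperpriors optional named list of functions `value -> log density`
#'   overriding [default_hyperprior()] per parameter.
#' @return a list of class `divtime_config`.
#' @export
divtime_config <- function(chain_length = 20000L, sample_every = 20L,
                           burnin = 0.1, replicates = 2L, seed = 1L,
                           prior_only = FALSE,
                           tree_prior = c("birth_death", "none"),
                           estimate_substitution = FALSE,
                           estimate_relrates = FALSE,
                           init = list(), operator_weights = NULL,
                           tune = list(), ess_threshold = 200,
                           hyperpriors = list()) {
  tree_prior <- match.arg(tree_prior)
  check_prob(burnin, "burnin")
  if (chain_length < 10L * sample_every)
    stop2("chain_length must be at least 10 * sample_every")
  init <- modifyList(list(M = 0.01, S = 0.3, r = 0.05, a = 0.1), init)
  tune <- modifyList(list(root_scale = 1.25, scalar_scale = 1.3,
                          tree_scale = 1.1, rate_window = 0.8,
                          a_window = 0.15, pinv_window = 0.7,
                          relrate_window = 0.1), tune)
  structure(list(chain_length = as.integer(chain_length),
                 sample_every = as.integer(sample_every), burnin = burnin,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 prior_only = isTRUE(prior_only), tree_prior = tree_prior,
                 estimate_substitution = isTRUE(estimate_substitution),
                 estimate_relrates = isTRUE(estimate_relrates),
                 init = init, operator_weights = operator_weights,
                 tune = tune, ess_threshold = ess_threshold,
                 hyperpriors = hyperpriors),
            class = "divtime_config")
}

# resolve calibration clades to node ids, demanding monophyly
resolve_calibrations <- function(tree, calibrations) {
  if (!length(calibrations)) return(integer(0))
  tips <- descendant_tips(tree)
  vapply(calibrations, function(cal) {
    if (is.null(cal$taxa)) stop2("calibration ", cal$name, " names no taxa")
    nd <- mrca_node(tree, cal$taxa)
    clade <- sort(tree$tip_label[tips[[nd]]])
    if (!identical(clade, sort(unique(cal$taxa))))
      stop2("calibration clade '", cal$name,
            "' is not monophyletic in the given topology (MRCA spans {",
            paste(clade, collapse = ", "), "})")
    nd
  }, integer(1))
}

# Find starting node ages inside the joint support of the ordering
# constraints and all hard calibration bounds, by interval constraint
# propagation: lower bounds flow root-ward (a parent exceeds every
# descendant's lower bound), upper bounds flow tip-ward, then nodes are
# placed bottom-up at their preferred age clamped into the feasible window.
initialize_ages <- function(tree, calibrations, cal_nodes) {
  n <- tree$n_tip
  n_node <- 2L * n - 1L
  internal <- (n + 1L):n_node
  lo <- rep(0, n_node)
  hi <- rep(Inf, n_node)
  pref <- tree$age
  for (i in seq_along(cal_nodes)) {
    cal <- calibrations[[i]]
    sup <- calibration_support(cal)
    nd <- cal_nodes[i]
    lo[nd] <- max(lo[nd], sup[1L])
    hi[nd] <- min(hi[nd], sup[2L])
    pref[nd] <- switch(cal$kind,
                       uniform = (cal$min + cal$max) / 2,
                       lognormal_offset = cal$offset + exp(cal$meanlog),
                       normal = cal$mean)
  }
  # the input tree's ages are topologically valid, so ordering internal nodes
  # by input age gives a postorder (children before parents)
  po <- internal[order(tree$age[internal])]
  for (nd in po) {
    ch <- tree$children[as.character(nd), ]
    lo[nd] <- max(lo[nd], lo[ch])
  }
  for (nd in rev(po)) {
    ch <- tree$children[as.character(nd), ]
    hi[ch] <- pmin(hi[ch], hi[nd])
  }
  infeasible <- lo > hi
  if (any(infeasible))
    stop2("hard calibration bounds are jointly infeasible on this topology ",
          "(no valid starting ages) near node(s): ",
          paste(which(infeasible), collapse = ", "))
  age <- numeric(n_node)
  for (nd in po) {
    ch <- tree$children[as.character(nd), ]
    base <- max(age[ch])
    eps <- 1e-6 * max(base, lo[nd], 1)
    lo_eff <- max(lo[nd], base) + eps   # strictly above children & offsets
    target <- max(pref[nd], lo_eff)
    if (is.finite(hi[nd]) && target >= hi[nd]) {
      if (hi[nd] <= lo_eff)
        stop2("could not find starting node ages satisfying calibrations ",
              "around node ", nd)
      target <- lo_eff + 0.9 * (hi[nd] - lo_eff)  # interior placement
    }
    age[nd] <- target
  }
  age
}

# parse a model spec string into a subst_model with default parameter values
model_from_spec <- function(spec, freq = rep(0.25, 4)) {
  subst_model(spec, freq = freq, kappa = 2, rates = rep(1, 6))
}

default_models_for_scheme <- function(scheme, align = NULL, tree = NULL) {
  models <- list()
  for (g in scheme$groups) {
    freq <- rep(0.25, 4)
    if (!is.null(align)) {
      obs <- align$seq[, g$sites, drop = FALSE]
      cnt <- table(factor(obs, levels = c("A", "C", "G", "T")))
      if (sum(cnt) > 0) freq <- (as.numeric(cnt) + 1) / (sum(cnt) + 4)
    }
    models[[g$name]] <- model_from_spec(g$model, freq = freq)
  }
  models
}

#' Run one Metropolis-Hastings chain
#'
#' Samples node ages, branch rates, clock and tree-prior parameters (and
#' optionally substitution parameters) on a fixed topology. Calibration
#' densities multiply the birth-death node-age prior (the common practical
#' approximation, with no conditioning correction). Identical seeds give
#' identical traces; every sampled state respects the tree's age ordering and
#' all hard calibration bounds.
#'
#' Operators: uniform slide of internal node ages within their ordering
#' bounds, root-age scale, likelihood-invariant exchange moves that slide a
#' node age (or scale the root age) while counter-adjusting the adjacent
#' branch rates so branch distances are preserved, log-space slide on single
#' branch rates, scale moves on the scalar parameters, uniform slide on the
#' relative extinction, and a whole-tree age scale with matching branch-rate
#' counter-scale.
#'
#' @param align a [dna_alignment()], or `NULL` for prior-only sampling.
#' @param tree a [time_tree()] giving the fixed topology and starting ages.
#' @param scheme a [partition_scheme()] (required with `align`).
#' @param models named list of [subst_model()]s per scheme group; built from
#'   the scheme's model strings and empirical base frequencies when `NULL`.
#' @param calibrations list of [calibration()]s whose taxon sets resolve to
#'   monophyletic clades of `tree`.
#' @param config a [divtime_config()].
#' @param rel_rates fixed per-partition relative rate multipliers (weighted
#'   mean 1); starting values when `estimate_relrates` is on. Default all 1.
#' @param replicate replicate id stored in the trace; the chain is seeded
#'   with `config$seed + replicate`.
#' @return a `data.frame` of class `mcmc_trace` with columns `state`,
#'   `posterior`, `likelihood`, `prior`, the scalar parameters, one
#'   `age.<node>` column per internal node, and `replicate`; acceptance
#'   rates per operator are in `attr(, "acceptance")`.
#' @export
run_mcmc <- function(align = NULL, tree, scheme = NULL, models = NULL,
                     calibrations = list(), config = divtime_config(),
                     rel_rates = NULL, replicate = 1L) {
  set.seed(config$seed + replicate)
  n <- tree$n_tip
  n_node <- 2L * n - 1L
  internal <- (n + 1L):n_node
  nonroot_internal <- setdiff(internal, tree$root)
  nonroot <- setdiff(seq_len(n_node), tree$root)
  cal_nodes <- resolve_calibrations(tree, calibrations)

  use_lik <- !config$prior_only && !is.null(align)
  if (use_lik) {
    if (is.null(scheme)) stop2("'scheme' is required when a likelihood is used")
    if (is.null(models)) models <- default_models_for_scheme(scheme, align)
    lk <- likelihood_data(align, tree, scheme)
    part_names <- names(lk$parts)
    part_w <- vapply(lk$parts, `[[`, 0, "n_site")
    part_w <- part_w / sum(part_w)
  } else {
    lk <- NULL; part_names <- character(0); part_w <- numeric(0)
  }
  n_part <- length(part_names)

  hyper <- function(name, value) {
    f <- config$hyperpriors[[name]]
    if (!is.null(f)) f(value) else default_hyperprior(name, value)
  }

  # ---- state ----
  age <- initialize_ages(tree, calibrations, cal_nodes)
  clock <- clock_params(config$init$M, config$init$S)
  bd <- bd_params(config$init$r, config$init$a)
  rates <- rep(NA_real_, n_node); rates[nonroot] <- clock$M
  relrate <- if (is.null(rel_rates)) rep(1, max(n_part, 1L))
             else unname(rel_rates[part_names])
  if (length(relrate) != max(n_part, 1L) || anyNA(relrate))
    stop2("rel_rates must name every partition group")

  est_sub <- config$estimate_substitution && use_lik
  est_rel <- config$estimate_relrates && use_lik && n_part > 1L

  log_prior <- function(age, rates, clock, bd, models, relrate) {
    lp <- 0
    for (i in seq_along(cal_nodes)) {
      lp <- lp + calibration_log_density(calibrations[[i]], age[cal_nodes[i]])
      if (!is.finite(lp)) return(-Inf)
    }
    if (config$tree_prior == "birth_death")
      lp <- lp + bd_node_ages_logpdf(age[internal], bd$r, bd$a) +
        hyper("bd.r", bd$r) + hyper("bd.a", bd$a)
    lp <- lp + ucln_log_density(rates, clock) +
      hyper("clock.M", clock$M) + hyper("clock.S", clock$S)
    if (est_sub) {
      for (nm in part_names) {
        m <- models[[nm]]
        if (!is.null(m$alpha)) lp <- lp + hyper("alpha", m$alpha)
        if (m$family %in% c("K80", "HKY")) lp <- lp + hyper("kappa", m$kappa)
        else lp <- lp + sum(vapply(m$rates[1:5], hyper, 0, name = "exch"))
        if (m$p_inv > 0) lp <- lp + hyper("pinv", m$p_inv)
      }
    }
    lp
  }
  part_ll <- function(age, rates, models, relrate, which = seq_len(n_part)) {
    if (!use_lik) return(numeric(0))
    child <- lk$edges[, "child"]; parent <- lk$edges[, "parent"]
    base_dist <- rates[child] * (age[parent] - age[child])
    vapply(which, function(i) {
      p <- lk$parts[[i]]; m <- models[[p$name]]
      partition_loglik_cpp(m$decomp$A, m$decomp$lambda, m$decomp$B,
                           base_dist * relrate[i], child, parent,
                           p$tip_part, p$const_part,
                           p$weights, m$freq, m$cat_rates, m$p_inv,
                           lk$ntip, lk$nnode)
    }, 0)
  }

  prior_cur <- log_prior(age, rates, clock, bd, models, relrate)
  if (!is.finite(prior_cur)) stop2("initial state has zero prior probability")
  ll_parts <- part_ll(age, rates, models, relrate)
  ll_cur <- sum(ll_parts)

  # ---- operator schedule ----
  ops <- c(age_slide = length(nonroot_internal), root_scale = 2,
           age_exchange = length(nonroot_internal), root_exchange = 2,
           rate_slide = length(nonroot) / 2, clock_M = 2, clock_S = 2,
           tree_scale = 2)
  if (config$tree_prior == "birth_death") ops <- c(ops, bd_r = 1, bd_a = 1)
  if (est_sub) ops <- c(ops, subst_param = 2 * n_part)
  if (est_rel) ops <- c(ops, relrate_exchange = 2)
  if (!is.null(config$operator_weights)) {
    keep <- intersect(names(config$operator_weights), names(ops))
    ops[keep] <- config$operator_weights[keep]
  }
  ops <- ops[ops > 0]
  op_names <- names(ops)
  op_prob <- ops / sum(ops)
  proposed <- accepted <- setNames(numeric(length(ops)), op_names)
  tn <- config$tune

  # ---- trace storage ----
  scalar_cols <- c("clock.M", "clock.S")
  if (config$tree_prior == "birth_death") scalar_cols <- c(scalar_cols, "bd.r", "bd.a")
  sub_cols <- character(0)
  if (est_sub) for (nm in part_names) {
    m <- models[[nm]]
    if (!is.null(m$alpha)) sub_cols <- c(sub_cols, paste0("alpha.", nm))
    if (m$family %in% c("K80", "HKY")) sub_cols <- c(sub_cols, paste0("kappa.", nm))
    else sub_cols <- c(sub_cols, paste0("exch", 1:5, ".", nm))
    if (m$p_inv > 0) sub_cols <- c(sub_cols, paste0("pinv.", nm))
  }
  rel_cols <- if (est_rel) paste0("relrate.", part_names) else character(0)
  age_cols <- paste0("age.", internal)
  cols <- c("state", "posterior", "likelihood", "prior", scalar_cols, sub_cols,
            rel_cols, "rate.mean", age_cols)
  n_samp <- config$chain_length %/% config$sample_every + 1L
  out <- matrix(NA_real_, n_samp, length(cols), dimnames = list(NULL, cols))

  snapshot <- function(gen, row) {
    rec <- c(gen, ll_cur + prior_cur, ll_cur, prior_cur, clock$M, clock$S)
    if (config$tree_prior == "birth_death") rec <- c(rec, bd$r, bd$a)
    if (est_sub) for (nm in part_names) {
      m <- models[[nm]]
      if (!is.null(m$alpha)) rec <- c(rec, m$alpha)
      if (m$family %in% c("K80", "HKY")) rec <- c(rec, m$kappa)
      else rec <- c(rec, m$rates[1:5])
      if (m$p_inv > 0) rec <- c(rec, m$p_inv)
    }
    if (est_rel) rec <- c(rec, relrate)
    rec <- c(rec, mean(rates[nonroot]), age[internal])
    out[row, ] <<- rec
  }
  snapshot(0L, 1L)
  row <- 2L

  draw_scale <- function(f) f^runif(1, -1, 1)

  for (gen in seq_len(config$chain_length)) {
    op <- sample.int(length(ops), 1L, prob = op_prob)
    opn <- op_names[op]
    proposed[op] <- proposed[op] + 1
    hastings <- 0
    valid <- TRUE   # FALSE when the proposal falls outside its support
    new_age <- NULL; new_rates <- NULL; new_clock <- NULL; new_bd <- NULL
    new_models <- NULL; new_rel <- NULL
    lik_parts_to_update <- integer(0)  # partitions whose ll changes

    if (opn == "age_slide") {
      nd <- nonroot_internal[sample.int(length(nonroot_internal), 1L)]
      lo <- max(age[tree$children[as.character(nd), ]])
      hi <- age[tree$parent[nd]]
      new_age <- age; new_age[nd] <- runif(1, lo, hi)
      lik_parts_to_update <- seq_len(n_part)
    } else if (opn == "root_scale") {
      u <- draw_scale(tn$root_scale)
      new_age <- age; new_age[tree$root] <- age[tree$root] * u
      if (new_age[tree$root] <= max(age[tree$children[as.character(tree$root), ]]))
        valid <- FALSE  # out of support; counts as a rejected proposal
      hastings <- log(u)
      lik_parts_to_update <- seq_len(n_part)
    } else if (opn == "age_exchange") {
      # joint move: slide an internal node age and counter-adjust the three
      # adjacent branch rates so every branch's expected substitutions stay
      # fixed -- the likelihood is invariant and the move walks along the
      # age-rate ridge; Hastings term is the Jacobian of the rate map
      nd <- nonroot_internal[sample.int(length(nonroot_internal), 1L)]
      ch <- tree$children[as.character(nd), ]
      lo <- max(age[ch]); hi <- age[tree$parent[nd]]
      t_old <- age[nd]; t_new <- runif(1, lo, hi)
      new_age <- age; new_age[nd] <- t_new
      new_rates <- rates
      new_rates[nd] <- rates[nd] * (hi - t_old) / (hi - t_new)
      new_rates[ch] <- rates[ch] * (t_old - age[ch]) / (t_new - age[ch])
      hastings <- log((hi - t_old) / (hi - t_new)) +
        sum(log((t_old - age[ch]) / (t_new - age[ch])))
      # branch distances unchanged, likelihood invariant
    } else if (opn == "root_exchange") {
      # scale the root age, counter-adjusting its two child branch rates
      u <- draw_scale(tn$root_scale)
      rt <- tree$root
      ch <- tree$children[as.character(rt), ]
      t_old <- age[rt]; t_new <- t_old * u
      if (t_new <= max(age[ch])) {
        valid <- FALSE
      } else {
        new_age <- age; new_age[rt] <- t_new
        new_rates <- rates
        new_rates[ch] <- rates[ch] * (t_old - age[ch]) / (t_new - age[ch])
        hastings <- log(u) +
          sum(log((t_old - age[ch]) / (t_new - age[ch])))
      }
      # branch distances unchanged, likelihood invariant
    } else if (opn == "rate_slide") {
      nd <- nonroot[sample.int(length(nonroot), 1L)]
      new_rates <- rates
      new_rates[nd] <- rates[nd] * exp(runif(1, -tn$rate_window, tn$rate_window))
      hastings <- log(new_rates[nd] / rates[nd])
      lik_parts_to_update <- seq_len(n_part)
    } else if (opn == "clock_M") {
      u <- draw_scale(tn$scalar_scale)
      new_clock <- clock; new_clock$M <- clock$M * u
      hastings <- log(u)
    } else if (opn == "clock_S") {
      u <- draw_scale(tn$scalar_scale)
      new_clock <- clock; new_clock$S <- clock$S * u
      hastings <- log(u)
    } else if (opn == "bd_r") {
      u <- draw_scale(tn$scalar_scale)
      new_bd <- bd; new_bd$r <- bd$r * u
      hastings <- log(u)
    } else if (opn == "bd_a") {
      new_bd <- bd; new_bd$a <- bd$a + runif(1, -tn$a_window, tn$a_window)
      if (new_bd$a < 0 || new_bd$a >= 1) valid <- FALSE
    } else if (opn == "tree_scale") {
      u <- draw_scale(tn$tree_scale)
      new_age <- age; new_age[internal] <- age[internal] * u
      new_rates <- rates; new_rates[nonroot] <- rates[nonroot] / u
      hastings <- (1L - n) * log(u)
      # distances unchanged, likelihood invariant
    } else if (opn == "subst_param") {
      pi_idx <- sample.int(n_part, 1L)
      nm <- part_names[pi_idx]
      m <- models[[nm]]
      choices <- c(if (!is.null(m$alpha)) "alpha",
                   if (m$family %in% c("K80", "HKY")) "kappa" else "exch",
                   if (m$p_inv > 0) "pinv")
      what <- choices[sample.int(length(choices), 1L)]
      m2 <- m
      if (what == "alpha") {
        u <- draw_scale(tn$scalar_scale); hastings <- log(u)
        m2 <- subst_model(m$family, m$freq, m$kappa, m$rates, m$alpha * u,
                          m$k, m$p_inv)
      } else if (what == "kappa") {
        u <- draw_scale(tn$scalar_scale); hastings <- log(u)
        m2 <- subst_model(m$family, m$freq, m$kappa * u, m$rates, m$alpha,
                          m$k, m$p_inv)
      } else if (what == "exch") {
        free <- if (m$family == "TVM") c(1L, 2L, 3L, 4L) else 1:5
        j <- free[sample.int(length(free), 1L)]
        u <- draw_scale(tn$scalar_scale); hastings <- log(u)
        rts <- m$rates; rts[j] <- rts[j] * u
        if (m$family == "TVM" && j == 2L) rts[5L] <- rts[2L]
        m2 <- subst_model(m$family, m$freq, m$kappa, rts, m$alpha, m$k, m$p_inv)
      } else { # pinv logit slide
        x <- log(m$p_inv / (1 - m$p_inv)) + runif(1, -tn$pinv_window, tn$pinv_window)
        p2 <- 1 / (1 + exp(-x))
        hastings <- log(p2 * (1 - p2)) - log(m$p_inv * (1 - m$p_inv))
        m2 <- subst_model(m$family, m$freq, m$kappa, m$rates, m$alpha, m$k, p2)
      }
      new_models <- models; new_models[[nm]] <- m2
      lik_parts_to_update <- pi_idx
    } else if (opn == "relrate_exchange") {
      ij <- sample.int(n_part, 2L)
      d <- runif(1, -tn$relrate_window, tn$relrate_window)
      new_rel <- relrate
      new_rel[ij[1L]] <- relrate[ij[1L]] + d
      new_rel[ij[2L]] <- relrate[ij[2L]] - d * part_w[ij[1L]] / part_w[ij[2L]]
      if (any(new_rel[ij] <= 0)) valid <- FALSE
      lik_parts_to_update <- ij
    }

    a2 <- new_age %||% age; r2 <- new_rates %||% rates
    c2 <- new_clock %||% clock; b2 <- new_bd %||% bd
    m2l <- new_models %||% models; rel2 <- new_rel %||% relrate

    prior_new <- if (valid) log_prior(a2, r2, c2, b2, m2l, rel2) else -Inf
    if (is.finite(prior_new)) {
      ll_new_parts <- ll_parts
      if (use_lik && length(lik_parts_to_update))
        ll_new_parts[lik_parts_to_update] <-
          part_ll(a2, r2, m2l, rel2, lik_parts_to_update)
      ll_new <- sum(ll_new_parts)
      delta <- (ll_new + prior_new) - (ll_cur + prior_cur) + hastings
      if (is.finite(delta) && log(runif(1)) < delta) {
        age <- a2; rates <- r2; clock <- c2; bd <- b2
        models <- m2l; relrate <- rel2
        ll_parts <- ll_new_parts; ll_cur <- ll_new; prior_cur <- prior_new
        accepted[op] <- accepted[op] + 1
      }
    }
    if (gen %% config$sample_every == 0L) {
      snapshot(gen, row)
      row <- row + 1L
    }
  }

  trace <- as.data.frame(out)
  trace$replicate <- replicate
  attr(trace, "acceptance") <- ifelse(proposed > 0, accepted / proposed, NA)
  attr(trace, "proposed") <- proposed
  attr(trace, "internal_nodes") <- internal
  attr(trace, "cal_nodes") <- cal_nodes
  class(trace) <- c("mcmc_trace", "data.frame")
  trace
}
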