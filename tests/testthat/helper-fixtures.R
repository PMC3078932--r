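# shared fixtures: small trees, alignments, models, and independent oracles

balanced4_tree <- function() parse_newick("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")

# a single-locus scheme whose two groups can share one model
one_locus_scheme <- function(n_site = 10L, genome = "nuc") {
  build_partition_scheme(data.frame(name = "g1", start = 1L, end = n_site,
                                    genome = genome, phase = 1L))
}

# random GTR-family model for property tests
random_model <- function(family = "GTR", alpha = NULL, p_inv = 0) {
  freq <- as.numeric(rgamma(4, 5) + 0.5); freq <- freq / sum(freq)
  rts <- as.numeric(rgamma(6, 2) + 0.1); rts <- rts / rts[6]
  if (family == "TVM") rts[5] <- rts[2]
  subst_model(family, freq = freq, rates = rts, alpha = alpha, p_inv = p_inv)
}

# exhaustive internal-state enumeration of the site likelihood for a 4-taxon
# rooted tree: the brute-force oracle the pruning algorithm is checked
# against (gamma + invariant mixture included)
enumeration_loglik <- function(model, tree, rates, align, rel_rate = 1) {
  lut <- divtime:::iupac_partials()
  post <- divtime:::postorder_edges(tree)
  cols <- align$seq[tree$tip_label, , drop = FALSE]
  states <- 1:4
  site_ll <- function(col) {
    cats <- model$cat_rates
    total <- 0
    for (ci in seq_along(cats)) {
      P <- lapply(seq_len(nrow(post)), function(e) {
        ch <- post[e, 1]; pa <- post[e, 2]
        transition_matrix(model,
          rates[ch] * (tree$age[pa] - tree$age[ch]) * rel_rate * cats[ci])
      })
      s <- 0
      for (x5 in states) for (x6 in states) for (x7 in states) {
        assign <- c(NA, NA, NA, NA, x5, x6, x7)
        p <- model$freq[x5]
        for (e in seq_len(nrow(post))) {
          ch <- post[e, 1]; pa <- post[e, 2]
          p <- p * if (ch <= 4) sum(P[[e]][assign[pa], ] * lut[[col[ch]]])
                   else P[[e]][assign[pa], assign[ch]]
        }
        s <- s + p
      }
      total <- total + s / length(cats)
    }
    const <- sum(model$freq * vapply(states, function(x)
      prod(vapply(1:4, function(tx) lut[[col[tx]]][x], 0)), 0))
    log(model$p_inv * const + (1 - model$p_inv) * total / 1)
  }
  sum(apply(cols, 2, site_ll))
}

# brute-force HPD: scan every window of gap consecutive sorted samples
hpd_bruteforce <- function(x, level = 0.95) {
  x <- sort(x); n <- length(x)
  gap <- min(n - 1L, max(1L, ceiling(level * n)))
  best <- c(x[1], x[1 + gap])
  for (i in seq_len(n - gap))
    if (x[i + gap] - x[i] < best[2] - best[1]) best <- c(x[i], x[i + gap])
  best
}

# small data + calibration scenario for sampler tests (single genome keeps
# the partition count at two)
small_dating_problem <- function(seed, n_taxa = 8L, bp = 250L) {
  set.seed(seed)
  tree <- simulate_tree(n_taxa, r = 0.08, a = 0.2)
  rates <- simulate_rates(tree, clock_params(0.02, 0.3))
  loci <- data.frame(name = c("g1", "g2"), start = c(1L, bp + 1L),
                     end = c(bp, 2L * bp), genome = "nuc", phase = 1L)
  scheme <- build_partition_scheme(loci)
  models <- list(
    nuc_pos12 = subst_model("HKY", kappa = 3, freq = c(.3, .2, .2, .3),
                            alpha = 0.5),
    nuc_pos3 = subst_model("HKY", kappa = 4, freq = c(.25, .25, .2, .3),
                           alpha = 1))
  align <- simulate_alignment(tree, rates, scheme, models, missing = 0.05)
  cals <- make_calibrations(tree, n_cal = 3L)
  list(tree = tree, rates = rates, scheme = scheme, models = models,
       align = align, calibrations = cals)
}

quick_config <- function(...) {
  args <- modifyList(list(chain_length = 2000L, sample_every = 10L,
                          replicates = 1L,
                          init = list(M = 0.02, S = 0.3, r = 0.08, a = 0.2)),
                     list(...))
  do.call(divtime_config, args)
}
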