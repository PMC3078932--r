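#' Partitioned phylogenetic log-likelihood
#'
#' Felsenstein pruning on a fixed rooted topology with per-branch rates
#' (substitutions/site/Myr) from a relaxed clock. The expected substitutions
#' on the edge above node `i` in partition `p` are
#' `rate[i] * (age[parent] - age[i]) * rel_rate[p]`. Site patterns are
#' compressed per partition; per-node rescaling guards against underflow, so
#' the result is finite for any tree depth.
#'
#' @param align a [dna_alignment()].
#' @param tree a [time_tree()]; its taxa must match the alignment's (any
#'   order).
#' @param rates numeric vector of strictly positive branch rates indexed by
#'   child node id (length `2n - 1`, the root entry is ignored), or a single
#'   rate recycled to all branches (a strict clock).
#' @param scheme a [partition_scheme()] covering all alignment sites.
#' @param models named list of [subst_model()]s, one per scheme group.
#' @param rel_rates per-partition relative rate multipliers; defaults to 1 for
#'   all partitions. Estimated multipliers are kept identifiable by the
#'   convention that their mean, weighted by partition length, is 1.
#' @return the log-likelihood (a single finite number, or `-Inf` for data of
#'   probability zero).
#' @export
log_likelihood <- function(align, tree, rates, scheme, models,
                           rel_rates = NULL) {
  lk <- likelihood_data(align, tree, scheme)
  if (length(rates) == 1L) rates <- rep(rates, 2L * tree$n_tip - 1L)
  br <- rates[setdiff(seq_len(2L * tree$n_tip - 1L), tree$root)]
  if (any(!is.finite(br) | br <= 0))
    stop2("branch rates must be strictly positive")
  if (is.null(rel_rates)) rel_rates <- rep(1, length(lk$parts))
  compute_loglik(lk, tree$age, rates, models, rel_rates)
}

# Precompute everything likelihood evaluation needs that does not depend on
# ages, rates or model parameters: postorder edges, compressed patterns and
# tip partial arrays per partition.
likelihood_data <- function(align, tree, scheme) {
  extra <- setdiff(align$taxa, tree$tip_label)
  miss <- setdiff(tree$tip_label, align$taxa)
  if (length(extra) || length(miss))
    stop2("taxa of alignment and tree differ; only in alignment: {",
          paste(extra, collapse = ", "), "}; only in tree: {",
          paste(miss, collapse = ", "), "}")
  validate_partition_scheme(scheme)
  seq <- align$seq[tree$tip_label, , drop = FALSE]  # tree tip order
  po <- postorder_edges(tree)
  ntip <- tree$n_tip
  lut <- iupac_partials()
  parts <- lapply(scheme$groups, function(g) {
    sub <- seq[, g$sites, drop = FALSE]
    key <- apply(sub, 2L, paste, collapse = "")
    uniq <- !duplicated(key)
    pat <- sub[, uniq, drop = FALSE]
    w <- as.vector(table(factor(key, levels = key[uniq])))
    npat <- ncol(pat)
    tip_part <- array(0, c(4L, npat, ntip))
    for (tx in seq_len(ntip))
      tip_part[, , tx] <- vapply(pat[tx, ], function(s) lut[[s]], numeric(4))
    const_part <- apply(tip_part, c(1L, 2L), prod)  # 4 x npat
    # stored as bare numeric vectors so each likelihood call avoids copies
    list(name = g$name, n_site = length(g$sites), weights = as.numeric(w),
         tip_part = as.numeric(tip_part), const_part = as.numeric(const_part))
  })
  list(parts = parts, edges = po, ntip = ntip, nnode = 2L * ntip - 1L)
}

# Evaluate the partitioned log-likelihood from precomputed data.
# models: named list matching names(lk$parts); decomps taken from each model.
compute_loglik <- function(lk, age, rates, models, rel_rates) {
  child <- lk$edges[, "child"]
  parent <- lk$edges[, "parent"]
  base_dist <- rates[child] * (age[parent] - age[child])
  if (any(base_dist < 0)) return(-Inf)
  total <- 0
  for (i in seq_along(lk$parts)) {
    p <- lk$parts[[i]]
    m <- models[[p$name]]
    if (is.null(m)) stop2("no substitution model for partition '", p$name, "'")
    ll <- partition_loglik_cpp(
      m$decomp$A, m$decomp$lambda, m$decomp$B,
      base_dist * rel_rates[i], child, parent,
      as.numeric(p$tip_part), as.numeric(p$const_part), p$weights,
      m$freq, m$cat_rates, m$p_inv, lk$ntip, lk$nnode)
    total <- total + ll
  }
  total
}
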