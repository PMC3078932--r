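#' Simulate an ultrametric birth-death time-tree
#'
#' Samples from the conditioned reconstructed birth-death process (complete
#' sampling, uniform origin prior): the `n - 1` node ages are iid draws from
#' the process's age density (Yule at `a = 0`: exponential with rate `r`),
#' and the ranked topology is built forward in time by splitting a uniformly
#' chosen extant lineage at each speciation — the same measure the
#' birth-death node-age prior evaluates.
#'
#' @param n number of taxa, `>= 2`.
#' @param r net diversification rate (per Myr), `> 0`.
#' @param a relative extinction rate, in `[0, 1)`.
#' @param seed optional random seed.
#' @param labels tip labels (default `t1..tn`, shuffled over tips).
#' @return a [time_tree()].
#' @export
simulate_tree <- function(n, r = 0.1, a = 0, seed = NULL, labels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bd <- bd_params(r, a)
  n <- as.integer(n)
  if (n < 2L) stop2("n must be >= 2")
  ages <- sort(bd_age_quantile(runif(n - 1L), bd$r, bd$a), decreasing = TRUE)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (length(labels) != n) stop2("need ", n, " labels")

  # forward construction: nodes numbered ape-style (tips 1..n, root n+1)
  n_node <- 2L * n - 1L
  parent <- integer(n_node)
  children <- matrix(0L, n - 1L, 2L,
                     dimnames = list(as.character((n + 1L):n_node), NULL))
  age <- numeric(n_node)
  age[(n + 1L):n_node] <- ages          # node n+1 is the root (oldest age)
  # one entry per open child slot = one extant lineage at the current time;
  # columns: node id, slot (1 or 2)
  slots <- cbind(node = c(n + 1L, n + 1L), slot = c(1L, 2L))
  tip_pool <- sample.int(n)             # random label assignment
  next_internal <- n + 2L
  if (n > 2L) for (k in 2L:(n - 1L)) {  # remaining speciations, old -> young
    # the k-th oldest age splits one of the k extant lineages, uniformly
    pick <- sample.int(nrow(slots), 1L)
    who <- slots[pick, "node"]; sl <- slots[pick, "slot"]
    nd <- next_internal; next_internal <- next_internal + 1L
    parent[nd] <- who
    children[as.character(who), sl] <- nd
    slots <- rbind(slots[-pick, , drop = FALSE],
                   cbind(node = c(nd, nd), slot = c(1L, 2L)))
  }
  # remaining open slots become tips at age 0
  for (i in seq_len(nrow(slots))) {
    tip <- tip_pool[i]
    parent[tip] <- slots[i, "node"]
    children[as.character(slots[i, "node"]), slots[i, "slot"]] <- tip
  }
  tr <- structure(list(n_tip = n, tip_label = labels, parent = parent,
                       children = children, age = age, root = n + 1L),
                  class = "time_tree")
  validate_time_tree(tr)
  tr
}

#' Simulate branch rates under the UCLN clock
#'
#' Independent lognormal draws with real-space mean `clock$M` and log-space
#' sd `clock$S` (`S = 0` gives a strict clock with every rate equal to `M`).
#'
#' @param tree a [time_tree()].
#' @param clock a [clock_params()] list.
#' @param seed optional random seed.
#' @return numeric vector over node ids (rate of the branch above each
#'   non-root node; `NA` at the root).
#' @export
simulate_rates <- function(tree, clock, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  clock <- clock_params(clock$M, clock$S)
  n_node <- 2L * tree$n_tip - 1L
  rates <- rep(NA_real_, n_node)
  nonroot <- setdiff(seq_len(n_node), tree$root)
  if (clock$S == 0) rates[nonroot] <- clock$M
  else rates[nonroot] <- rlnorm(length(nonroot),
                                meanlog = log(clock$M) - clock$S^2 / 2,
                                sdlog = clock$S)
  rates
}

#' Simulate a partitioned alignment along a time-tree
#'
#' Root states are drawn from each partition model's stationary frequencies
#' and evolved edge-wise with the model's transition probabilities at
#' distance `rate * (age difference) * rel_rate`, including discrete-gamma
#' site rates and invariant sites. Missing cells (`?`) are masked uniformly
#' at random at the requested fraction.
#'
#' @param tree a [time_tree()].
#' @param rates branch rates as from [simulate_rates()].
#' @param scheme a [partition_scheme()].
#' @param models named list of [subst_model()]s per scheme group.
#' @param missing fraction of cells replaced by `?`.
#' @param rel_rates per-partition relative rate multipliers.
#' @param seed optional random seed.
#' @return a [dna_alignment()] whose sites follow the scheme's layout.
#' @export
simulate_alignment <- function(tree, rates, scheme, models, missing = 0.065,
                               rel_rates = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rel_rates)) rel_rates <- rep(1, length(scheme$groups))
  n <- tree$n_tip
  n_node <- 2L * n - 1L
  if (length(rates) == 1L) rates <- rep(rates, n_node)  # strict clock
  nuc <- c("A", "C", "G", "T")
  total_sites <- sum(vapply(scheme$groups, function(g) length(g$sites), 0L))
  out <- matrix("?", n, max(unlist(lapply(scheme$groups, `[[`, "sites"))))
  rownames(out) <- tree$tip_label
  po <- postorder_edges(tree)
  preorder <- rev(seq_len(nrow(po)))    # parents before children
  for (gi in seq_along(scheme$groups)) {
    g <- scheme$groups[[gi]]
    m <- models[[g$name]]
    L <- length(g$sites)
    # per-site rate: invariant class w.p. p_inv, else a gamma category
    site_rate <- m$cat_rates[sample.int(length(m$cat_rates), L, replace = TRUE)]
    if (m$p_inv > 0) site_rate[runif(L) < m$p_inv] <- 0
    states <- matrix(0L, n_node, L)
    states[tree$root, ] <- sample.int(4L, L, replace = TRUE, prob = m$freq)
    for (e in preorder) {
      ch <- po[e, "child"]; pa <- po[e, "parent"]
      d <- rates[ch] * (tree$age[pa] - tree$age[ch]) * rel_rates[gi]
      for (rc in unique(site_rate)) {
        sel <- site_rate == rc
        if (!any(sel)) next
        if (rc == 0) { states[ch, sel] <- states[pa, sel]; next }
        P <- transition_matrix(m, d * rc)
        cum <- t(apply(P, 1L, cumsum))
        u <- runif(sum(sel))
        from <- states[pa, sel]
        states[ch, sel] <- 1L + rowSums(cum[from, , drop = FALSE] < u)
      }
    }
    out[, g$sites] <- matrix(nuc[states[seq_len(n), ]], n, L)
  }
  if (missing > 0) {
    mask <- runif(length(out)) < missing
    out[mask] <- "?"
  }
  dna_alignment(out)
}

#' Generate node calibrations from a known true tree
#'
#' Truth-consistent calibrations bracket the true node age (uniform bounds
#' contain it; lognormal offsets sit below it; normal means sit near it). A
#' biased ("unreliable") calibration violates this deliberately: its
#' lognormal offset is pushed *above* the true node age by `bias_shift` times
#' the age, emulating a misassigned fossil.
#'
#' Calibrations are placed on reasonably deep nodes (age at least
#' `min_depth` of the root age, root always included): fossil and
#' biogeographic constraints bound major divergences, and sequence data carry
#' essentially no information about the age of very recent splits, so
#' calibrating those would be unrealistic and untestable.
#'
#' @param tree a [time_tree()] with known ages.
#' @param n_cal number of consistent calibrations (root always included).
#' @param nodes optional explicit internal node ids to calibrate (overrides
#'   `n_cal` and the depth filter).
#' @param min_depth minimum node age for the calibration pool, as a fraction
#'   of the root age.
#' @param kinds calibration kinds cycled over the picked nodes.
#' @param bias_node optional internal node id to give a biased calibration.
#' @param bias_shift relative upward shift of the biased offset.
#' @param seed optional random seed.
#' @return named list of [calibration()]s with resolvable taxon sets.
#' @export
make_calibrations <- function(tree, n_cal = 4L, nodes = NULL,
                              kinds = c("uniform", "lognormal_offset", "normal"),
                              bias_node = NULL, bias_shift = 0.5,
                              min_depth = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- tree$n_tip
  internal <- (n + 1L):(2L * n - 1L)
  tips <- descendant_tips(tree)
  if (is.null(nodes)) {
    pool <- setdiff(internal, c(tree$root, bias_node))
    deep <- pool[tree$age[pool] >= min_depth * tree$age[tree$root]]
    # fall back to the oldest remaining nodes when the deep pool is short
    if (length(deep) < n_cal - 1L)
      deep <- unique(c(deep, pool[order(-tree$age[pool])]))[
        seq_len(min(n_cal - 1L, length(pool)))]
    nodes <- c(tree$root,
               deep[sample.int(length(deep), min(n_cal - 1L, length(deep)))])
  }
  if (!is.null(bias_node)) {
    if (bias_node <= n) stop2("cannot place a calibration bias on a leaf")
    if (!bias_node %in% internal) stop2("bias_node is not an internal node")
  }
  build <- function(nd, kind, idx, biased = FALSE) {
    t_true <- tree$age[nd]
    taxa <- tree$tip_label[tips[[nd]]]
    nm <- paste0(if (biased) "bad" else "cal", idx)
    if (biased) {
      off <- t_true * (1 + bias_shift)
      return(calibration(nm, taxa, "lognormal_offset", offset = off,
                         meanlog = log(0.25 * off) - 0.5^2 / 2, sdlog = 0.5))
    }
    switch(kind,
      uniform = calibration(nm, taxa, "uniform",
                            min = t_true * runif(1, 0.55, 0.85),
                            max = t_true * runif(1, 1.15, 1.5)),
      lognormal_offset = {
        off <- t_true * runif(1, 0.5, 0.8)
        calibration(nm, taxa, "lognormal_offset", offset = off,
                    meanlog = log(t_true - off) - 0.5^2 / 2, sdlog = 0.5)
      },
      normal = calibration(nm, taxa, "normal",
                           mean = t_true * runif(1, 0.95, 1.05),
                           sd = 0.1 * t_true, fossil = FALSE))
  }
  cals <- lapply(seq_along(nodes), function(i)
    build(nodes[i], kinds[(i - 1L) %% length(kinds) + 1L], i))
  if (!is.null(bias_node)) {
    bad <- build(bias_node, "lognormal_offset", length(nodes) + 1L,
                 biased = TRUE)
    # keep the scenario runnable: a hard-capped (uniform) ancestor of the
    # biased node must leave room above the biased hard minimum, otherwise
    # the joint prior support is empty and no chain can start
    anc <- ancestor_path(tree, bias_node)
    for (i in seq_along(cals)) {
      if (cals[[i]]$kind == "uniform" && nodes[i] %in% anc &&
          cals[[i]]$max < 1.25 * bad$offset)
        cals[[i]]$max <- 1.25 * bad$offset
    }
    cals <- c(cals, list(bad))
  }
  names(cals) <- vapply(cals, `[[`, "", "name")
  cals
}

#' Generate the default desk-scale synthetic scenario
#'
#' Mirrors the shape of the original study at reduced size: 12 taxa, six loci
#' (two fast "mitochondrial", four slow "nuclear") of 300 bp each under the
#' codon-position partition scheme, 6.5% missing data, and five calibrations
#' (optionally plus one deliberately biased constraint). Writes FASTA +
#' Newick + calibration YAML + a truth table when `dir` is given.
#'
#' @param seed random seed driving every draw.
#' @param n_taxa,n_mt,n_nuc,locus_bp scenario shape.
#' @param missing missing-data fraction.
#' @param clock true clock parameters ([clock_params()]).
#' @param bd true tree-prior parameters ([bd_params()]).
#' @param n_cal number of truth-consistent calibrations.
#' @param biased include a planted unreliable calibration?
#' @param dir optional output directory for scenario files.
#' @return list with `tree`, `rates`, `align`, `scheme`, `models`,
#'   `calibrations`, `truth` (data.frame of true parameter values) and
#'   `files` (paths, when written).
#' @export
simulate_scenario <- function(seed = 1L, n_taxa = 12L, n_mt = 2L, n_nuc = 4L,
                              locus_bp = 300L, missing = 0.065,
                              clock = clock_params(0.02, 0.3),
                              bd = bd_params(0.08, 0.2), n_cal = 5L,
                              biased = FALSE, dir = NULL) {
  set.seed(seed)
  tree <- simulate_tree(n_taxa, bd$r, bd$a)
  rates <- simulate_rates(tree, clock)
  loci <- data.frame(
    name = c(paste0("mt", seq_len(n_mt)), paste0("nuc", seq_len(n_nuc))),
    start = seq(1L, by = locus_bp, length.out = n_mt + n_nuc),
    end = seq(locus_bp, by = locus_bp, length.out = n_mt + n_nuc),
    genome = c(rep("mt", n_mt), rep("nuc", n_nuc)), phase = 1L)
  scheme <- build_partition_scheme(loci)
  models <- list(
    mt_pos12 = subst_model("HKY", kappa = 4, freq = c(.30, .25, .15, .30),
                           alpha = 0.4, p_inv = 0.2),
    mt_pos3 = subst_model("TVM", rates = c(1.2, 3, 0.8, 0.9, 3, 1),
                          freq = c(.35, .25, .10, .30), alpha = 1.5),
    nuc_pos12 = subst_model("K80", kappa = 3, alpha = 0.5, p_inv = 0.3),
    nuc_pos3 = subst_model("GTR", rates = c(1.5, 4, 0.7, 1.1, 5, 1),
                           freq = c(.28, .22, .22, .28), alpha = 1))
  models <- models[names(scheme$groups)]
  # mitochondrial partitions evolve faster than nuclear ones
  rel <- setNames(rep(1, length(scheme$groups)), names(scheme$groups))
  w <- vapply(scheme$groups, function(g) length(g$sites), 0)
  w <- w / sum(w)
  is_mt <- grepl("^mt", names(rel))
  if (any(is_mt) && any(!is_mt)) {
    rho <- 3   # mitochondrial / nuclear rate ratio
    x <- 1 / (sum(w[is_mt]) * rho + sum(w[!is_mt]))
    rel[is_mt] <- rho * x
    rel[!is_mt] <- x
  }
  align <- simulate_alignment(tree, rates, scheme, models, missing = missing,
                              rel_rates = rel)
  bias_node <- if (biased) {
    cand <- setdiff((n_taxa + 1L):(2L * n_taxa - 1L), tree$root)
    cand[which.max(tree$age[cand])]
  }
  cals <- make_calibrations(tree, n_cal = n_cal, bias_node = bias_node)
  truth <- data.frame(
    parameter = c("clock.M", "clock.S", "bd.r", "bd.a",
                  paste0("relrate.", names(rel)),
                  paste0("age.", (n_taxa + 1L):(2L * n_taxa - 1L))),
    value = c(clock$M, clock$S, bd$r, bd$a, unname(rel),
              tree$age[(n_taxa + 1L):(2L * n_taxa - 1L)]))
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(align = file.path(dir, "alignment.fasta"),
                  tree = file.path(dir, "tree.nwk"),
                  calibrations = file.path(dir, "calibrations.yaml"),
                  truth = file.path(dir, "truth.tsv"),
                  loci = file.path(dir, "loci.tsv"))
    write_alignment(align, files$align, "fasta")
    write_newick(tree, files$tree)
    write_calibrations(cals, files$calibrations)
    write.table(truth, files$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(loci, files$loci, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(tree = tree, rates = rates, align = align, scheme = scheme,
       models = models, rel_rates = rel, calibrations = cals, truth = truth,
       files = files)
}
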