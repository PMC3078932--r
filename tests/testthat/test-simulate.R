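test_that("simulated trees have the right shape and ordering", {
  for (n in c(2, 3, 10, 40)) {
    tr <- simulate_tree(n, r = 0.1, a = 0.4, seed = n)
    expect_equal(tr$n_tip, n)
    expect_length(tr$age, 2 * n - 1)
    internal <- (n + 1):(2 * n - 1)
    expect_true(all(tr$age[1:n] == 0))
    expect_equal(tr$age[tr$root], max(tr$age))
    # root strictly oldest, ages strictly positive inside
    if (n > 2) expect_true(all(tr$age[setdiff(internal, tr$root)] <
                                 tr$age[tr$root]))
    expect_silent(divtime:::validate_time_tree(tr))
  }
  expect_error(simulate_tree(1, 0.1, 0), "n must")
  expect_error(simulate_tree(5, -0.1, 0), "r must")
  expect_error(simulate_tree(5, 0.1, 1), "a must")
})

test_that("Yule trees match the lineage-through-time expectation", {
  # with iid exponential ages, E[lineages older than t] = 1 + (n-1) e^{-rt}
  set.seed(55)
  n <- 10; r <- 0.1
  reps <- 500
  ts <- c(2, 5, 10, 20)
  counts <- matrix(0, reps, length(ts))
  for (i in seq_len(reps)) {
    tr <- simulate_tree(n, r, 0)
    ages <- tr$age[(n + 1):(2 * n - 1)]
    counts[i, ] <- vapply(ts, function(t) 1 + sum(ages > t), 0)
  }
  expected <- 1 + (n - 1) * exp(-r * ts)
  expect_equal(colMeans(counts), expected, tolerance = 0.05)
})

test_that("birth-death node ages follow the conditioned age density", {
  set.seed(56)
  r <- 0.1; a <- 0.6
  ages <- unlist(lapply(1:300, function(i) {
    tr <- simulate_tree(6, r, a)
    tr$age[7:11]
  }))
  ks <- divtime:::ks_distance(ages, divtime:::bd_age_cdf, r = r, a = a)
  expect_lt(ks, 0.05)
})

test_that("UCLN rate draws honour the requested moments", {
  tr <- simulate_tree(12, 0.1, 0.2, seed = 3)
  rts <- simulate_rates(tr, clock_params(0.02, 0), seed = 4)
  expect_true(all(rts[-tr$root] == 0.02))
  expect_true(is.na(rts[tr$root]))
  big <- simulate_tree(2, 0.1, 0, seed = 5)
  set.seed(6)
  draws <- replicate(5000, simulate_rates(big, clock_params(0.02, 0.5))[1])
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.02), 3 * se)
  expect_true(all(draws > 0))
})

test_that("alignment simulation respects degenerate and stationary limits", {
  tr <- simulate_tree(6, 0.1, 0.2, seed = 8)
  sch <- one_locus_scheme(30)
  m <- subst_model("HKY+G", kappa = 3, freq = c(.3, .2, .2, .3), alpha = 0.5)
  models <- list(nuc_pos12 = m, nuc_pos3 = m)
  # (near-)zero rates: all sequences identical to the root draw
  aln0 <- simulate_alignment(tr, 1e-12, sch, models, missing = 0, seed = 9)
  for (i in 2:6)
    expect_equal(unname(aln0$seq[i, ]), unname(aln0$seq[1, ]))
  # long simulation: empirical frequencies near pi
  big <- one_locus_scheme(100000)
  two <- simulate_tree(2, 0.1, 0, seed = 10)
  aln <- simulate_alignment(two, 0.05, big, models, missing = 0, seed = 11)
  emp <- as.numeric(table(factor(aln$seq, levels = c("A", "C", "G", "T"))))
  emp <- emp / sum(emp)
  expect_equal(emp, m$freq, tolerance = 0.01)
  # requested missingness is hit
  alnm <- simulate_alignment(two, 0.05, one_locus_scheme(5000), models,
                             missing = 0.065, seed = 12)
  expect_lt(abs(missing_fraction(alnm) - 0.065), 0.01)
})

test_that("the generating parameters beat perturbed ones in likelihood", {
  set.seed(60)
  wins <- 0; reps <- 25
  tr <- simulate_tree(6, 0.1, 0.2, seed = 61)
  sch <- one_locus_scheme(400)
  for (i in seq_len(reps)) {
    m <- subst_model("HKY+G", kappa = 3, freq = c(.3, .2, .2, .3), alpha = 0.5)
    m_bad <- subst_model("HKY+G", kappa = 3, freq = c(.3, .2, .2, .3), alpha = 1.0)
    models <- list(nuc_pos12 = m, nuc_pos3 = m)
    aln <- simulate_alignment(tr, 0.1, sch, models, missing = 0.05)
    ll_true <- log_likelihood(aln, tr, 0.1, sch, models)
    ll_bad <- log_likelihood(aln, tr, 0.1, sch,
                             list(nuc_pos12 = m_bad, nuc_pos3 = m_bad))
    wins <- wins + (ll_true > ll_bad)
  }
  expect_gte(wins / reps, 0.9)
})

test_that("generated calibrations bracket the truth except the planted one", {
  tr <- simulate_tree(10, 0.1, 0.2, seed = 70)
  bias_nd <- setdiff(11:19, tr$root)[1]
  cals <- make_calibrations(tr, n_cal = 4, bias_node = bias_nd, seed = 71)
  expect_length(cals, 5)
  for (cal in cals) {
    nd <- mrca_node(tr, cal$taxa)
    t_true <- tr$age[nd]
    if (startsWith(cal$name, "bad")) {
      expect_gt(cal$offset, t_true)   # hard bound excludes the truth
    } else {
      iv <- divtime:::calibration_interval(cal)
      expect_gte(t_true, iv[1])
      expect_lte(t_true, iv[2])
      if (cal$kind == "lognormal_offset") expect_lt(cal$offset, t_true)
    }
  }
  expect_error(make_calibrations(tr, nodes = 12, bias_node = 3), "leaf")
})

test_that("the packaged scenario writes re-readable artifacts", {
  dir <- withr::local_tempdir()
  sc <- simulate_scenario(seed = 5, n_taxa = 8, locus_bp = 60, dir = dir)
  expect_equal(missing_fraction(sc$align), 0.065, tolerance = 0.02)
  aln <- read_alignment(sc$files$align, "fasta")
  expect_equal(aln$seq, sc$align$seq, ignore_attr = TRUE)
  tr <- parse_newick(file = sc$files$tree)
  expect_equal(sort(tr$tip_label), sort(sc$tree$tip_label))
  expect_equal(tr$age[tr$root], sc$tree$age[sc$tree$root], tolerance = 1e-6)
  cals <- read_calibrations(sc$files$calibrations)
  expect_equal(names(cals), names(sc$calibrations))
  truth <- read.table(sc$files$truth, header = TRUE, sep = "\t")
  expect_true(all(c("clock.M", "bd.r") %in% truth$parameter))
  # identical seed, identical files
  dir2 <- withr::local_tempdir()
  sc2 <- simulate_scenario(seed = 5, n_taxa = 8, locus_bp = 60, dir = dir2)
  expect_identical(readLines(sc$files$align), readLines(sc2$files$align))
  expect_identical(readLines(sc$files$tree), readLines(sc2$files$tree))
})
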