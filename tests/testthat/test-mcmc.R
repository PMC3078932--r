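test_that("configuration constraints are enforced", {
  expect_error(divtime_config(chain_length = 50, sample_every = 10),
               "at least 10")
  expect_error(divtime_config(burnin = 1), "burnin")
  expect_error(divtime_config(burnin = -0.1), "burnin")
})

test_that("identical seeds give byte-identical traces", {
  prob <- small_dating_problem(101)
  cfg <- quick_config(chain_length = 500, sample_every = 10, seed = 42)
  t1 <- run_mcmc(prob$align, prob$tree, prob$scheme, prob$models,
                 prob$calibrations, cfg)
  t2 <- run_mcmc(prob$align, prob$tree, prob$scheme, prob$models,
                 prob$calibrations, cfg)
  expect_identical(t1, t2)
})

test_that("each trace record satisfies the posterior identity and hard bounds", {
  prob <- small_dating_problem(102)
  cfg <- quick_config(chain_length = 1500, sample_every = 10, seed = 7)
  tr <- run_mcmc(prob$align, prob$tree, prob$scheme, prob$models,
                 prob$calibrations, cfg)
  expect_equal(tr$posterior, tr$likelihood + tr$prior, tolerance = 1e-8)
  expect_true(all(diff(tr$state) > 0))
  # age ordering within every sampled state
  n <- prob$tree$n_tip
  for (nd in setdiff((n + 1):(2 * n - 1), prob$tree$root)) {
    pa <- prob$tree$parent[nd]
    if (pa > n)
      expect_true(all(tr[[paste0("age.", pa)]] > tr[[paste0("age.", nd)]]))
  }
  # hard calibration bounds never violated
  cal_nodes <- divtime:::resolve_calibrations(prob$tree, prob$calibrations)
  for (i in seq_along(cal_nodes)) {
    sup <- divtime:::calibration_support(prob$calibrations[[i]])
    x <- tr[[paste0("age.", cal_nodes[i])]]
    expect_true(all(x >= sup[1] & x <= sup[2]))
  }
})

test_that("non-monophyletic calibration clades are refused by name", {
  tr <- parse_newick("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  bad <- list(calibration("split_pair", c("A", "C"), "uniform",
                          min = 1, max = 3))
  expect_error(run_mcmc(NULL, tr, calibrations = bad,
                        config = quick_config(prior_only = TRUE)),
               "split_pair")
})

test_that("prior-only sampling reproduces a lone uniform calibration", {
  tr <- parse_newick("(A:40,B:40);")
  cal <- list(calibration("J", c("A", "B"), "uniform",
                          min = 32.25, max = 56.0))
  cfg <- divtime_config(chain_length = 20000, sample_every = 10,
                        replicates = 2, prior_only = TRUE,
                        tree_prior = "none", seed = 1)
  fit <- suppressWarnings(divtime(NULL, tr, cal, config = cfg))
  x <- fit$trace[["age.3"]]
  # analytic mean (32.25 + 56)/2 = 44.125, sd = 23.75/sqrt(12)
  mc_se <- (56 - 32.25) / sqrt(12) / sqrt(ess(x))
  expect_lt(abs(mean(x) - 44.125), 3 * mc_se)
  expect_gte(min(x), 32.25)
  expect_lte(max(x), 56.0)
})

test_that("prior-only node-age marginals match the birth-death closed form", {
  # 3-taxon detailed-balance smoke test: with fixed (r, a) the root age is
  # the max and the other node the min of two iid draws from the BD age law
  tr <- simulate_tree(3, 0.1, 0.3, seed = 5)
  cfg <- divtime_config(chain_length = 60000, sample_every = 10,
                        replicates = 2, prior_only = TRUE, seed = 2,
                        operator_weights = c(bd_r = 0, bd_a = 0),
                        init = list(r = 0.1, a = 0.3))
  fit <- suppressWarnings(divtime(NULL, tr, list(), config = cfg))
  G <- function(t) divtime:::bd_age_cdf(t, 0.1, 0.3)
  ks_root <- divtime:::ks_distance(fit$trace[["age.4"]],
                                   function(q) G(q)^2)
  ks_child <- divtime:::ks_distance(fit$trace[["age.5"]],
                                    function(q) 1 - (1 - G(q))^2)
  expect_lt(ks_root, 0.05)
  expect_lt(ks_child, 0.05)
})

test_that("ESS recovers iid and AR(1) information content", {
  set.seed(4)
  x <- rnorm(1e4)
  expect_lt(abs(ess(x) - 1e4) / 1e4, 0.15)
  # AR(1), rho = 0.5: ESS -> N (1-rho)/(1+rho) = N/3
  rho <- 0.5
  ar <- as.numeric(stats::arima.sim(list(ar = rho), 1e4))
  target <- 1e4 * (1 - rho) / (1 + rho)
  expect_lt(abs(ess(ar) - target) / target, 0.20)
  expect_warning(e <- ess(rep(2, 100)), "constant")
  expect_equal(e, 100)
  expect_error(ess(1:5), "at least 10")
})

test_that("HPD equals the brute-force shortest-window search", {
  h <- hpd(1:100, 0.95)
  expect_equal(h[2] - h[1], 95)           # 96 consecutive integers
  set.seed(10)
  for (i in 1:10) {
    x <- switch(i %% 3 + 1, rnorm(200), rlnorm(150), rgamma(300, 2))
    for (lv in c(0.5, 0.9, 0.95))
      expect_equal(hpd(x, lv), hpd_bruteforce(x, lv))
  }
  expect_equal(hpd(rep(3.3, 50)), c(3.3, 3.3))
  expect_error(hpd(1:100, 1.2), "level")
  expect_error(hpd(1:10), "at least 20")
})

test_that("combining traces removes burn-in and preserves replicate ids", {
  mk <- function(rep, n = 100) {
    tr <- data.frame(state = seq_len(n), posterior = rnorm(n),
                     likelihood = 0, prior = 0, replicate = rep)
    class(tr) <- c("mcmc_trace", "data.frame"); tr
  }
  set.seed(2)
  a <- mk(1); b <- mk(2)
  comb <- combine_traces(list(a, b), 0.1)
  expect_equal(nrow(comb), 180)
  expect_equal(unique(comb$replicate), c(1, 2))
  # doubling a trace doubles every sample count
  dbl <- combine_traces(list(a, a), 0)
  expect_equal(nrow(dbl), 200)
  # combined mean is the weighted mean of replicate means
  expect_equal(mean(comb$posterior),
               mean(c(a$posterior[11:100], b$posterior[11:100])))
  names(b)[2] <- "post"
  expect_error(combine_traces(list(a, b), 0.1), "schema")
})

test_that("traces round-trip through the tab-separated log format", {
  prob <- small_dating_problem(103)
  cfg <- quick_config(chain_length = 300, sample_every = 10, seed = 3)
  tr <- run_mcmc(prob$align, prob$tree, prob$scheme, prob$models,
                 prob$calibrations, cfg)
  f <- withr::local_tempfile(fileext = ".log")
  write_trace(tr, f)
  expect_identical(readLines(f)[1],
                   paste(names(tr), collapse = "\t"))
  back <- read_trace(f)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12,
               ignore_attr = TRUE)
})
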