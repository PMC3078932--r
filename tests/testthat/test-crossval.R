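test_that("concordance scores prior-posterior fit as an inside fraction", {
  cal_u <- calibration("u", NULL, "uniform", min = 10, max = 20)
  # all samples at the prior median
  expect_equal(concordance(rep(15, 200), cal_u), 1)
  # posterior entirely below a hard lower bound
  cal_l <- calibration("l", NULL, "lognormal_offset", offset = 50,
                       meanlog = 2, sdlog = 0.5)
  expect_equal(concordance(runif(200, 10, 40), cal_l), 0)
  expect_error(concordance(1:50, cal_u), "at least 100")
  # samples drawn from the prior itself score about the interval mass
  # (exactly 1 for uniform, whose hard bounds are used as-is)
  set.seed(1)
  expect_equal(concordance(divtime:::calibration_draw(cal_u, 1e4), cal_u), 1)
  for (cal in list(calibration("n", NULL, "normal", mean = 30, sd = 4),
                   cal_l)) {
    x <- divtime:::calibration_draw(cal, 1e4)
    expect_equal(concordance(x, cal), 0.95, tolerance = 0.03,
                 label = paste("kind", cal$kind))
  }
})

test_that("threshold zero retains everything in a single round", {
  prob <- small_dating_problem(301)
  cfg <- quick_config(chain_length = 1500, sample_every = 10, seed = 5)
  rep <- suppressWarnings(crossval_calibrations(
    prob$align, prob$tree, prob$scheme, prob$models, prob$calibrations,
    cfg, threshold = 0))
  expect_s3_class(rep, "crossval_report")
  expect_equal(sort(rep$final_set), sort(names(prob$calibrations)))
  expect_true(all(rep$scores$decision == "retained"))
  expect_equal(max(rep$history$round), 1)
})

test_that("fewer than two calibrations is untestable", {
  prob <- small_dating_problem(302)
  expect_error(crossval_calibrations(prob$align, prob$tree, prob$scheme,
                                     prob$models, prob$calibrations[1],
                                     quick_config()),
               "untestable")
})

test_that("a planted unreliable calibration is excluded, consistent ones kept", {
  # one deliberately misdated constraint (hard bound above the true age)
  # among truth-consistent ones; moderate chains are enough because the
  # planted violation is gross
  set.seed(303)
  sc <- simulate_scenario(seed = 303, n_taxa = 10, n_mt = 1, n_nuc = 1,
                          locus_bp = 250, n_cal = 4, biased = TRUE)
  cfg <- divtime_config(chain_length = 3000, sample_every = 10,
                        replicates = 1, seed = 303,
                        init = list(M = 0.02, S = 0.3, r = 0.08, a = 0.2))
  rep <- suppressWarnings(crossval_calibrations(
    sc$align, sc$tree, sc$scheme, sc$models, sc$calibrations, cfg,
    rel_rates = sc$rel_rates))
  bad <- grep("^bad", names(sc$calibrations), value = TRUE)
  expect_false(bad %in% rep$final_set)
  expect_setequal(rep$final_set, setdiff(names(sc$calibrations), bad))
  # report invariants: decisions partition the input set, history non-empty
  expect_setequal(rep$scores$calibration, names(sc$calibrations))
  expect_gte(nrow(rep$history), length(sc$calibrations))
  # reproducibility under a fixed seed
  rep2 <- suppressWarnings(crossval_calibrations(
    sc$align, sc$tree, sc$scheme, sc$models, sc$calibrations, cfg,
    rel_rates = sc$rel_rates))
  expect_identical(rep$scores, rep2$scores)
})

test_that("reports serialize to TSV plus structured summary", {
  prob <- small_dating_problem(304)
  cfg <- quick_config(chain_length = 1500, sample_every = 10, seed = 6)
  rep <- suppressWarnings(crossval_calibrations(
    prob$align, prob$tree, prob$scheme, prob$models, prob$calibrations,
    cfg, threshold = 0))
  dir <- withr::local_tempdir()
  files <- write_crossval_report(rep, dir)
  tab <- read.table(files[1], header = TRUE, sep = "\t")
  expect_setequal(tab$calibration, rep$scores$calibration)
  y <- yaml::read_yaml(files[2])
  expect_equal(y$schema, "divtime-crossval/1")
  expect_setequal(unlist(y$final_set), rep$final_set)
})
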