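test_that("calibration densities honour hard and soft bounds", {
  cals <- paper_calibrations()
  # node B: hard lower bound at the zeid fossil age 55.8 Ma
  expect_identical(calibration_log_density(cals$B, 50.0), -Inf)
  expect_identical(calibration_log_density(cals$B, 55.8), -Inf)
  expect_true(is.finite(calibration_log_density(cals$B, 60)))
  # node J: uniform log density inside its bounds
  expect_equal(calibration_log_density(cals$J, 40), log(1 / (56.0 - 32.25)),
               tolerance = 1e-4)
  expect_identical(calibration_log_density(cals$J, 30), -Inf)
  expect_identical(calibration_log_density(cals$J, 60), -Inf)
  # node E: normal density peaks at its 110 Ma mean
  ages <- seq(60, 160, by = 0.5)
  dens <- calibration_log_density(cals$E, ages)
  expect_equal(ages[which.max(dens)], 110.0)
  expect_error(calibration_log_density(cals$E, -1), "non-negative")
})

test_that("the acanthomorph fixture carries the published constraints", {
  cals <- paper_calibrations()
  expect_length(cals, 10)
  expect_equal(names(cals), LETTERS[1:10])
  expect_equal(sum(!vapply(cals, `[[`, TRUE, "fossil")), 2L)
  expect_equal(c(cals$G$min, cals$G$max), c(96.9, 150.9))
  expect_equal(c(cals$C$min, cals$C$max), c(96.9, 150.9))
  expect_equal(c(cals$F$min, cals$F$max), c(14.0, 20.5))
  expect_equal(c(cals$J$min, cals$J$max), c(32.25, 56.0))
  offs <- vapply(cals[c("A", "B", "D", "H", "I")], `[[`, 0, "offset")
  expect_equal(unname(offs), c(93.5, 55.8, 61.7, 37.2, 48.6))
  # node E sd from inverting its central 95% interval (98.2, 121.8)
  expect_equal(cals$E$sd, 11.8 / qnorm(0.975), tolerance = 1e-6)
  expect_equal(qnorm(0.025, cals$E$mean, cals$E$sd), 98.2, tolerance = 1e-6)
  expect_equal(qnorm(0.975, cals$E$mean, cals$E$sd), 121.8, tolerance = 1e-6)
})

test_that("every calibration density integrates to one with the advertised support", {
  cals <- c(paper_calibrations(),
            list(x = calibration("x", NULL, "lognormal_offset", offset = 10,
                                 meanlog = 1, sdlog = 0.4)))
  for (cal in cals) {
    f <- function(a) exp(calibration_log_density(cal, a))
    dom <- switch(cal$kind, uniform = c(cal$min, cal$max),
                  lognormal_offset = c(cal$offset, Inf),
                  normal = c(max(0, cal$mean - 12 * cal$sd),
                             cal$mean + 12 * cal$sd))
    total <- integrate(f, dom[1], dom[2], rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6, label = paste("calibration", cal$name))
    sup <- divtime:::calibration_support(cal)
    if (cal$kind != "normal") {
      expect_identical(calibration_log_density(cal, max(sup[1] - 1e-6, 0)),
                       -Inf)
      if (is.finite(sup[2]))
        expect_identical(calibration_log_density(cal, sup[2] + 1e-6), -Inf)
    }
  }
})

test_that("calibration sets round-trip through the YAML config format", {
  cals <- c(paper_calibrations(),
            make_calibrations(simulate_tree(6, 0.1, 0.2, seed = 3),
                              n_cal = 3, seed = 4))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_calibrations(cals, f)
  back <- read_calibrations(f)
  expect_equal(names(back), names(cals))
  for (nm in names(cals))
    expect_equal(unclass(back[[nm]]), unclass(cals[[nm]]), tolerance = 1e-12,
                 label = paste("calibration", nm))
})

test_that("the packaged fixture file matches the in-code fixture", {
  f <- system.file("extdata", "acanthomorph_calibrations.yaml",
                   package = "divtime")
  expect_true(nzchar(f))
  cals <- read_calibrations(f)
  ref <- paper_calibrations()
  expect_equal(names(cals), names(ref))
  expect_equal(cals$B$offset, 55.8)
})
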