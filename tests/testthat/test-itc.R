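test_that("bound_fraction solves the mass-action equilibrium", {
  expect_equal(bound_fraction(40e-6, 0, 1, 3.8e-6), 0)
  # stoichiometric limit: kd -> 0 with titrant below saturation
  expect_equal(bound_fraction(40e-6, 30e-6, 1, 1e-15), 30e-6,
               tolerance = 1e-9)
  # against a high-precision bisection oracle
  for (xt in c(5e-6, 40e-6, 120e-6)) {
    expect_equal(bound_fraction(40e-6, xt, 1, 3.8e-6),
                 bisect_bound(40e-6, xt, 1, 3.8e-6),
                 tolerance = 1e-12)
  }
  expect_error(bound_fraction(-1e-6, 1e-6, 1, 1e-6), "must be")
})

test_that("simulate_isotherm obeys baseline, conservation and oracle checks", {
  design <- itc_experiment(40e-6, 400e-6, rep(2e-6, 25),
                           cell_volume = 185e-6, temperature = 15)
  # zero enthalpy: every heat is the offset
  expect_equal(simulate_isotherm(design, 1, 3.8e-6, dh = 0,
                                 q_offset = 1.5),
               rep(1.5, 25))
  # saturating single small injection: total heat = n * mt * V0 * dh
  sat <- itc_experiment(40e-6, 1, 1e-6, cell_volume = 1.4e-3)
  h <- simulate_isotherm(sat, 1, 1e-12, -8000)
  expect_equal(sum(h), -8000 * 40e-6 * 1.4e-3 * 1e6, tolerance = 1e-3)
  # per-injection heats match an independent bisection re-solve
  h1 <- simulate_isotherm(design, 1, 3.8e-6, -8000, q_offset = 0.2)
  h2 <- oracle_isotherm(design, 1, 3.8e-6, -8000, q_offset = 0.2)
  expect_equal(h1, h2, tolerance = 1e-9)
  # over-injection is a design error
  expect_error(itc_experiment(40e-6, 400e-6, rep(20e-6, 10),
                              cell_volume = 185e-6),
               "cell volume")
})

test_that("splitting injections perturbs total heat only at second order", {
  # displacement dilution makes the total heat depend on the injection
  # granularity through (v/V0)^2 terms; halving the step halves the gap
  totals <- vapply(c(2e-6, 1e-6, 0.5e-6), function(v) {
    d <- itc_experiment(40e-6, 400e-6, rep(v, round(50e-6 / v)),
                        cell_volume = 185e-6)
    sum(simulate_isotherm(d, 1, 3.8e-6, -8000))
  }, numeric(1))
  gap21 <- abs(totals[2] - totals[1])
  gap32 <- abs(totals[3] - totals[2])
  expect_lt(abs(totals[2] - totals[1]) / abs(totals[1]), 0.005)
  expect_lt(gap32, 0.6 * gap21)   # first-order-in-step convergence of totals
})

test_that("noiseless isotherms round-trip n, Kd and dH within 1%", {
  for (kd in c(3.8e-6, 6.5e-6)) {
    iso <- make_itc_isotherm(n = 1, kd = kd, dh = -8000, q_offset = 0.3)
    fit <- fit_isotherm(iso)
    expect_true(fit$converged)
    expect_equal(fit$n, 1, tolerance = 0.01)
    expect_equal(fit$kd, kd, tolerance = 0.01)
    expect_equal(fit$dh, -8000, tolerance = 0.01)
    expect_equal(fit$q_offset, 0.3, tolerance = 0.05)
  }
})

test_that("degenerate heat vectors do not converge", {
  design <- itc_experiment(40e-6, 400e-6, rep(2e-6, 25),
                           cell_volume = 185e-6)
  design$heats <- withr::with_seed(5, rnorm(25, sd = 2))
  fit <- suppressWarnings(fit_isotherm(design))
  expect_false(fit$converged)
  design$heats <- rep(1.7, 25)
  fit2 <- suppressWarnings(fit_isotherm(design))
  expect_false(fit2$converged)
  short <- itc_experiment(40e-6, 400e-6, rep(2e-6, 4),
                          cell_volume = 185e-6, heats = rep(1, 4))
  expect_error(fit_isotherm(short), "at least 5")
})

test_that("recovery holds across the Wiseman c range and flags low c", {
  mt <- 40e-6
  for (c_par in c(1, 10, 100, 1000)) {
    kd <- mt / c_par
    iso <- make_itc_isotherm(n = 1, kd = kd, dh = -8000)
    fit <- fit_isotherm(iso)
    expect_equal(fit$n, 1, tolerance = 0.01)
    expect_equal(fit$kd, kd, tolerance = 0.01)
    expect_equal(fit$dh, -8000, tolerance = 0.01)
    expect_false(fit$n_poorly_determined)
  }
  # c = 0.2: the isotherm is featureless in n; the fit must say so
  iso_low <- make_itc_isotherm(n = 1, kd = mt / 0.2, dh = -8000)
  fit_low <- fit_isotherm(iso_low)
  expect_true(fit_low$n_poorly_determined)
})

test_that("median Kd error stays under 10% with 2% heat noise at c ~ 10", {
  # 200 seeded replicates give a stable estimate of the median (the least-
  # squares estimator sits on the Cramer-Rao bound for this design, with a
  # CRLB-implied median of ~8.4%); the objective basin is unimodal here, so
  # each replicate is fitted from one neutral start
  kd <- 4e-6
  first_heat <- abs(simulate_isotherm(
    itc_experiment(40e-6, 400e-6, rep(2e-6, 25), cell_volume = 185e-6),
    1, kd, -8000)[1])
  errs <- vapply(1:200, function(i) {
    iso <- make_itc_isotherm(n = 1, kd = kd, dh = -8000,
                             noise_sd = 0.02 * first_heat, seed = 1000 + i)
    fit <- fit_isotherm(iso, initial_guess = list(n = 1, kd = 1e-5))
    abs(fit$kd - kd) / kd
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("ITC experiments round-trip through TSV and fits through JSON", {
  iso <- make_itc_isotherm(n = 1, kd = 3.8e-6, dh = -8000, noise_sd = 0.5,
                           seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_itc(iso, f)
  back <- read_itc(f)
  expect_equal(back$cell_conc, iso$cell_conc)
  expect_equal(back$syringe_conc, iso$syringe_conc)
  expect_equal(back$injection_volumes, iso$injection_volumes)
  expect_equal(back$heats, iso$heats, tolerance = 1e-6)
  fit <- fit_isotherm(back)
  fj <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, fj)
  parsed <- jsonlite::read_json(fj)
  expect_equal(parsed$kd, fit$kd, tolerance = 1e-9)
})

test_that("excluding the first injection still recovers the parameters", {
  iso <- make_itc_isotherm(n = 1, kd = 3.8e-6, dh = -8000)
  iso$heats[1] <- iso$heats[1] * 0.6   # classic short first injection
  fit <- fit_isotherm(iso, exclude_first = TRUE)
  expect_equal(fit$kd, 3.8e-6, tolerance = 0.01)
  expect_equal(fit$n, 1, tolerance = 0.01)
})
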