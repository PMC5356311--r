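test_that("absorbance slopes convert to turnovers by Beer-Lambert", {
  expect_equal(rate_from_absorbance(0.0065, 6500, 1, 0.1), 10)
  # doubling the enzyme halves the turnover
  expect_equal(rate_from_absorbance(0.0065, 6500, 1, 0.2), 5)
  expect_error(rate_from_absorbance(0.01, 0, 1, 0.1), "epsilon")
  # the bundled extinction table is positive and complete
  eps <- extinction_coefficients()
  expect_true(all(eps$epsilon_M_cm > 0))
  expect_setequal(eps$substrate, c("Mn2+", "VA", "DMP", "ABTS", "RB5"))
})

test_that("noiseless single-site curves are recovered exactly", {
  km <- 62; kcat <- 106
  curve <- simulate_kinetic_curve(km * c(0.25, 0.5, 1, 2, 3, 4, 6, 8),
                                  km, kcat)
  fit <- fit_michaelis_menten(curve)
  td <- tidy(fit)
  expect_equal(td$Km_uM, km, tolerance = 1e-6)
  expect_equal(td$kcat_s, kcat, tolerance = 1e-6)
  expect_equal(td$efficiency_s_mM, 1000 * kcat / km, tolerance = 1e-6)
  expect_error(fit_michaelis_menten(curve[1:4, ]), "distinct")
})

test_that("noisy single-site recovery has small median error", {
  km <- 62; kcat <- 106
  conc <- exp(seq(log(km / 4), log(8 * km), length.out = 8))
  errs <- sapply(1:100, function(seed) {
    curve <- simulate_kinetic_curve(conc, km, kcat, sd = 0.02 * kcat,
                                    replicates = 3, seed = seed)
    td <- tidy(fit_michaelis_menten(curve))
    c(abs(td$Km_uM - km) / km, abs(td$kcat_s - kcat) / kcat)
  })
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.05)
})

test_that("the least-squares fit beats or matches a grid-search oracle", {
  set.seed(44)
  for (i in 1:10) {
    km <- runif(1, 20, 500)
    kcat <- runif(1, 5, 300)
    conc <- exp(seq(log(km / 5), log(10 * km), length.out = 9))
    curve <- simulate_kinetic_curve(conc, km, kcat, sd = 0.03 * kcat,
                                    seed = 1000 + i)
    fit <- fit_michaelis_menten(curve)
    oracle <- mm_grid_oracle(curve, c(km / 10, km * 10),
                             c(kcat * 0.3, kcat * 3))
    # the continuous optimum cannot be worse than the best grid point
    expect_lte(fit$rss, oracle$sse * 1.005)
    td <- tidy(fit)
    expect_equal(td$Km_uM, oracle$Km, tolerance = 0.05)
    expect_equal(td$kcat_s, oracle$kcat, tolerance = 0.05)
  }
})

test_that("saturation warning fires when Km exceeds the assayed range", {
  curve <- simulate_kinetic_curve(c(1, 2, 4, 8, 16, 32), 500, 10)
  expect_warning(fit_michaelis_menten(curve), "saturated")
})

test_that("noiseless biphasic curves recover both sites within 1%", {
  conc <- c(1, 2, 5, 10, 30, 100, 300, 1000, 3000, 1e4, 3e4, 1e5, 3e5)
  curve <- simulate_kinetic_curve(conc, c(5.3, 32500), c(4.5, 31))
  fit <- fit_two_site(curve)
  td <- tidy(fit)
  # site 1 is the low-Km, high-efficiency site
  expect_equal(td$Km_uM, c(5.3, 32500), tolerance = 0.01)
  expect_equal(td$kcat_s, c(4.5, 31), tolerance = 0.01)
  expect_true(fit$comparison$preferred[fit$comparison$model == "two-site"])
})

test_that("AIC prefers the single-site model for single-site data", {
  conc <- exp(seq(log(10), log(5000), length.out = 10))
  curve <- simulate_kinetic_curve(conc, 150, 40, sd = 0.4, replicates = 3,
                                  seed = 77)
  fit <- suppressWarnings(fit_two_site(curve))
  expect_true(fit$comparison$preferred[fit$comparison$model == "single"])
})

test_that("degenerate two-site designs are flagged or collapse to one site", {
  conc <- exp(seq(log(5), log(5000), length.out = 12))
  # identical Km in both sites: ill-conditioned by design
  curve <- simulate_kinetic_curve(conc, c(100, 100), c(20, 20))
  expect_warning(fit_two_site(curve), "ill-conditioned")
  # one site with kcat ~ 0 reduces to the single-site fit
  curve2 <- simulate_kinetic_curve(conc, 120, 30)
  f2 <- suppressWarnings(fit_two_site(curve2))
  td2 <- tidy(f2)
  active <- which.max(td2$kcat_s)
  single <- tidy(fit_michaelis_menten(curve2))
  expect_equal(td2$Km_uM[active], single$Km_uM, tolerance = 1e-4)
  expect_equal(td2$kcat_s[active] + td2$kcat_s[-active], single$kcat_s,
               tolerance = 1e-4)
})

test_that("catalytic efficiency applies the unit factor once", {
  expect_equal(catalytic_efficiency(62, 106, 3), 1710)
  expect_equal(catalytic_efficiency(1000, 1), 1)
  expect_equal(catalytic_efficiency(3170, 539, 3), 170)
  expect_error(catalytic_efficiency(0, 10), "Km")
})

test_that("fold changes reproduce the usual n-fold statements", {
  expect_equal(fold_change(700, 62, "rounded"), 11)
  expect_equal(fold_change(205, 28, "rounded"), 7)
  expect_equal(fold_change(5, 5), 1)
  expect_error(fold_change(1, 0), "zero")
})

test_that("relative efficiency normalises to the per-substrate maximum", {
  eff <- tibble::tibble(
    enzyme = rep(c("E1", "E2", "E3"), 2),
    substrate = rep(c("Mn2+", "VA"), each = 3),
    efficiency = c(260, 617, 1710, NA, 24, 205))
  prof <- relative_efficiency_profile(eff)
  mn <- prof$relative_pct[prof$substrate == "Mn2+"]
  expect_equal(mn, c(15.2, 36.1, 100), tolerance = 0.01)
  # absent activity reports 0%
  expect_equal(prof$relative_pct[is.na(prof$efficiency)], 0)
  # single enzyme is trivially 100%
  one <- relative_efficiency_profile(
    tibble::tibble(enzyme = "E", substrate = "S", efficiency = 7))
  expect_equal(one$relative_pct, 100)
  expect_error(relative_efficiency_profile(
    tibble::tibble(enzyme = "E", substrate = "S", efficiency = NA)),
    "no positive")
})
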