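test_that("distribution specs validate and draw from the right family", {
  expect_error(dist_spec("normal", mean = 1), "sd")
  expect_error(dist_spec("truncnorm", mean = 0, sd = 1, lower = 2,
                         upper = 1), "lower < upper")
  set.seed(1)
  u <- draw_spec(dist_spec("uniform", min = 2, max = 3), 500)
  expect_true(all(u >= 2 & u <= 3))
  tn <- draw_spec(dist_spec("truncnorm", mean = 0, sd = 1, lower = 0,
                            upper = 1), 500)
  expect_true(all(tn >= 0 & tn <= 1))
  emp <- draw_spec(dist_spec("empirical", values = c(1, 5, 9)), 200)
  expect_true(all(emp %in% c(1, 5, 9)))
  expect_equal(draw_spec(dist_spec("point", value = 7), 3), rep(7, 3))
})

test_that("negative normal draws are redrawn, with a rejection cap", {
  set.seed(2)
  x <- draw_spec(dist_spec("normal", mean = 1, sd = 0.8), 2000)
  expect_true(all(x >= 0))
  expect_error(draw_spec(dist_spec("normal", mean = -3, sd = 0.5), 100),
               "rejection rate")
})

test_that("point-mass specs collapse the simulation to the
           deterministic value", {
  det <- cdi_oral(0.713, exposure_profile("adult")) / 0.7
  mc <- simulate_risk(list(Fe = dist_spec("point", value = 0.713)),
                      groups = "adult", routes = "oral",
                      n_iter = 200, seed = 4, factor_cv = 0)
  hq <- mc$draws$adult$Fe$oral$HQ
  expect_equal(unique(hq), det, tolerance = 1e-12)
  sm <- mc$summary
  expect_equal(sm$p5, det, tolerance = 1e-12)
  expect_equal(sm$p95, det, tolerance = 1e-12)
})

test_that("vanishing spread collapses percentiles continuously", {
  det <- cdi_oral(0.5, exposure_profile("child")) / 0.024
  spec <- dist_spec("truncnorm", mean = 0.5, sd = 1e-9,
                    lower = 0.5 - 3e-9, upper = 0.5 + 3e-9)
  mc <- simulate_risk(list(Mn = spec), groups = "child", routes = "oral",
                      n_iter = 1000, seed = 5, factor_cv = 0)
  sm <- mc$summary
  expect_equal(sm$p5, det, tolerance = 1e-6)
  expect_equal(sm$p95, det, tolerance = 1e-6)
})

test_that("the same seed reproduces the simulation bit for bit", {
  specs <- list(Cr = dist_spec("lognormal", meanlog = -4, sdlog = 0.5))
  a <- simulate_risk(specs, n_iter = 500, seed = 11)
  b <- simulate_risk(specs, n_iter = 500, seed = 11)
  expect_identical(a$draws, b$draws)
  expect_identical(a$summary, b$summary)
  c <- simulate_risk(specs, n_iter = 500, seed = 12)
  expect_false(identical(a$draws, c$draws))
  expect_error(simulate_risk(specs, n_iter = 10), "seed")
})

test_that("simulated HQ quantiles and mean match the lognormal
           closed form when only concentration varies", {
  mu <- log(0.2); sg <- 0.5
  mc <- simulate_risk(list(Mn = dist_spec("lognormal", meanlog = mu,
                                          sdlog = sg)),
                      groups = "adult", routes = "oral",
                      n_iter = 1e5, seed = 21, factor_cv = 0)
  k <- cdi_oral(1, exposure_profile("adult")) / 0.024  # HQ per unit conc
  hq <- mc$draws$adult$Mn$oral$HQ
  expect_equal(unname(quantile(hq, 0.95, type = 7)),
               k * qlnorm(0.95, mu, sg), tolerance = 0.01)
  expect_equal(mean(hq), k * exp(mu + sg^2 / 2), tolerance = 0.01)
})

test_that("percentile summaries use the linear-interpolation rule", {
  expect_equal(unname(percentile_summary(1:100, probs = 0.95)), 95.05)
  expect_equal(unname(percentile_summary(rep(3, 10))), rep(3, 3))
  expect_error(percentile_summary(1:10, probs = 1.2), "probs")
  mc <- simulate_risk(list(Pb = dist_spec("point", value = 0.019)),
                      groups = "adult", routes = "oral", n_iter = 50,
                      seed = 3, factor_cv = 0)
  ps <- percentile_summary(mc)
  expect_true(all(ps$p5 <= ps$p50 & ps$p50 <= ps$p95))
})

test_that("concentration calibration moment-matches the observed mean", {
  s <- generate_samples(generator_config(n_samples = 200, seed = 61))
  sp <- calibrate_concentration_spec(s, "Mn")
  expect_s3_class(sp, "dist_spec")
  analytic <- exp(sp$par$meanlog + sp$par$sdlog^2 / 2)
  expect_equal(analytic, mean(s$Mn), tolerance = 1e-12)
  # empirical draw check within 3 standard errors of the mean
  set.seed(62)
  dr <- draw_spec(sp, 1000)
  se <- sd(dr) / sqrt(1000)
  expect_lt(abs(mean(dr) - mean(s$Mn)), 3 * se + 1e-12)
  # constant column -> point spec; bootstrap respects the observed range
  const <- data.frame(sample_id = letters[1:3], Fe = rep(0.2, 3))
  expect_equal(calibrate_concentration_spec(const, "Fe")$family, "point")
  boot <- calibrate_concentration_spec(s, "Fe", family = "empirical")
  bd <- draw_spec(boot, 500)
  expect_true(min(bd) >= min(s$Fe) && max(bd) <= max(s$Fe))
  neg <- data.frame(sample_id = letters[1:4], Cr = c(0, 0.01, 0.02, 0.03))
  expect_warning(calibrate_concentration_spec(neg, "Cr"), "nonpositive")
})

test_that("survey-calibrated simulation flags child oral Mn and Pb", {
  s <- generate_samples(generator_config(n_samples = 45, seed = 7))
  specs <- lapply(stats::setNames(c("Mn", "Pb"), c("Mn", "Pb")),
                  function(m) calibrate_concentration_spec(s, m))
  mc <- simulate_risk(specs, groups = c("adult", "child"),
                      routes = "oral", n_iter = 5000, seed = 9)
  sm <- mc$summary[mc$summary$quantity == "HQ", ]
  expect_true(all(sm$p95[sm$group == "child"] > 1))
  expect_true(all(sm$mean[sm$group == "adult"] < 1))
})
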