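test_that("chloro-alkaline indices follow the standard definition", {
  exact <- cai_indices(data.frame(Cl = 10, Na = 6, K = 4, SO4 = 1,
                                  HCO3 = 1, NO3 = 0))
  expect_equal(exact$CAI_I, 0)
  expect_equal(exact$CAI_II, 0)
  pos <- cai_indices(data.frame(Cl = 10, Na = 4, K = 0, SO4 = 3,
                                HCO3 = 2, NO3 = 1))
  expect_equal(pos$CAI_I, 0.6)
  expect_equal(pos$CAI_II, 1)
  undef <- cai_indices(data.frame(Cl = 0, Na = 1, K = 0, SO4 = 0,
                                  HCO3 = 0, NO3 = 0))
  expect_true(is.na(undef$CAI_I) && is.na(undef$CAI_II))
})

test_that("reverse-exchange waters give positive CAI of agreeing sign", {
  # Cl far above Na+K: reverse exchange; and the converse
  tab <- random_ion_table(30, seed = 21)
  tab$Cl <- tab$Na + tab$K + runif(30, 1, 5)    # chloride excess
  r <- cai_indices(tab)
  expect_true(all(r$CAI_I > 0) && all(r$CAI_II > 0))
  tab$Cl <- pmax(tab$Na + tab$K - runif(30, 0.5, 1), 0.1)
  r2 <- cai_indices(tab)
  expect_true(all(sign(r2$CAI_I) == sign(r2$CAI_II)))
})

test_that("Piper triangle percentages sum to 100", {
  p <- piper_percentages(random_ion_table(40, seed = 31))
  expect_equal(p$pct_Ca + p$pct_Mg + p$pct_NaK, rep(100, 40),
               tolerance = 1e-9)
  expect_equal(p$pct_Cl + p$pct_SO4 + p$pct_HCO3CO3, rep(100, 40),
               tolerance = 1e-9)
})

test_that("Piper facies rules recover the canonical end-members", {
  expect_equal(piper_facies(data.frame(Ca = 0, Mg = 0, Na = 10, K = 0,
                                       Cl = 10, SO4 = 0, HCO3 = 0,
                                       NO3 = 0)), "Na-Cl")
  expect_equal(piper_facies(data.frame(Ca = 6, Mg = 3, Na = 1, K = 0,
                                       Cl = 2, SO4 = 7, HCO3 = 1,
                                       NO3 = 0)), "Ca-Mg-SO4")
  thirds <- data.frame(Ca = 1, Mg = 1, Na = 1, K = 0, Cl = 1, SO4 = 1,
                       HCO3 = 1, NO3 = 0)
  expect_equal(piper_facies(thirds), "mixed Ca-Mg-Cl/SO4")
  fresh <- data.frame(Ca = 3, Mg = 1, Na = 1, K = 0, Cl = 1, SO4 = 1,
                      HCO3 = 8, NO3 = 0)
  expect_equal(piper_facies(fresh), "other")
})

test_that("Gibbs ratios and zones behave on constructed waters", {
  even <- data.frame(TDS = 200, Na = 50, Ca = 50, Cl = 60, HCO3 = 60)
  g <- gibbs_ratios(even)
  expect_equal(g$cation_ratio, 0.5)
  expect_equal(g$anion_ratio, 0.5)
  means <- worked_fixture()[1, ]
  gm <- gibbs_ratios(means)
  expect_equal(gm$cation_ratio, 364 / (364 + 259), tolerance = 1e-12)
  expect_true(gm$cation_ratio > 0.5 && gm$anion_ratio > 0.5)
  expect_equal(gm$gibbs_zone_cation, "evaporation")
  expect_error(gibbs_ratios(data.frame(TDS = 1, Na = 0, Ca = 0,
                                       Cl = 1, HCO3 = 1)), "denominator")
})

test_that("Sulin quadrants separate meteoric from marine waters", {
  met <- data.frame(Na = 12, K = 1, Cl = 8, Mg = 3, SO4 = 2)
  expect_equal(sulin_classification(met), "deep meteoric")
  met2 <- data.frame(Na = 9, K = 0, Cl = 8, Mg = 3, SO4 = 5)
  expect_equal(sulin_classification(met2), "shallow meteoric")
  marine <- data.frame(Na = 10, K = 0, Cl = 12, Mg = 5, SO4 = 2)
  expect_equal(sulin_classification(marine), "recent marine")
  old <- data.frame(Na = 10, K = 0, Cl = 18, Mg = 5, SO4 = 2)
  expect_equal(sulin_classification(old), "old marine")
  # boundary Cl = Na + K breaks to the meteoric branch
  tie <- data.frame(Na = 10, K = 0, Cl = 10, Mg = 5, SO4 = 2)
  expect_match(sulin_classification(tie), "meteoric")
})

test_that("saturation index is zero at equilibrium and matches the
           frozen hand computation for halite in dilute NaCl", {
  # IAP tuned to K: back-compute the Ca and CO3 activities for calcite
  # via a pure Na/Cl matrix kept at zero so gamma terms are controlled
  si <- saturation_index(
    data.frame(Na = 1, Cl = 1), pH = 7, minerals = "halite"
  )
  # 1 meq/L Na and Cl = 1 mmol/L NaCl; frozen independent arithmetic:
  # I = 1e-3, gamma = 10^(-0.5092*(sqrt(I)/(1+sqrt(I)) - 0.3 I)) = 0.96505,
  # SI = log10((1e-3*gamma)^2) - 1.570 = -7.600912
  expect_equal(si$halite, -7.600912, tolerance = 1e-6)
})

test_that("SI is monotone in recipe-ion concentration", {
  base <- worked_fixture()[1, ]
  ions <- to_meq(base)
  grid <- seq(0.5, 2, length.out = 6)
  si_cal <- vapply(grid, function(f) {
    x <- ions; x$Ca <- ions$Ca * f
    saturation_index(x, pH = base$pH, minerals = "calcite")$calcite
  }, numeric(1))
  expect_true(all(diff(si_cal) > 0))
})

test_that("mean survey chemistry is supersaturated with carbonates and
           undersaturated with evaporites", {
  means <- worked_fixture()[1, ]
  si <- saturation_index(to_meq(means), pH = means$pH)
  expect_gt(si$calcite, 0)
  expect_gt(si$dolomite, 0)
  expect_lt(si$gypsum, 0)
  expect_lt(si$halite, 0)
})

test_that("zero recipe-ion activity reports the undersaturated sentinel", {
  si <- saturation_index(data.frame(Na = 0, Cl = 5), pH = 7,
                         minerals = "halite")
  expect_equal(si$halite, -Inf)
})
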