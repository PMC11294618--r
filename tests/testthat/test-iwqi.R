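test_that("min-max normalisation maps columns to [0, 1]", {
  expect_equal(as.numeric(normalize_matrix(cbind(c(1, 2, 3)))),
               c(0, 0.5, 1))
  expect_warning(y <- normalize_matrix(cbind(a = c(5, 5, 5))), "constant")
  expect_equal(as.numeric(y), rep(0.5, 3))
  X <- weight_fixture()
  Y <- normalize_matrix(X)
  expect_equal(unname(apply(Y, 2, min)), rep(0, 3))
  expect_equal(unname(apply(Y, 2, max)), rep(1, 3))
})

test_that("entropy weights match the literal spreadsheet oracle", {
  # oracle (transcribed arithmetic, independent of the implementation):
  # P_ij = (Y_ij + 1e-4)/colsum, e_j = -sum(P ln P)/ln m,
  # w_j = (1-e_j)/sum(1-e_j)
  Y <- matrix(c(0, 0.5, 1, 0, 1, 1), 3, 2)
  oracle <- local({
    Ye <- Y + 1e-4
    e <- apply(Ye, 2, function(col) {
      P <- col / sum(col)
      -sum(P * log(P)) / log(nrow(Y))
    })
    (1 - e) / sum(1 - e)
  })
  expect_equal(unname(oracle), c(0.5325858, 0.4674142), tolerance = 1e-6)
  expect_equal(unname(entropy_weights(Y)), unname(oracle),
               tolerance = 1e-12)
  # and on the 5 x 3 fixture (frozen oracle values)
  w <- entropy_weights(normalize_matrix(weight_fixture()))
  expect_equal(unname(w), c(0.2340346, 0.5319308, 0.2340346),
               tolerance = 1e-6)
})

test_that("entropy weighting prefers concentrated columns and treats
           identical columns symmetrically", {
  Y <- cbind(a = c(0, 0.5, 1), b = c(0, 0.5, 1))
  expect_equal(unname(entropy_weights(Y)), c(0.5, 0.5))
  conc <- cbind(peaked = c(1, 0, 0, 0, 0), flat = c(1, 0.9, 1, 0.95, 1))
  w <- entropy_weights(conc)
  expect_gt(w[["peaked"]], w[["flat"]])
  expect_error(entropy_weights(matrix(0.5, 4, 2)), "degenerate")
})

test_that("CRITIC weights match the spreadsheet oracle and its
           qualitative structure", {
  X <- weight_fixture()
  # frozen oracle: sd on min-max normalised columns, Pearson r on X,
  # S_j = sd_j * sum_k(1 - r_jk), w = S/sum(S)
  w <- critic_weights(X)
  expect_equal(unname(w), c(0.2568509, 0.2621716, 0.4809775),
               tolerance = 1e-6)
  # equal-contrast uncorrelated columns share the weight equally
  eq <- cbind(a = c(0, 1, 0, 1), b = c(0, 0, 1, 1))
  expect_equal(unname(critic_weights(eq)), c(0.5, 0.5))
  # a column independent of two perfectly correlated ones wins
  base <- c(1, 2, 3, 4, 5)
  trip <- cbind(a = base, b = 2 * base + 1, c = c(2, 5, 1, 4, 3))
  w3 <- critic_weights(trip)
  expect_true(which.max(w3) == 3)
  expect_warning(critic_weights(cbind(a = base, b = rep(1, 5))),
                 "zero-variance")
})

test_that("weight vectors sum to one and are permutation invariant", {
  s <- generate_samples(generator_config(n_samples = 20, seed = 9))
  X <- as.matrix(s[, standards_table()$parameter])
  w1 <- entropy_weights(normalize_matrix(X))
  w2 <- critic_weights(X)
  W <- integrated_weights(w1, w2)
  for (w in list(w1, w2, W)) expect_equal(sum(w), 1, tolerance = 1e-9)
  perm <- sample(nrow(X))
  expect_equal(entropy_weights(normalize_matrix(X[perm, ])), w1,
               tolerance = 1e-12)
  expect_equal(critic_weights(X[perm, ]), w2, tolerance = 1e-12)
})

test_that("integrated weights combine as the normalised product", {
  # identical inputs renormalise the squared weights (the product form
  # is idempotent only for the uniform vector)
  w <- c(a = 0.3, b = 0.7)
  expect_equal(integrated_weights(w, w), w^2 / sum(w^2))
  u <- c(a = 0.5, b = 0.5)
  expect_equal(integrated_weights(u, u), u)
  expect_equal(
    unname(integrated_weights(c(a = 0.8, b = 0.2), c(a = 0.2, b = 0.8))),
    c(0.5, 0.5)
  )
  expect_error(integrated_weights(c(a = 1, b = 0), c(a = 0, b = 1)),
               "degenerate")
  lin <- integrated_weights(c(a = 0.8, b = 0.2), c(a = 0.2, b = 0.8),
                            method = "linear", p = 0.25)
  expect_equal(unname(lin), c(0.35, 0.65))
  expect_equal(preference_coefficient(c(0.5, 0.5), c(0.8, 0.2),
                                      c(0.2, 0.8)),
               2 * (0.09 * 0.09))
})

test_that("quality ratings follow Q = 100 (C - Cjp)/(S - Cjp)", {
  std <- standards_table()
  at_standard <- worked_fixture()[5, ]
  expect_equal(unname(quality_rating(at_standard, std)),
               rep(100, nrow(std)))
  expect_equal(quality_rating(worked_fixture()[1, ], std)[["Mn"]], 265)
  neutral <- at_standard
  neutral$pH <- 7
  expect_equal(quality_rating(neutral, std)[["pH"]], 0)
  bad <- std
  bad$Sj[1] <- bad$Cjp[1]
  expect_error(quality_rating(at_standard, bad), "misconfigured")
})

test_that("IWQI is the weighted rating sum with left-closed classes", {
  std <- standards_table()
  W <- stats::setNames(std$Wj, std$parameter)
  expect_equal(sum(W), 1, tolerance = 1e-9)
  Q <- stats::setNames(rep(100, nrow(std)), std$parameter)
  r <- iwqi_score(Q, W)
  expect_equal(r$iwqi, 100)
  expect_equal(r$class, "medium")   # boundary convention: 100 is medium
  expect_equal(iwqi_class(c(0, 49.9, 50, 149, 199, 200, 999)),
               c("excellent", "excellent", "good", "medium", "poor",
                 "extremely poor", "extremely poor"))
  expect_error(iwqi_score(Q[-1], W), "different parameters")
})

test_that("published integrated weights rank parameters as reported", {
  std <- standards_table()
  ord <- std$parameter[order(std$Wj, decreasing = TRUE)]
  expect_equal(ord, c("Mn", "NO3", "Fe", "K", "HCO3", "Cl", "Na", "SO4",
                      "Ca", "Mg", "pH", "TDS", "EC", "TH"))
})

test_that("IWQI is monotone in concentrations with zero ideal value", {
  s <- generate_samples(generator_config(n_samples = 10, seed = 33))
  base <- iwqi(s, weights = "published")
  worse <- s
  up <- setdiff(standards_table()$parameter, "pH")
  worse[, up] <- worse[, up] * 1.2
  expect_true(all(iwqi(worse, weights = "published")$iwqi > base$iwqi))
})

test_that("synthetic survey-structured data span several quality
           classes under the published weights", {
  s <- generate_samples(generator_config(n_samples = 45, seed = 7))
  r <- iwqi(s, weights = "published")
  expect_gte(length(unique(r$class)), 3)
  expect_gt(max(r$iwqi), 200)
})
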