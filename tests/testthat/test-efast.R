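test_that("eFAST isolates the only active factor", {
  fn <- function(X) X[, 1]
  res <- efast_indices(fn, n_factors = 2, samples = 129, seed = 1)
  expect_equal(res$total[1, 1], 1, tolerance = 0.05)
  expect_lt(res$total[2, 1], 0.05)
  expect_equal(res$first[1, 1], 1, tolerance = 0.05)
})

test_that("eFAST matches analytic variance fractions of an additive model", {
  a <- 3; b <- 1
  fn <- function(X) a * X[, 1] + b * X[, 2]
  res <- efast_indices(fn, n_factors = 2, samples = 257, seed = 2)
  frac <- c(a^2, b^2) / (a^2 + b^2)
  expect_equal(unname(res$first[, 1]), frac, tolerance = 0.05)
  expect_equal(sum(res$first[, 1]), 1, tolerance = 0.05)
  # total-order >= first-order (within estimator noise)
  expect_true(all(res$total[, 1] >= res$first[, 1] - 0.05))
})

test_that("eFAST rejects sample sizes below the interference minimum", {
  expect_error(efast_indices(function(X) X[, 1], 2, samples = 33, M = 4),
               "at least 4\\*M\\^2\\+1")
})

test_that("model-level eFAST selects influential Vmax parameters", {
  fx <- make_fixture_network()
  st <- simulate_study(fx, cv = 0, seed = 4)
  obs <- training_observables(fx, st$dataset)
  sens <- efast_sensitivity(fx, fx$params, obs,
                            parameters = c("Vf_glut", "Vf_gk", "Vf_pfk"),
                            samples = 65, threshold = 0.85, seed = 5)
  expect_true(all(dim(sens$indices) == c(3, nrow(st$dataset))))
  # glucose transport dominates glucose-driven fold-changes
  expect_true("Vf_glut" %in% sens$selection)
})
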