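fx <- make_fixture_network()

test_that("the reduced fixture has the structural features the pipeline needs", {
  rel <- conserved_moieties(fx)
  expect_gte(length(rel), 1)                       # a conserved cofactor pair
  expect_true(any(vapply(rel, function(r)
    setequal(r$members, c("NAD_m", "NADH_m")), TRUE)))
  expect_identical(nrow(fx$compartments), 3L)      # two cellular + medium
  tpl <- vapply(fx$reactions, `[[`, "", "template")
  expect_true("facilitated_transport" %in% tpl)    # transport
  expect_true(any(grepl("reversible|bi_bi", tpl))) # reversibility
  t0 <- Sys.time()
  ss <- steady_state(fx, glucose = 16.7, horizon = 1440)
  expect_true(ss$converged)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 10)
})

test_that("ground-truth sampling is seeded, bounded and log-normal", {
  expect_identical(generate_ground_truth(fx, sigma = 0, seed = 1)$values,
                   fx$params$values)
  g1 <- generate_ground_truth(fx, sigma = 0.3, seed = 9)
  g2 <- generate_ground_truth(fx, sigma = 0.3, seed = 9)
  expect_identical(g1$values, g2$values)
  expect_identical(g1$provenance, "sampled")

  vm <- vmax_names(fx, free_only = FALSE)
  draws <- unlist(lapply(1:70, function(s)
    log(generate_ground_truth(fx, sigma = 0.3, seed = s)$values[vm] /
          fx$params$values[vm])))
  expect_lt(abs(sd(draws) - 0.3) / 0.3, 0.1)
  expect_true(all(g1$values[vm] >= fx$params$lower[vm] - 1e-12))
  expect_true(all(g1$values[vm] <= fx$params$upper[vm] + 1e-12))
})

test_that("noiseless synthetic studies reproduce the simulation exactly", {
  st <- simulate_study(fx, cv = 0, seed = 4)
  expect_identical(st$dataset$fold_change, unname(st$noiseless))
  expect_true(all(st$dataset$sd == 0))
  expect_equal(st$insulin$fold_change, st$insulin$noiseless)
})

test_that("noise magnitude matches the configured CV", {
  st <- simulate_study(fx, cv = 0.15, replicates = 200, seed = 6)
  rel_sd <- st$dataset$sd / st$noiseless
  expect_equal(median(rel_sd), 0.15, tolerance = 0.2)
})

test_that("studies are a pure function of (config, seed)", {
  s1 <- simulate_study(fx, cv = 0.2, seed = 11)
  s2 <- simulate_study(fx, cv = 0.2, seed = 11)
  expect_identical(s1$dataset, s2$dataset)
  expect_identical(s1$insulin, s2$insulin)
  s3 <- simulate_study(fx, cv = 0.2, seed = 12)
  expect_false(identical(s1$dataset$fold_change, s3$dataset$fold_change))
})

test_that("the recorded insulin ground truth reproduces the response", {
  st <- simulate_study(fx, cv = 0, seed = 2)
  it <- st$insulin_truth
  rebuilt <- it$intercept +
    as.numeric(st$flux_table[, it$drivers] %*% it$coefficients)
  expect_equal(st$insulin$fold_change, rebuilt, tolerance = 1e-10)
})

test_that("VIP recovery finds the designated drivers", {
  r <- vip_recovery(fx, seed = 3)
  expect_identical(sort(names(r$vip)), sort(names(fx$reactions)))
  expect_true(all(r$top3 %in% names(fx$reactions)))
  expect_true(r$ok)
})
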