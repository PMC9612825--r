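fx <- make_fixture_network()
cfg <- gsis_config()
bl <- perturbation_baseline(fx, fx$params, cfg, horizon = 1440)

test_that("the identity perturbation reproduces the baseline exactly", {
  res <- apply_intervention(fx, fx$params,
                            list(reaction = "gk", factor = 1, label = "id"),
                            cfg, baseline = bl, horizon = 1440)
  expect_identical(unname(res$species_fc), rep(1, length(res$species_fc)))
  expect_true(all(res$flux_fc[!is.na(res$flux_fc)] == 1))
  expect_length(res$reversals, 0)
})

test_that("doubling a non-limiting downstream step leaves uptake flux alone", {
  # transport-limited chain: boundary -> A (slow carrier) -> B (fast sink)
  def <- toy_definition(
    compartments = list(
      list(id = "e", name = "out", relative_volume = 10, exchange = TRUE),
      list(id = "c", name = "in", relative_volume = 1, exchange = FALSE)),
    species = list(toy_species("S_e", comp = "e", initial = 10, boundary = TRUE),
                   toy_species("A", initial = 0.01),
                   toy_species("B", initial = 0.01, boundary = TRUE)),
    reactions = list(
      list(id = "tin", template = "facilitated_transport", pathway = "other",
           substrates = list(S_e = 1), products = list(A = 1),
           params = list(vf = "Vt", km_sub = list("Kt"))),
      list(id = "sink", template = "irreversible_mm_1s", pathway = "other",
           substrates = list(A = 1), products = list(B = 1),
           params = list(vf = "Vs", km_sub = list("Ks"), km_prod = list(NULL)))),
    parameters = list(toy_param("Vt", 0.5, "Vmax"), toy_param("Kt", 5, "Km"),
                      toy_param("Vs", 50, "Vmax"), toy_param("Ks", 0.05, "Km")))
  m <- build_network(def)
  s1 <- steady_state(m, glucose = NA, horizon = 500)
  p2 <- update_params(m$params, c(Vs = 100))
  s2 <- steady_state(m, p2, glucose = NA, horizon = 500)
  expect_equal(s2$fluxes[["tin"]], s1$fluxes[["tin"]], tolerance = 1e-3)
})

test_that("the scan covers both directions for every reaction and species", {
  sc <- scan_vmax(fx, fx$params, factor = 2, reactions = c("gk", "ldh"),
                  config = cfg, baseline = bl, horizon = 1440)
  expect_length(sc$results, 4)     # 2 reactions x 2 directions
  expect_length(sc$failed, 0)
  r <- sc$results[[1]]
  expect_length(r$species_fc, sum(!fx$species$boundary))
  expect_true(all(c("metabolite", "flux") %in% sc$tidy$type))
  expect_true(is.character(r$no_change))
})

test_that("conserved totals are untouched by Vmax perturbations", {
  rel <- conserved_moieties(fx)
  res <- apply_intervention(fx, fx$params,
                            list(reaction = "pdh", factor = 2, label = "x"),
                            cfg, baseline = bl, horizon = 1440)
  # NAD + NADH total identical before and after (amount-weighted)
  nad_rel <- rel[[which(vapply(rel, function(r) "NAD_m" %in% r$members, TRUE))]]
  tot <- function(state) sum(state[nad_rel$members] * nad_rel$coefficients)
  pert_state <- res$species_fc * bl$state
  expect_equal(tot(pert_state), tot(bl$state), tolerance = 1e-6)
})

test_that("insulin effects follow the linear model's coefficients", {
  set.seed(2)
  X <- matrix(runif(6 * 4, 0.5, 1.5), 6, 4,
              dimnames = list(NULL, c("gk", "ldh", "pdh", "mct")))
  y <- 1 + 0.8 * X[, "pdh"] - 0.5 * X[, "ldh"]
  ens <- list(simpls_fit(X, y, 2))
  base_fl <- X[1, ]
  expect_equal(insulin_effect(base_fl, ens, base_fl), 1)
  up <- base_fl; up["pdh"] <- up["pdh"] * 1.5
  expect_gt(insulin_effect(up, ens, base_fl), 1)
  # dot-product oracle
  f <- ens[[1]]
  oracle <- (sum(up * f$coef_raw) + f$intercept) /
    (sum(base_fl * f$coef_raw) + f$intercept)
  expect_equal(insulin_effect(up, ens, base_fl), oracle, tolerance = 1e-12)
})

test_that("unknown scenarios list the registry", {
  expect_error(apply_intervention(fx, fx$params, "statin", cfg, baseline = bl),
               "metformin, agrimony, ak_knockdown")
})
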