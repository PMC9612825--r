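fx <- make_fixture_network()

test_that("rate-law identities hold", {
  # half saturation: irreversible MM at [S] = Km gives Vmax/2
  vf <- fx$params$values[["Vf_pfk"]]
  km <- fx$params$values[["Km_pfk_G6P_c"]]
  expect_equal(reaction_rate(fx, "pfk", c(G6P_c = km)), vf / 2)
  # saturation limit
  expect_equal(reaction_rate(fx, "pfk", c(G6P_c = 1e9)), vf, tolerance = 1e-6)
  # Haldane equilibrium: net rate 0 at [P]/[S] = Keq (equal Kms)
  m <- build_network(rev_ab_definition(vf = 2, vr = 1, kma = 0.4, kmb = 0.4))
  keq <- 2
  expect_equal(reaction_rate(m, "rab", c(A = 0.3, B = 0.3 * keq)), 0)
  # state errors
  expect_error(reaction_rate(fx, "pfk", c(G6P_c = -1)),
               "negative concentration")
})

test_that("rhs is the volume-scaled stoichiometric image of the rates", {
  p0 <- fx$params
  p0$values[grep("^V[fr]_", names(p0$values))] <- 0
  p0$lower[] <- -Inf
  expect_true(all(rhs(fx, params = p0) == 0))

  # mass-action chain matches the analytic exponential
  m <- build_network(chain_definition(k = 0.3, a0 = 2, b0 = 0))
  prot <- stimulation_protocol(data.frame(duration = 10),
                               output_grid = seq(0, 10, 0.5))
  tr <- simulate(m, protocol = prot)
  expect_equal(tr$conc[, "A"], 2 * exp(-0.3 * tr$times), tolerance = 1e-6)
  expect_equal(tr$conc[, "B"], 2 - 2 * exp(-0.3 * tr$times), tolerance = 1e-6)
})

test_that("conserved totals stay constant along trajectories", {
  rel <- conserved_moieties(fx)
  prot <- stimulation_protocol(data.frame(duration = c(30, 60),
                                          GLC_e = c(2.8, 16.7)))
  tr <- simulate(fx, protocol = prot)
  tot <- conservation_totals(fx, tr, rel)
  drift <- apply(tot, 2, function(x) diff(range(x)) / max(abs(x)))
  expect_true(all(drift < 1e-6))
  expect_true(all(tr$conc > -1e-9))
})

test_that("simulate honors initial state and is tolerance-robust", {
  prot <- stimulation_protocol(data.frame(duration = 5, GLC_e = 16.7))
  tr <- simulate(fx, protocol = prot)
  init <- setNames(fx$species$initial[!fx$species$boundary],
                   fx$species$id[!fx$species$boundary])
  expect_equal(tr$conc[1, names(init)], init)

  tr2 <- simulate(fx, protocol = prot, rtol = 1e-10, atol = 1e-12)
  n <- length(tr$times)
  expect_lt(max(abs(tr2$conc[n, ] - tr$conc[n, ]) / pmax(tr$conc[n, ], 1e-9)),
            1e-3)
})

test_that("steady states are certified and initial-condition independent", {
  # linear reversible toy relaxes to the Keq ratio
  m <- build_network(rev_ab_definition(vf = 2, vr = 1, kma = 0.4, kmb = 0.4,
                                       a0 = 1.5, b0 = 0.1))
  ss <- steady_state(m, glucose = NA, horizon = 600)
  expect_true(ss$converged)
  expect_equal(ss$state[["B"]] / ss$state[["A"]], 2, tolerance = 1e-5)

  ss1 <- steady_state(fx, glucose = 16.7, horizon = 1440)
  expect_true(ss1$converged)
  expect_lt(ss1$sv_inf, 1e-6)
  # a different start that preserves every conserved pool total
  init2 <- setNames(fx$species$initial[!fx$species$boundary],
                    fx$species$id[!fx$species$boundary])
  init2[c("GLC_c", "G6P_c", "FBP_c", "TRI_c", "PYR_c", "LAC_c")] <-
    3 * init2[c("GLC_c", "G6P_c", "FBP_c", "TRI_c", "PYR_c", "LAC_c")]
  init2[c("NAD_m", "NADH_m")] <- sum(init2[c("NAD_m", "NADH_m")]) / 2
  init2[c("CIT_m", "OAA_m")] <- sum(init2[c("CIT_m", "OAA_m")]) / 2
  ss2 <- steady_state(fx, init = init2, glucose = 16.7, horizon = 2880)
  expect_lt(max(abs(ss2$state - ss1$state) / pmax(ss1$state, 1e-9)), 0.005)
})

test_that("fold-change operations match elementwise oracles", {
  prot <- stimulation_protocol(data.frame(duration = c(20, 20),
                                          GLC_e = c(2.8, 16.7)))
  tr <- simulate(fx, protocol = prot)
  fc <- fold_change(tr, tr, time = 30)
  expect_true(all(fc$fold_change == 1))

  set.seed(9)
  cn <- colnames(tr$conc)
  c1 <- matrix(runif(3 * length(cn), 0.1, 2), 3, dimnames = list(NULL, cn))
  t1 <- fake_traj(0:2, c1); t2 <- fake_traj(0:2, 2 * c1)
  fc2 <- fold_change(t2, t1, time = 1)
  expect_equal(fc2$fold_change, rep(2, length(cn)))
  fc3 <- fold_change(t2, t1, time = 2, comparison = "vs_t0")
  expect_equal(fc3$fold_change, unname(2 * c1[3, ] / (2 * c1[1, ])))

  # undefined flag for vanishing reference
  c1[2, 1] <- 0
  fcu <- fold_change(t2, fake_traj(0:2, c1), time = 1)
  expect_true(fcu$undefined[1])
  expect_true(is.na(fcu$fold_change[1]))
})

test_that("compartment pooling uses 3:1 amount weighting", {
  cn <- colnames(simulate(fx, protocol = stimulation_protocol(
    data.frame(duration = 1)))$conc)
  base <- matrix(1, 2, length(cn), dimnames = list(NULL, cn))
  num <- base; den <- base
  # PYR is present in cytosol (x3) and mitochondria (x1)
  num[2, "PYR_c"] <- 4; num[2, "PYR_m"] <- 1
  den[2, "PYR_c"] <- 2; den[2, "PYR_m"] <- 1
  pf <- pooled_fold_change(fx, fake_traj(0:1, num), fake_traj(0:1, den), 1)
  expect_equal(pf$fold_change[pf$metabolite == "PYR"], 13 / 7)
  # doubling both compartments doubles the pool
  pf2 <- pooled_fold_change(fx, fake_traj(0:1, 2 * base), fake_traj(0:1, base), 1)
  expect_true(all(pf2$fold_change == 2))
  # cytosol-only metabolite passes through
  num2 <- base; num2[2, "GLC_c"] <- 3.5
  pf3 <- pooled_fold_change(fx, fake_traj(0:1, num2), fake_traj(0:1, base), 1)
  expect_equal(pf3$fold_change[pf3$metabolite == "GLC"], 3.5)
})

test_that("time-averaged fluxes are trapezoidal means", {
  tt <- 0:10
  fl <- cbind(const = rep(2, 11), ramp = tt)
  tr <- fake_traj(tt, matrix(1, 11, 1, dimnames = list(NULL, "A")), fl)
  av <- time_averaged_fluxes(tr, c(0, 10))
  expect_equal(unname(av["const"]), 2)
  expect_equal(unname(av["ramp"]), 5)
  # arbitrary smooth series vs fine-grid Riemann oracle
  f <- function(x) 1 + sin(x / 3) + 0.1 * x
  tr2 <- fake_traj(tt, matrix(1, 11, 1, dimnames = list(NULL, "A")),
                   cbind(s = f(tt)))
  xf <- seq(0, 10, by = 0.001)
  oracle <- mean(f(xf))
  expect_equal(unname(time_averaged_fluxes(tr2, c(0, 10))["s"]), oracle,
               tolerance = 5e-3)
  expect_error(time_averaged_fluxes(tr2, c(3, 3.1)), "fewer than two")
})

test_that("flux normalization maps the reference to 100", {
  fl <- c(glut = 0.2, gk = 0.1, rev = -0.05)
  nf <- normalize_fluxes_to_glut(fl)
  expect_equal(unname(nf), c(100, 50, -25))
  expect_error(normalize_fluxes_to_glut(c(glut = 0, gk = 1)), "zero")
  expect_error(normalize_fluxes_to_glut(c(gk = 1)), "no flux named")
})

test_that("LHS initial conditions are stratified and reproducible", {
  rg <- data.frame(species = c("A", "B"), low = c(0.1, 1), high = c(1.1, 3))
  x <- lhs_initial_conditions(rg, n = 50, seed = 3)
  expect_identical(dim(x), c(50L, 2L))
  expect_true(all(x[, "A"] >= 0.1 & x[, "A"] <= 1.1))
  # exactly one sample per stratum
  for (j in 1:2) {
    strata <- floor((x[, j] - rg$low[j]) / (rg$high[j] - rg$low[j]) * 50)
    expect_setequal(strata, 0:49)
  }
  expect_identical(x, lhs_initial_conditions(rg, n = 50, seed = 3))
  expect_error(lhs_initial_conditions(
    data.frame(species = "A", low = 2, high = 1), 5), "low < high")
})
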