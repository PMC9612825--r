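test_that("minimal networks assemble the expected stoichiometric columns", {
  def <- chain_definition()
  m <- build_network(def)
  expect_identical(dim(m$S), c(2L, 1L))
  expect_equal(unname(m$S[, "r1"]), c(-1, 1))

  bibi <- toy_definition(
    reactions = list(list(
      id = "r", template = "mass_action", pathway = "other",
      substrates = list(A = 1, B = 1), products = list(C = 1, D = 1),
      params = list(vf = "k"))),
    species = lapply(c("A", "B", "C", "D"), toy_species),
    parameters = list(toy_param("k", 1, "Vmax")))
  m2 <- build_network(bibi)
  expect_equal(unname(m2$S[c("A", "B", "C", "D"), "r"]), c(-1, -1, 1, 1))
})

test_that("definition errors name the offending identifier", {
  def <- chain_definition()
  def$species <- c(def$species, list(toy_species("A")))
  expect_error(build_network(def), "duplicate species id: A")

  def2 <- chain_definition()
  def2$reactions[[1]]$substrates <- list(ZZZ = 1)
  expect_error(build_network(def2), "unresolved species reference 'ZZZ'")

  def3 <- chain_definition()
  def3$reactions[[1]]$substrates <- list()
  def3$reactions[[1]]$products <- list()
  expect_error(build_network(def3), "empty reaction")

  def4 <- chain_definition()
  def4$reactions[[1]]$params$vf <- "nope"
  expect_error(build_network(def4), "unresolved parameter reference 'nope'")

  def5 <- chain_definition()
  def5$reactions <- c(def5$reactions, def5$reactions)
  expect_error(build_network(def5), "duplicate reaction id")
})

test_that("model definitions round-trip through read/write", {
  def <- rev_ab_definition()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_definition(def, path)
  def2 <- read_model_definition(path)
  m1 <- build_network(def)
  m2 <- build_network(def2)
  expect_identical(m1$S, m2$S)
  expect_identical(m1$params$values, m2$params$values)
  expect_identical(names(m1$reactions), names(m2$reactions))
})

test_that("the full beta-cell network has the published structure", {
  m <- betacell_model()
  expect_identical(nrow(m$S), 56L)
  expect_identical(ncol(m$S), 65L)
  pw <- pathway_counts(m)
  expect_equal(pw$species[pw$pathway == "glycolysis"], 12)
  expect_equal(pw$reactions[pw$pathway == "glycolysis"], 13)
  expect_equal(sum(pw$reactions), 65)  # pathway tags partition the reactions
})

test_that("conserved moieties are exact and match an SVD oracle", {
  # closed two-species cycle: one relation A + B
  m <- build_network(rev_ab_definition())
  rel <- conserved_moieties(m)
  expect_length(rel, 1)
  expect_equal(sort(rel[[1]]$members), c("A", "B"))
  expect_equal(unname(rel[[1]]$coefficients), c(1, 1))

  # exactness on the full model: c^T S = 0 in integer arithmetic
  full <- betacell_model()
  relf <- conserved_moieties(full)
  for (r in relf) {
    w <- setNames(rep(0, nrow(full$S)), rownames(full$S))
    w[r$members] <- r$coefficients
    expect_identical(max(abs(t(w) %*% full$S)), 0)
  }
  # dimension + span vs SVD oracle on the full model
  expect_identical(length(relf), nrow(full$S) - qr(full$S)$rank)
  B <- vapply(relf, function(r) {
    w <- setNames(rep(0, nrow(full$S)), rownames(full$S))
    w[r$members] <- r$coefficients
    w
  }, numeric(nrow(full$S)))
  expect_true(same_span(B, svd_left_null(full$S), tol = 1e-9))
})

test_that("rational null space matches the SVD oracle on random matrices", {
  set.seed(42)
  for (i in 1:20) {
    # wide matrices usually have a trivial left null space, tall ones do not
    dims <- if (i %% 2) c(6, 8) else c(8, 5)
    S <- matrix(sample(-2:2, prod(dims), replace = TRUE), dims[1], dims[2])
    B <- betaGSIS:::rational_nullspace(t(S))
    if (ncol(B) > 0)
      expect_identical(max(abs(t(B) %*% S)), 0)  # exact left-null
    expect_true(same_span(B, svd_left_null(S), tol = 1e-9))
  }
})

test_that("mass balance reports sources/sinks and degenerate species", {
  full <- betacell_model()
  mb <- validate_mass_balance(full)
  expect_setequal(mb$sources_sinks, c("glut", "mct", "asct2", "ox", "fruT"))
  expect_true(mb$balanced)

  closed <- validate_mass_balance(build_network(rev_ab_definition()))
  expect_length(closed$sources_sinks, 0)

  # species with no consuming path is flagged
  orphanish <- chain_definition()  # irreversible A -> B: B never consumed
  mb2 <- validate_mass_balance(build_network(orphanish))
  expect_true("B" %in% mb2$flagged$species)
  expect_false(mb2$balanced)
})

test_that("parameter inventory reports the published counts", {
  m <- betacell_model()
  inv <- parameter_inventory(m)
  expect_identical(inv$total, 385L)
  expect_identical(inv$vmax, 96L)
  expect_identical(inv$free_vmax, 96L)  # before constraints
})

test_that("SBML export is well-formed and complete", {
  m <- make_fixture_network()
  path <- withr::local_tempfile(fileext = ".xml")
  export_sbml(m, path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  expect_length(xml2::xml_find_all(doc, "//d1:species", ns), nrow(m$species))
  expect_length(xml2::xml_find_all(doc, "//d1:reaction", ns),
                length(m$reactions))
  expect_gt(length(xml2::xml_find_all(doc, "//d1:kineticLaw", ns)), 0)
})
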