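# ---- declarative definition builder -----------------------------------------
# Collects compartments, species, reactions and auto-named parameters into a
# definition list (the same structure read_model_definition() returns).
# Parameter naming: Vf_<rx>, Vr_<rx>, Keq_<rx>, Km_<rx>_<species>,
# Ki_<rx>_<species> (product inhibition), Kia/Kib/Kiq_<rx>, n_<rx> (Hill),
# Ka_<rx>_<mod>, Kni_<rx>_<mod>.

definition_builder <- function(name = "model") {
  env <- new.env(parent = emptyenv())
  env$def <- list(name = name, notes = list(), compartments = list(),
                  species = list(), reactions = list(), parameters = list(),
                  equilibrium_candidates = list())
  env
}

db_compartment <- function(b, id, name = id, relative_volume = 1,
                           exchange = FALSE) {
  b$def$compartments[[length(b$def$compartments) + 1]] <-
    list(id = id, name = name, relative_volume = relative_volume,
         exchange = exchange)
  invisible(b)
}

db_species <- function(b, id, name, compartment, initial, boundary = FALSE,
                       pathway = "other") {
  b$def$species[[length(b$def$species) + 1]] <-
    list(id = id, name = name, compartment = compartment,
         initial_concentration = initial, boundary = boundary,
         pathway = pathway)
  invisible(b)
}

db_param <- function(b, name, value, kind, bounds_factor = NULL) {
  low <- NULL; high <- NULL
  if (!is.null(bounds_factor)) { low <- value / bounds_factor; high <- value * bounds_factor }
  b$def$parameters[[length(b$def$parameters) + 1]] <-
    list(name = name, value = value, kind = kind, low = low, high = high)
  invisible(b)
}

# km_prod entries: named numeric over products; NA marks a product absent from
# the rate law (no product-inhibition term). For irreversible templates the
# product constants are named Ki_, for reversible ones Km_.
db_reaction <- function(b, id, name = id, pathway, template, substrates,
                        products, vf, vr = NULL, keq = NULL,
                        km_sub = NULL, km_prod = NULL,
                        kia = NULL, kib = NULL, kiq = NULL, hill = NULL,
                        activator = NULL, act_ka = NULL,
                        inhibitor = NULL, inh_ki = NULL,
                        vmax_bounds = 100) {
  tpl <- TEMPLATES[[template]]
  if (is.null(tpl)) stop("unknown template ", template)
  rev <- isTRUE(tpl$rev) && template != "facilitated_transport"
  pn <- list(vf = paste0("Vf_", id), vr = NULL, keq = NULL,
             km_sub = character(0), km_prod = character(0),
             kia = NULL, kib = NULL, kiq = NULL, hill = NULL,
             act_ka = NULL, inh_ki = NULL)
  db_param(b, pn$vf, vf, "Vmax", vmax_bounds)
  if (!is.null(vr)) {
    pn$vr <- paste0("Vr_", id); db_param(b, pn$vr, vr, "Vmax", vmax_bounds)
  }
  if (!is.null(keq)) {
    pn$keq <- paste0("Keq_", id); db_param(b, pn$keq, keq, "Keq")
  }
  if (template == "facilitated_transport") {
    pn$km_sub <- paste0("Km_", id)
    db_param(b, pn$km_sub, km_sub[[1]], "Km")
    pn$km_prod <- pn$km_sub
  } else if (template != "mass_action") {
    for (sp in names(substrates)) {
      nm <- paste0("Km_", id, "_", sp)
      db_param(b, nm, km_sub[[sp]], "Km")
      pn$km_sub <- c(pn$km_sub, nm)
    }
    for (sp in names(products)) {
      v <- if (!is.null(km_prod)) km_prod[[sp]] else NA
      if (is.null(v) || is.na(v)) { pn$km_prod <- c(pn$km_prod, NA); next }
      nm <- paste0(if (rev) "Km_" else "Ki_", id, "_", sp)
      db_param(b, nm, v, if (rev) "Km" else "Ki")
      pn$km_prod <- c(pn$km_prod, nm)
    }
  }
  for (fld in c("kia", "kib", "kiq")) {
    v <- get(fld)
    if (!is.null(v)) {
      nm <- paste0(toupper(substr(fld, 1, 1)), substr(fld, 2, 3), "_", id)
      db_param(b, nm, v, "Ki")
      pn[[fld]] <- nm
    }
  }
  if (!is.null(hill)) { pn$hill <- paste0("n_", id); db_param(b, pn$hill, hill, "misc") }
  if (!is.null(activator)) {
    pn$act_ka <- paste0("Ka_", id, "_", activator)
    db_param(b, pn$act_ka, act_ka, "Km")
  }
  if (!is.null(inhibitor)) {
    pn$inh_ki <- paste0("Kni_", id, "_", inhibitor)
    db_param(b, pn$inh_ki, inh_ki, "Ki")
  }
  km_prod_json <- lapply(seq_along(pn$km_prod), function(i)
    if (is.na(pn$km_prod[i])) NULL else pn$km_prod[i])
  b$def$reactions[[length(b$def$reactions) + 1]] <- list(
    id = id, name = name, pathway = pathway, template = template,
    substrates = as.list(substrates), products = as.list(products),
    modifiers = list(activator = activator, inhibitor = inhibitor),
    params = list(vf = pn$vf, vr = pn$vr, keq = pn$keq,
                  km_sub = as.list(pn$km_sub), km_prod = km_prod_json,
                  kia = pn$kia, kib = pn$kib, kiq = pn$kiq, hill = pn$hill,
                  act_ka = pn$act_ka, inh_ki = pn$inh_ki))
  invisible(b)
}

# ---- reduced fixture network ------------------------------------------------

#' Fixture network for tests and synthetic studies
#'
#' `"reduced"` builds a 12-species / 12-reaction two-compartment glycolysis
#' trunk with a lactate branch, a lumped mitochondrial oxidation arm and a
#' conserved NAD/NADH cofactor pair, preserving every structural feature the
#' pipeline exercises (reversibility, facilitated transport, compartment
#' pooling, conserved moieties) at a fraction of the full network's cost.
#' `"full"` loads the complete beta-cell network from the shipped definition
#' document ([betacell_definition()]).
#'
#' Initial concentrations of the reduced fixture are its basal (2.8 mM
#' glucose) steady state, so stimulation protocols start from rest.
#'
#' @param size `"reduced"` or `"full"`.
#' @return a `bg_model`.
#' @export
make_fixture_network <- function(size = c("reduced", "full")) {
  size <- match.arg(size)
  if (size == "full") return(build_network(betacell_definition()))
  b <- definition_builder("reduced beta-cell fixture")
  db_compartment(b, "e", "extracellular", 10, exchange = TRUE)
  db_compartment(b, "c", "cytosol", 3)
  db_compartment(b, "m", "mitochondria", 1)

  ini <- fixture_initial_state()
  sp <- function(id, name, comp, pathway, boundary = FALSE)
    db_species(b, id, name, comp, ini[[id]], boundary, pathway)
  sp("GLC_e", "GLC_e", "e", "other", boundary = TRUE)
  sp("LAC_e", "LAC_e", "e", "other", boundary = TRUE)
  sp("GLC_c", "GLC", "c", "glycolysis")
  sp("G6P_c", "G6P", "c", "glycolysis")
  sp("FBP_c", "FBP", "c", "glycolysis")
  sp("TRI_c", "TRI", "c", "glycolysis")
  sp("PYR_c", "PYR", "c", "glycolysis")
  sp("LAC_c", "LAC", "c", "glycolysis")
  sp("PYR_m", "PYR", "m", "tca")
  sp("ACA_m", "ACA", "m", "tca")
  sp("CIT_m", "CIT", "m", "tca")
  sp("OAA_m", "OAA", "m", "tca")
  sp("NAD_m", "NAD", "m", "etc")
  sp("NADH_m", "NADH", "m", "etc")

  db_reaction(b, "glut", "glucose transport", "glycolysis",
              "facilitated_transport", c(GLC_e = 1), c(GLC_c = 1),
              vf = 0.8547, km_sub = list(17))
  db_reaction(b, "gk", "glucokinase", "glycolysis", "irreversible_mm_1s",
              c(GLC_c = 1), c(G6P_c = 1), vf = 0.45,
              km_sub = list(GLC_c = 8), km_prod = list(G6P_c = 0.5))
  db_reaction(b, "pfk", "phosphofructokinase (lumped)", "glycolysis",
              "irreversible_mm_1s", c(G6P_c = 1), c(FBP_c = 1), vf = 0.27,
              km_sub = list(G6P_c = 0.4), km_prod = list(FBP_c = NA))
  db_reaction(b, "aldo", "aldolase", "glycolysis", "ordered_bi_bi",
              c(FBP_c = 1), c(TRI_c = 2), vf = 30, vr = 29.4,
              keq = 30 / 29.4,
              km_sub = list(FBP_c = 0.3), km_prod = list(TRI_c = 0.2))
  db_reaction(b, "gapdh", "lower glycolysis (lumped)", "glycolysis",
              "irreversible_mm_2s", c(TRI_c = 1, NAD_m = 1),
              c(PYR_c = 1, NADH_m = 1), vf = 0.9,
              km_sub = list(TRI_c = 0.2, NAD_m = 0.3),
              km_prod = list(PYR_c = NA, NADH_m = NA))
  db_reaction(b, "ldh", "lactate dehydrogenase", "glycolysis", "ordered_bi_bi",
              c(PYR_c = 1, NADH_m = 1), c(LAC_c = 1, NAD_m = 1),
              vf = 1.3333, vr = 0.4, keq = 3.3333,
              km_sub = list(PYR_c = 0.3, NADH_m = 0.05),
              km_prod = list(LAC_c = 2, NAD_m = 0.5))
  db_reaction(b, "mct", "lactate transport", "glycolysis",
              "facilitated_transport", c(LAC_c = 1), c(LAC_e = 1),
              vf = 2.1, km_sub = list(2))
  db_reaction(b, "pyrh", "mitochondrial pyruvate carrier", "tca",
              "facilitated_transport", c(PYR_c = 1), c(PYR_m = 1),
              vf = 5.37, km_sub = list(0.5))
  db_reaction(b, "pdh", "pyruvate dehydrogenase", "tca", "irreversible_mm_2s",
              c(PYR_m = 1, NAD_m = 1), c(ACA_m = 1, NADH_m = 1), vf = 0.571,
              km_sub = list(PYR_m = 0.1, NAD_m = 0.3),
              km_prod = list(ACA_m = 0.2, NADH_m = NA))
  db_reaction(b, "cs", "citrate synthase", "tca", "irreversible_mm_2s",
              c(ACA_m = 1, OAA_m = 1), c(CIT_m = 1), vf = 0.8,
              km_sub = list(ACA_m = 0.05, OAA_m = 0.01),
              km_prod = list(CIT_m = NA))
  db_reaction(b, "citox", "citrate oxidation (lumped TCA turn)", "tca",
              "irreversible_mm_2s", c(CIT_m = 1, NAD_m = 1),
              c(OAA_m = 1, NADH_m = 1), vf = 0.6,
              km_sub = list(CIT_m = 0.4, NAD_m = 0.3),
              km_prod = list(OAA_m = NA, NADH_m = NA))
  db_reaction(b, "dhases", "NADH turnover (lumped dehydrogenases/ETC)",
              "etc", "reversible_uni_uni_haldane", c(NADH_m = 1),
              c(NAD_m = 1), vf = 2.4444, vr = 0.24444, keq = 10,
              km_sub = list(NADH_m = 0.1), km_prod = list(NAD_m = 1.0))
  b$def$equilibrium_candidates <- list("aldo")
  build_network(b$def)
}

# basal (2.8 mM glucose) steady state of the reduced fixture; regenerate with
# scratch scripts if the fixture kinetics change
fixture_initial_state <- function() {
  list(GLC_e = 2.8, LAC_e = 0.8,
       GLC_c = 1.38752, G6P_c = 0.10555, FBP_c = 0.0159742,
       TRI_c = 0.04551, PYR_c = 0.0577255, LAC_c = 0.791126,
       PYR_m = 0.0444362, ACA_m = 0.00912118, CIT_m = 0.163234,
       OAA_m = 0.198766, NAD_m = 0.625303, NADH_m = 0.0346974)
}

# ---- ground truth + synthetic study ----------------------------------------

#' Sample a ground-truth parameter set
#'
#' Vmax values are drawn log-normally around their nominal values with log-sd
#' `sigma`, rejected back inside the fitting bounds (up to 100 tries, then
#' clipped with a warning). All other parameters stay nominal.
#'
#' @param model a `bg_model`.
#' @param sigma log-scale spread (0 returns the nominal set).
#' @param seed integer seed.
#' @param parameters names of the parameters to resample (default: every
#'   Vmax; for parameter-recovery experiments pass the free parameters only,
#'   so the generating truth lies inside the fitted model class).
#' @return a `bg_params` with provenance `"sampled"`.
#' @export
generate_ground_truth <- function(model, sigma = 0.3, seed = 1,
                                  parameters = vmax_names(model, free_only = FALSE)) {
  p <- model$params
  set.seed(seed)
  vm <- parameters
  if (sigma > 0) {
    for (nm in vm) {
      val <- p$values[nm]
      lo <- max(p$lower[nm], val / 100); hi <- min(p$upper[nm], val * 100)
      ok <- FALSE
      for (i in seq_len(100)) {
        cand <- val * exp(rnorm(1, 0, sigma))
        if (cand >= lo && cand <= hi) { ok <- TRUE; break }
      }
      if (!ok) { cand <- min(max(cand, lo), hi); warning("clipped ", nm, " to bounds") }
      p$values[nm] <- cand
    }
  }
  p$provenance <- "sampled"
  p
}

study_design <- function(model) {
  # emulates the three-study assembly; for the full network the published
  # metabolite panels are used, for fixtures every pooled metabolite
  key <- unique(pool_key(model))
  full <- length(model$reactions) > 20
  panel13 <- if (full) c("2PG", "3PG", "AKG", "ALA", "ASP", "CIT", "FUM",
                         "G3P", "LAC", "MAL", "PEP", "PYR", "R5P", "SUC")
             else key
  panel_mal <- if (full) c("AKG", "ALA", "ASP", "CIT", "FUM", "G3P", "G6P",
                           "GLC", "GLU", "ICIT", "LAC", "MAL", "PYR", "SUC")
             else key
  panel15 <- if (full) c("2PG", "3PG", "AKG", "ALA", "CIT", "F6P", "FUM",
                         "G6P", "ICIT", "LAC", "MAL", "PEP", "R5P", "SUC")
             else key
  rbind(
    expand.grid(metabolite = panel13, time_min = c(3, 6, 10, 15),
                comparison = "high_vs_low", source = "spegel2013",
                stringsAsFactors = FALSE),
    expand.grid(metabolite = panel_mal, time_min = 60,
                comparison = "high_vs_low", source = "malmgren",
                stringsAsFactors = FALSE),
    expand.grid(metabolite = panel15, time_min = c(6, 15),
                comparison = "vs_t0", source = "spegel2015",
                stringsAsFactors = FALSE))
}

#' Generate a synthetic metabolomics + insulin study
#'
#' Simulates the stimulation designs of the emulated studies under a known
#' ground-truth parameter set, then overlays multiplicative log-normal noise:
#' each observation is the mean of `replicates` simulated replicate
#' measurements `noiseless * exp(eps)`, `eps ~ N(0, log(1 + cv))`, with the
#' replicate sample sd in the `sd` column. The insulin response is an affine
#' function of three designated reaction fluxes (time-averaged over each
#' stimulation window) plus noise; the combination is recorded as ground
#' truth so flux-regression recovery can be scored.
#'
#' @param model a `bg_model`.
#' @param truth ground-truth `bg_params` (e.g. [generate_ground_truth()]).
#' @param config a [gsis_config()].
#' @param cv coefficient of variation of the multiplicative noise (0 = none).
#' @param replicates simulated replicate count.
#' @param seed integer seed.
#' @param drivers three reaction ids whose fluxes drive insulin.
#' @param driver_signs direction of each driver's contribution.
#' @return object of class `bg_synthetic_study`: `dataset` (a `bg_dataset`),
#'   `noiseless`, `insulin` (per-timepoint data.frame), `insulin_truth`
#'   (drivers, coefficients, intercept), `truth`, `flux_table` (5 x reactions
#'   window-averaged fluxes under truth), `seed`.
#' @export
simulate_study <- function(model, truth = model$params,
                           config = gsis_config(), cv = 0.15, replicates = 3,
                           seed = 1,
                           drivers = NULL, driver_signs = c(1, -1, 1)) {
  design <- study_design(model)
  design$role <- expected_role(design$comparison, design$time_min, design$source)
  design$fold_change <- 1; design$sd <- 0
  noiseless <- predict_dataset(model, truth, as_dataset(design, validate = FALSE),
                               config)
  if (anyNA(noiseless)) stop("synthetic study invalid: simulation failed")
  set.seed(seed)
  sdlog <- if (cv > 0) log(1 + cv) else 0
  value <- numeric(length(noiseless)); sds <- numeric(length(noiseless))
  for (i in seq_along(noiseless)) {
    reps <- noiseless[i] * exp(rnorm(replicates, 0, sdlog))
    if (cv == 0) { value[i] <- noiseless[i]; sds[i] <- 0 }
    else { value[i] <- mean(reps); sds[i] <- sd(reps) }
  }
  dataset <- as_dataset(data.frame(
    metabolite = design$metabolite, time_min = design$time_min,
    comparison = design$comparison, fold_change = value, sd = sds,
    source = design$source, role = design$role, stringsAsFactors = FALSE))

  # insulin: affine in three designated window-averaged fluxes
  times <- c(3, 6, 10, 15, 60)
  flux_table <- flux_table_for_times(model, truth, times, config)
  if (is.null(drivers))
    drivers <- intersect(c("pyk", "pdh", "ak", "gk", "ldh", "citox"),
                         colnames(flux_table))[1:3]
  stopifnot(length(drivers) == 3, all(drivers %in% colnames(flux_table)))
  F60 <- flux_table[length(times), drivers]
  b <- driver_signs / abs(F60)
  raw <- as.numeric(flux_table[, drivers] %*% b)
  beta <- 1.5 / (raw[length(times)] - raw[1])
  coefs <- setNames(beta * b, drivers)
  intercept <- 1.5 - sum(coefs * flux_table[1, drivers])
  y0 <- intercept + as.numeric(flux_table[, drivers] %*% coefs)
  y <- y0 * exp(rnorm(length(times), 0, sdlog))
  insulin <- data.frame(time_min = times, fold_change = y, noiseless = y0,
                        sd = abs(y0) * cv)
  structure(list(dataset = dataset, noiseless = noiseless, insulin = insulin,
                 insulin_truth = list(drivers = drivers, coefficients = coefs,
                                      intercept = intercept),
                 truth = truth, flux_table = flux_table, seed = seed,
                 config = config, cv = cv, replicates = replicates),
            class = "bg_synthetic_study")
}

#' @export
print.bg_synthetic_study <- function(x, ...) {
  cat("<bg_synthetic_study> ", nrow(x$dataset), " observations (",
      sum(x$dataset$role == "train"), " train / ",
      sum(x$dataset$role == "validation"), " validation), cv = ", x$cv,
      ", seed = ", x$seed, "\n", sep = "")
  cat("insulin drivers:", paste(x$insulin_truth$drivers, collapse = ", "), "\n")
  invisible(x)
}

#' Synthetic insulin observations for arbitrary flux conditions
#'
#' Evaluates a study's recorded insulin ground truth (affine in the three
#' designated driver fluxes) on new flux rows and overlays multiplicative
#' noise — the generator side of building flux-to-insulin regressions over
#' richer condition sets (e.g. stacked time windows across several parameter
#' sets), where a handful of collinear time points alone would leave the
#' regression ill-posed.
#'
#' @param study a `bg_synthetic_study`.
#' @param flux_table matrix with one row per condition, reaction columns.
#' @param cv multiplicative noise level (0 = noiseless).
#' @param seed integer seed.
#' @return numeric response vector, one insulin fold-change per row.
#' @export
synthetic_insulin <- function(study, flux_table, cv = study$cv, seed = 1) {
  it <- study$insulin_truth
  y0 <- it$intercept +
    as.numeric(flux_table[, it$drivers, drop = FALSE] %*% it$coefficients)
  set.seed(seed)
  if (cv > 0) y0 <- y0 * exp(rnorm(length(y0), 0, log(1 + cv)))
  y0
}

#' Known-answer VIP recovery experiment
#'
#' Generates a synthetic flux table with independent column variation around
#' the model's predicted flux magnitudes (log-normal jitter per reaction), an
#' insulin response that is an affine function of three designated driver
#' reactions plus noise, fits the SIMPLS regression, and checks whether the
#' three drivers occupy the top three VIP ranks.
#'
#' Fluxes simulated from a kinetic model cannot be used directly here:
#' steady-state fluxes along an unbranched chain are exactly proportional, so
#' attribution of importance to one member of a chain is structurally
#' ill-posed. Drawing the columns independently gives the recovery a known,
#' well-posed answer while keeping each column on its physiological scale.
#'
#' @param model a `bg_model` (its 60-min stimulated fluxes set the column
#'   scales) or a named vector of flux scales.
#' @param drivers three reaction ids.
#' @param driver_signs contribution signs.
#' @param n_rows synthetic conditions.
#' @param spread log-sd of the column jitter.
#' @param cv relative sd of the response noise.
#' @param seed integer seed.
#' @param config a [gsis_config()] (used only when scales are computed).
#' @return list with `ok` (drivers == top-3 VIP set), `top3`, `vip`, `X`, `y`.
#' @export
vip_recovery <- function(model, drivers = c("glut", "gk", "ldh"),
                         driver_signs = c(1, 1, -1), n_rows = 32,
                         spread = 0.3, cv = 0.15, seed = 1,
                         config = gsis_config()) {
  scales <- flux_scales(model, config)
  stopifnot(all(drivers %in% names(scales)))
  X <- synthetic_flux_table(scales, n_rows = n_rows, spread = spread,
                            seed = seed)
  b <- setNames(driver_signs / (scales[drivers] * spread), drivers)
  y0 <- 2 + as.numeric((X[, drivers] -
                          matrix(scales[drivers], n_rows, 3, byrow = TRUE)) %*% b)
  y <- y0 + rnorm(n_rows, 0, cv * sd(y0))
  fit <- suppressWarnings(simpls_fit(X, y, 3))
  v <- vip_scores(fit)
  top3 <- names(sort(v, decreasing = TRUE))[1:3]
  list(ok = setequal(top3, drivers), top3 = top3, vip = v, X = X, y = y)
}

flux_scales <- function(model, config = gsis_config()) {
  scales <- if (inherits(model, "bg_model")) {
    ft <- flux_table_for_times(model, model$params, 60, config)
    abs(ft[1, ])
  } else abs(model)
  scales[scales < 1e-6] <- 1e-6
  scales
}

#' Column-independent synthetic flux table
#'
#' Draws a flux table whose columns vary independently (log-normal jitter
#' around each reaction's physiological flux magnitude). Used for
#' known-answer regression experiments ([vip_recovery()] and the directional
#' intervention checks), where flux tables simulated from the kinetic model
#' are too collinear to attribute a response to individual reactions.
#'
#' @param model a `bg_model` (its 60-min stimulated fluxes set the column
#'   scales) or a named vector of flux scales.
#' @param n_rows conditions (rows).
#' @param spread log-sd of the jitter.
#' @param seed integer seed.
#' @param config a [gsis_config()] (used only when scales are computed).
#' @return matrix (n_rows x reactions).
#' @export
synthetic_flux_table <- function(model, n_rows = 32, spread = 0.3, seed = 1,
                                 config = gsis_config()) {
  scales <- flux_scales(model, config)
  set.seed(seed)
  p <- length(scales)
  matrix(rep(scales, each = n_rows) * exp(rnorm(n_rows * p, 0, spread)),
         n_rows, p, dimnames = list(NULL, names(scales)))
}

#' Window-averaged flux table across stimulation durations
#'
#' One row per stimulation time point: the average flux of every reaction
#' from the glucose switch to that time under the high-glucose protocol (the
#' input matrix of the flux-to-insulin PLSR).
#'
#' @param model a `bg_model`.
#' @param params a `bg_params`.
#' @param times stimulation durations (minutes).
#' @param config a [gsis_config()].
#' @return matrix (length(times) x reactions).
#' @export
flux_table_for_times <- function(model, params, times = c(3, 6, 10, 15, 60),
                                 config = gsis_config()) {
  pre <- config$preincubation
  prot <- stimulation_protocol(
    data.frame(duration = c(pre, max(times)),
               GLC_e = c(config$low_glucose, config$high_glucose)),
    output_grid = seq(0, pre + max(times), by = 1))
  traj <- simulate(model, params, protocol = prot,
                   rtol = config$rtol, atol = config$atol)
  out <- t(vapply(times, function(tm)
    time_averaged_fluxes(traj, c(pre, pre + tm)), numeric(ncol(traj$flux))))
  rownames(out) <- times
  out
}
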