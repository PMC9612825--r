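# Vmax perturbation machinery: multiply a reaction's maximal velocities by a
# factor (forward and reverse together, so the perturbation changes capacity,
# not the equilibrium position), re-run the stimulated condition, and compare
# against the unperturbed baseline.

perturb_params <- function(model, params, reaction, factor) {
  stopifnot(factor > 0)
  r <- model$reactions[[reaction]]
  if (is.null(r)) stop("unknown reaction: ", reaction)
  p <- r$params
  targets <- p$vf
  if (!is.na(p$vr) && !isTRUE(r$constrained)) targets <- c(targets, p$vr)
  params$values[targets] <- params$values[targets] * factor
  params$lower[targets] <- pmin(params$lower[targets], params$values[targets])
  params$upper[targets] <- pmax(params$upper[targets], params$values[targets])
  params
}

#' Baseline condition for perturbation analyses
#'
#' Computes the unperturbed reference: the certified steady state under high
#' glucose, and (for insulin predictions) the time-averaged reaction fluxes
#' over the stimulation window of the standard high-vs-low protocol.
#'
#' @param model a `bg_model`.
#' @param params a `bg_params`.
#' @param config a [gsis_config()].
#' @param horizon steady-state horizon (minutes).
#' @param window flux-averaging window after the glucose switch (minutes),
#'   matching the PLSR training rows.
#' @return list of class `bg_baseline`.
#' @export
perturbation_baseline <- function(model, params = model$params,
                                  config = gsis_config(), horizon = 4320,
                                  window = 60) {
  ss <- steady_state(model, params, glucose = config$high_glucose,
                     horizon = horizon)
  prot <- stimulation_protocol(data.frame(
    duration = c(config$preincubation, window),
    GLC_e = c(config$low_glucose, config$high_glucose)))
  traj <- simulate(model, params, protocol = prot,
                   rtol = config$rtol, atol = config$atol)
  wfl <- time_averaged_fluxes(traj, c(config$preincubation,
                                      config$preincubation + window))
  structure(list(state = ss$state, fluxes = ss$fluxes,
                 converged = ss$converged, window_fluxes = wfl,
                 config = config, horizon = horizon, window = window),
            class = "bg_baseline")
}

perturbation_result <- function(model, params, baseline, label, reaction,
                                factor, plsr_ensemble = NULL,
                                log2_threshold = 0.05) {
  config <- baseline$config
  ss <- steady_state(model, params, glucose = config$high_glucose,
                     horizon = baseline$horizon)
  species_fc <- ss$state / pmax(baseline$state, 1e-12)
  species_fc[baseline$state < 1e-9] <- NA_real_
  key <- pool_key(model)[names(ss$state)]
  w <- compartment_volumes(model)[model$species$compartment[
    match(names(ss$state), model$species$id)]]
  pooled <- rowsum(w * ss$state, key)[, 1] / rowsum(w * baseline$state, key)[, 1]
  flux_fc <- ifelse(abs(baseline$fluxes) < 1e-12, NA_real_,
                    ss$fluxes / baseline$fluxes)
  reversals <- names(ss$fluxes)[sign(ss$fluxes) * sign(baseline$fluxes) < 0 &
                                  abs(ss$fluxes) > 1e-9 &
                                  abs(baseline$fluxes) > 1e-9]
  no_change <- names(species_fc)[!is.na(species_fc) &
                                   abs(log2(species_fc)) < log2_threshold]
  insulin_fc <- NA_real_
  if (!is.null(plsr_ensemble)) {
    prot <- stimulation_protocol(data.frame(
      duration = c(config$preincubation, baseline$window),
      GLC_e = c(config$low_glucose, config$high_glucose)))
    traj <- simulate(model, params, protocol = prot,
                     rtol = config$rtol, atol = config$atol)
    wfl <- time_averaged_fluxes(traj, c(config$preincubation,
                                        config$preincubation + baseline$window))
    insulin_fc <- insulin_effect(wfl, plsr_ensemble, baseline$window_fluxes)
  }
  structure(list(label = label, reaction = reaction, factor = factor,
                 species_fc = species_fc, pooled_fc = pooled,
                 flux_fc = flux_fc, reversals = reversals,
                 no_change = no_change, insulin_fc = insulin_fc,
                 converged = ss$converged),
            class = "bg_perturbation")
}

#' @export
print.bg_perturbation <- function(x, ...) {
  cat("<bg_perturbation> ", x$label, " (", x$reaction, " x", x$factor, ")\n",
      sep = "")
  ch <- x$species_fc[!is.na(x$species_fc)]
  ch <- ch[abs(log2(ch)) >= 0.05]
  cat(length(ch), " species changed (|log2 FC| >= 0.05); ",
      length(x$reversals), " flux reversal(s)", sep = "")
  if (!is.na(x$insulin_fc))
    cat("; predicted insulin fold-change ", signif(x$insulin_fc, 4), sep = "")
  cat("\n")
  invisible(x)
}

#' Systematic Vmax perturbation scan
#'
#' Increases and decreases every reaction's maximal velocity by `factor`
#' (both directions), re-computes the stimulated steady state, and reports
#' fold-changes of all metabolites and fluxes versus the unperturbed
#' baseline, flux-direction reversals, and (when a PLSR ensemble is given)
#' the predicted insulin effect. Species with `|log2 FC| < 0.05` are flagged
#' "no change". Scenario failures are recorded and the scan continues.
#'
#' @inheritParams perturbation_baseline
#' @param factor multiplicative perturbation (both `factor` and `1/factor`
#'   scenarios are run per reaction).
#' @param reactions reaction ids to scan (default: all).
#' @param plsr_ensemble optional list of `bg_plsr` fits for insulin effects.
#' @param baseline optionally a precomputed [perturbation_baseline()].
#' @return list of class `bg_scan`: `results` (list of `bg_perturbation`),
#'   `failed` (labels), `tidy` (long data.frame: perturbation, target,
#'   fold_change, type).
#' @export
scan_vmax <- function(model, params = model$params, factor = 2,
                      reactions = names(model$reactions),
                      config = gsis_config(), plsr_ensemble = NULL,
                      baseline = NULL, horizon = 4320) {
  if (is.null(baseline))
    baseline <- perturbation_baseline(model, params, config, horizon = horizon)
  results <- list(); failed <- character(0)
  for (rid in reactions) {
    for (f in unique(c(factor, 1 / factor))) {
      lab <- paste0(rid, "_x", signif(f, 3))
      res <- tryCatch(
        perturbation_result(model, perturb_params(model, params, rid, f),
                            baseline, lab, rid, f, plsr_ensemble),
        error = function(e) NULL)
      if (is.null(res)) failed <- c(failed, lab) else results[[lab]] <- res
    }
  }
  tidy <- do.call(rbind, lapply(results, function(r) rbind(
    data.frame(perturbation = r$label, target = names(r$pooled_fc),
               fold_change = unname(r$pooled_fc), type = "metabolite"),
    data.frame(perturbation = r$label, target = names(r$flux_fc),
               fold_change = unname(r$flux_fc), type = "flux"),
    if (!is.na(r$insulin_fc))
      data.frame(perturbation = r$label, target = "insulin",
                 fold_change = r$insulin_fc, type = "insulin"))))
  rownames(tidy) <- NULL
  structure(list(results = results, failed = failed, tidy = tidy,
                 baseline = baseline), class = "bg_scan")
}

#' Named pharmacological intervention scenarios
#'
#' Registered scenarios: `metformin` (80 percent knockdown of glucose
#' transport, `glut` x 0.2), `agrimony` (five-fold increase of
#' glucose-6-phosphate dehydrogenase, `g6pd` x 5, emulating PPP-driving
#' antioxidant action) and `ak_knockdown` (five-fold reduction of adenylate
#' kinase, `ak` x 0.2). A user scenario is a `list(reaction=, factor=,
#' label=)`.
#'
#' @inheritParams scan_vmax
#' @param scenario scenario name or user list.
#' @return a `bg_perturbation`.
#' @export
apply_intervention <- function(model, params = model$params, scenario,
                               config = gsis_config(), plsr_ensemble = NULL,
                               baseline = NULL, horizon = 4320) {
  registry <- list(
    metformin = list(reaction = "glut", factor = 0.2, label = "metformin"),
    agrimony = list(reaction = "g6pd", factor = 5, label = "agrimony"),
    ak_knockdown = list(reaction = "ak", factor = 0.2, label = "ak_knockdown"))
  if (is.character(scenario)) {
    if (!scenario %in% names(registry))
      stop("unknown scenario '", scenario, "'; registered: ",
           paste(names(registry), collapse = ", "))
    scenario <- registry[[scenario]]
  }
  if (is.null(baseline))
    baseline <- perturbation_baseline(model, params, config, horizon = horizon)
  perturbation_result(model,
                      perturb_params(model, params, scenario$reaction,
                                     scenario$factor),
                      baseline, scenario$label %||% scenario$reaction,
                      scenario$reaction, scenario$factor, plsr_ensemble)
}

#' Predicted insulin effect of perturbed fluxes
#'
#' Ratio of the PLSR-ensemble insulin prediction on the perturbed
#' time-averaged fluxes to the prediction on the baseline fluxes.
#'
#' @param perturbed_fluxes,baseline_fluxes named flux vectors in the
#'   ensemble's column order.
#' @param plsr_ensemble a `bg_plsr` or list of them.
#' @return scalar fold-change.
#' @export
insulin_effect <- function(perturbed_fluxes, plsr_ensemble, baseline_fluxes) {
  predict_insulin(plsr_ensemble, perturbed_fluxes) /
    predict_insulin(plsr_ensemble, baseline_fluxes)
}
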