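# project-wide plumbing: tidy writers, pipeline configuration, manifests,
# derived random streams

#' Write a trajectory as tidy delimited tables
#'
#' Writes `<prefix>_concentrations.tsv` and `<prefix>_fluxes.tsv` in long
#' form (`time`, `id`, `value`), tab-delimited, period decimal separator,
#' fixed significant digits for diffability.
#'
#' @param traj a `bg_trajectory`.
#' @param prefix output path prefix.
#' @param digits significant digits.
#' @param wide also write wide matrices (`*_wide.tsv`).
#' @return invisibly, the paths written.
#' @export
write_trajectory <- function(traj, prefix, digits = 10, wide = FALSE) {
  fmt <- function(x) signif(x, digits)
  paths <- character(0)
  for (what in c("concentrations", "fluxes")) {
    m <- if (what == "concentrations") traj$conc else traj$flux
    long <- data.frame(time = rep(traj$times, ncol(m)),
                       id = rep(colnames(m), each = nrow(m)),
                       value = fmt(as.numeric(m)))
    p <- paste0(prefix, "_", what, ".tsv")
    write.table(long, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    if (wide) {
      pw <- paste0(prefix, "_", what, "_wide.tsv")
      write.table(data.frame(time = traj$times, fmt(m), check.names = FALSE),
                  pw, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, pw)
    }
  }
  invisible(paths)
}

#' Read a tidy long-form table written by [write_trajectory()]
#' @param path file path.
#' @return data.frame with `time`, `id`, `value`.
#' @export
read_tidy_table <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Pipeline configuration
#'
#' Single configuration object consumed by [run_pipeline()]; every stage
#' reads its settings from here. Unknown keys are rejected.
#'
#' @param model `"reduced"`, `"full"`, or a path to a definition document.
#' @param seed global seed; each stage derives its own stream from it.
#' @param cv synthetic-study noise level.
#' @param free_parameters free Vmax names (default: a small identifiable set
#'   chosen per model).
#' @param runs,iterations,swarm_size,keep_best PSO scale.
#' @param efast_samples eFAST samples per curve (0 skips the eFAST stage,
#'   falling back to all free parameters).
#' @param n_components PLSR components.
#' @param train_times stimulation durations used as PLSR training rows.
#' @param scan_reactions reactions for the perturbation stage (default: the
#'   registered intervention targets).
#' @param gsis a [gsis_config()].
#' @param ... unknown keys are rejected.
#' @return list of class `bg_pipeline_config`.
#' @export
pipeline_config <- function(model = "reduced", seed = 1, cv = 0.15,
                            free_parameters = NULL, runs = 5,
                            iterations = 150, swarm_size = 20, keep_best = 4,
                            efast_samples = 0, n_components = 3,
                            train_times = c(3, 15, 60),
                            scan_reactions = NULL, gsis = gsis_config(), ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(names(extra), collapse = ", "))
  structure(list(model = model, seed = seed, cv = cv,
                 free_parameters = free_parameters, runs = runs,
                 iterations = iterations, swarm_size = swarm_size,
                 keep_best = keep_best, efast_samples = efast_samples,
                 n_components = n_components, train_times = train_times,
                 scan_reactions = scan_reactions, gsis = gsis),
            class = "bg_pipeline_config")
}

# per-stage derived seeds: deterministic function of (global seed, stage name)
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (seed * 7919L + h) %% 2147480000L
}

#' Run the full analysis pipeline on synthetic data
#'
#' Sequences the stages end to end at the configured scale: synthetic-study
#' generation, identifiability screen + equilibrium reparameterization, eFAST
#' parameter selection (optional at desk scale), PSO fitting, flux
#' prediction, PLSR with VIP scores, and the perturbation scenarios. Writes
#' every stage artifact under `out` together with a JSON manifest (config,
#' seed, package version).
#'
#' @param config a [pipeline_config()].
#' @param out output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  model <- if (config$model %in% c("reduced", "full"))
    make_fixture_network(config$model) else build_network(config$model)

  # 1. synthetic study
  study <- simulate_study(model, generate_ground_truth(
    model, sigma = 0.3, seed = derive_seed(config$seed, "truth")),
    config = config$gsis, cv = config$cv,
    seed = derive_seed(config$seed, "study"))
  write_dataset(study$dataset, file.path(out, "dataset.tsv"))

  # 2. identifiability screen + equilibrium constraints
  pairs <- detect_correlated_velocity_pairs(model, model$params,
                                            study$dataset, config$gsis)
  write.table(pairs, file.path(out, "correlated_pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  model_c <- if (nrow(pairs)) reparameterize_equilibrium(model, pairs) else model

  # 3. parameter selection
  free <- config$free_parameters %||% default_free_parameters(model_c)
  if (config$efast_samples > 0) {
    sens <- efast_sensitivity(model_c, model_c$params,
                              training_observables(model_c, study$dataset,
                                                   config$gsis),
                              parameters = free,
                              samples = config$efast_samples,
                              seed = derive_seed(config$seed, "efast"))
    write.table(data.frame(parameter = rownames(sens$indices),
                           max_index = apply(sens$indices, 1, max)),
                file.path(out, "efast_selection.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (length(sens$selection)) free <- sens$selection
  }

  # 4. fitting
  fc <- fit_config(free_parameters = free, runs = config$runs,
                   iterations = config$iterations,
                   swarm_size = config$swarm_size,
                   keep_best = min(config$keep_best, config$runs),
                   seed = derive_seed(config$seed, "pso"))
  fit <- fit_pso(model_c, study$dataset, fc, gsis = config$gsis)
  fitted_tab <- do.call(rbind, lapply(seq_along(fit$par_sets), function(i)
    data.frame(set = i, parameter = free,
               value = fit$par_sets[[i]]$values[free], wssr = fit$wssr[i])))
  write.table(fitted_tab, file.path(out, "fitted_parameters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # 5. flux prediction + PLSR ensemble
  times <- sort(unique(c(config$train_times, study$insulin$time_min)))
  ensemble <- lapply(fit$par_sets, function(p) {
    ft <- flux_table_for_times(model_c, p, times, config$gsis)
    tr <- times %in% config$train_times
    simpls_fit(ft[tr, , drop = FALSE],
               study$insulin$fold_change[match(times[tr], study$insulin$time_min)],
               n_components = min(config$n_components, sum(tr) - 1))
  })
  vips <- rowMeans(vapply(ensemble, vip_scores,
                          numeric(length(ensemble[[1]]$vip))), na.rm = TRUE)
  write.table(data.frame(reaction = names(vips), vip = vips)[order(vips), ],
              file.path(out, "vip_scores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # 6. perturbations
  baseline <- perturbation_baseline(model_c, fit$par_sets[[1]], config$gsis)
  scan_rx <- config$scan_reactions %||%
    intersect(c("glut", "g6pd", "ak"), names(model$reactions))
  scan <- scan_vmax(model_c, fit$par_sets[[1]], reactions = scan_rx,
                    config = config$gsis, plsr_ensemble = ensemble,
                    baseline = baseline)
  write.table(scan$tidy, file.path(out, "perturbation_scan.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  manifest <- list(package = "betaGSIS",
                   version = as.character(utils::packageVersion("betaGSIS")),
                   seed = config$seed,
                   config = unclass(config[setdiff(names(config), "gsis")]),
                   gsis = unclass(config$gsis),
                   artifacts = list.files(out))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(study = study, pairs = pairs, fit = fit,
                 ensemble = ensemble, scan = scan, out = out))
}

default_free_parameters <- function(model) {
  cand <- paste0("Vf_", c("glut", "gk", "pfk", "pdh", "ldh"))
  found <- intersect(cand, names(model$params$values))
  if (length(found) >= 3) found else utils::head(vmax_names(model), 5)
}
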