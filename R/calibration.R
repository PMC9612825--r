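#' Load a fold-change metabolomics dataset
#'
#' Reads a tab-delimited table with columns `metabolite`, `time_min`,
#' `comparison` (`high_vs_low` or `vs_t0`), `fold_change`, `sd`, `source`,
#' `role` (`train` or `validation`). For rows from the three emulated source
#' studies the train/validation role is validated against the assembly rules:
#' high-vs-low fold-changes at 3 and 10 min (Spegel-2013 design) and 60 min
#' (Malmgren design) train, the 6- and 15-min high-vs-low points validate,
#' and the vs-t0 points (Spegel-2015 design) train.
#'
#' @param path file path.
#' @return data.frame of class `bg_dataset`.
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) {
    warning("empty dataset: ", path)
    return(as_dataset(d[0, , drop = FALSE], validate = FALSE))
  }
  as_dataset(d)
}

as_dataset <- function(d, validate = TRUE) {
  req <- c("metabolite", "time_min", "comparison", "fold_change", "sd",
           "source", "role")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("dataset lacks column(s): ", paste(miss, collapse = ", "))
  if (validate) {
    for (i in seq_len(nrow(d))) {
      if (!is.finite(d$fold_change[i]) || d$fold_change[i] <= 0)
        stop("row ", i, ": fold_change must be > 0")
      if (!is.finite(d$sd[i]) || d$sd[i] < 0)
        stop("row ", i, ": sd must be >= 0")
      if (!d$comparison[i] %in% c("high_vs_low", "vs_t0"))
        stop("row ", i, ": unknown comparison '", d$comparison[i], "'")
      if (!d$role[i] %in% c("train", "validation"))
        stop("row ", i, ": unknown role '", d$role[i], "'")
    }
    expected <- expected_role(d$comparison, d$time_min, d$source)
    bad <- which(!is.na(expected) & expected != d$role)
    if (length(bad))
      stop("row ", bad[1], ": role '", d$role[bad[1]],
           "' conflicts with the data-assembly split (expected '",
           expected[bad[1]], "')")
  }
  class(d) <- c("bg_dataset", "data.frame")
  d
}

expected_role <- function(comparison, time_min, source) {
  known <- c("spegel2013", "malmgren", "spegel2015")
  out <- rep(NA_character_, length(comparison))
  k <- tolower(source) %in% known
  out[k & comparison == "high_vs_low" & time_min %in% c(3, 10, 60)] <- "train"
  out[k & comparison == "high_vs_low" & time_min %in% c(6, 15)] <- "validation"
  out[k & comparison == "vs_t0"] <- "train"
  out
}

#' Write a dataset in the standard tab-delimited layout
#' @param dataset a `bg_dataset`.
#' @param path output path.
#' @export
write_dataset <- function(dataset, path) {
  write.table(dataset, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- protocol configuration shared by fitting, sensitivity, perturbation ----

#' GSIS protocol configuration
#'
#' @param low_glucose,high_glucose extracellular glucose (mM) of the basal and
#'   stimulated conditions.
#' @param preincubation minutes of basal pre-incubation before the switch to
#'   high glucose in the high-vs-low design.
#' @param rtol,atol integration tolerances used in calibration loops (looser
#'   than the reporting default, a configuration key).
#' @return list of class `bg_gsis_config`.
#' @export
gsis_config <- function(low_glucose = 2.8, high_glucose = 16.7,
                        preincubation = 120, rtol = 1e-5, atol = 1e-8) {
  structure(list(low_glucose = low_glucose, high_glucose = high_glucose,
                 preincubation = preincubation, rtol = rtol, atol = atol),
            class = "bg_gsis_config")
}

#' Model predictions for every observation of a dataset
#'
#' Simulates the stimulation designs behind the dataset (basal pre-incubation
#' then high glucose for the high-vs-low comparisons, high glucose from the
#' initial state for the vs-t0 comparisons) and extracts compartment-pooled
#' metabolite fold-changes matching each observation row.
#'
#' @param model a `bg_model`.
#' @param params a `bg_params`.
#' @param dataset a `bg_dataset`.
#' @param config a [gsis_config()].
#' @return numeric vector of predictions aligned with `dataset` rows.
#' @export
predict_dataset <- function(model, params = model$params, dataset,
                            config = gsis_config()) {
  fn <- make_prediction_fn(model, params, dataset, config)
  fn(as.numeric(params$values))
}

# closure over a compiled model: parvec -> predictions (fast path for PSO)
make_prediction_fn <- function(model, params, dataset, config = gsis_config()) {
  compiled <- compile_model(model, params)
  hvl_times <- sort(unique(dataset$time_min[dataset$comparison == "high_vs_low"]))
  t0_times <- sort(unique(dataset$time_min[dataset$comparison == "vs_t0"]))
  pre <- config$preincubation
  key <- pool_key(model)
  has_glc <- "GLC_e" %in% model$species$id[model$species$boundary]
  phases <- function(durations, glucose) {
    ph <- data.frame(duration = durations)
    if (has_glc) ph$GLC_e <- glucose
    ph
  }

  prot_high <- if (length(hvl_times))
    stimulation_protocol(
      phases(c(pre, max(hvl_times)), c(config$low_glucose, config$high_glucose)),
      output_grid = c(0, pre, pre + hvl_times))
  prot_low <- if (length(hvl_times))
    stimulation_protocol(
      phases(pre + max(hvl_times), config$low_glucose),
      output_grid = c(0, pre + hvl_times))
  prot_t0 <- if (length(t0_times))
    stimulation_protocol(
      phases(max(t0_times), config$high_glucose),
      output_grid = c(0, t0_times))

  want <- paste(dataset$comparison, dataset$time_min, dataset$metabolite)

  function(parvec) {
    vals <- setNames(rep(NA_real_, nrow(dataset)), NULL)
    lookup <- character(0); fcs <- numeric(0)
    if (length(hvl_times)) {
      th <- simulate_compiled(model, compiled, parvec, NULL, prot_high,
                              config$rtol, config$atol, error_on_failure = FALSE)
      tl <- simulate_compiled(model, compiled, parvec, NULL, prot_low,
                              config$rtol, config$atol, error_on_failure = FALSE)
      if (isTRUE(th$failed) || isTRUE(tl$failed)) return(vals)
      for (tm in hvl_times) {
        fc <- pooled_fc_fast(model, key, th, tl, pre + tm)
        lookup <- c(lookup, paste("high_vs_low", tm, names(fc)))
        fcs <- c(fcs, fc)
      }
    }
    if (length(t0_times)) {
      tt <- simulate_compiled(model, compiled, parvec, NULL, prot_t0,
                              config$rtol, config$atol, error_on_failure = FALSE)
      if (isTRUE(tt$failed)) return(vals)
      for (tm in t0_times) {
        fc <- pooled_fc_fast(model, key, tt, NULL, tm, vs_t0 = TRUE)
        lookup <- c(lookup, paste("vs_t0", tm, names(fc)))
        fcs <- c(fcs, fc)
      }
    }
    vals <- fcs[match(want, lookup)]
    vals
  }
}

pooled_fc_fast <- function(model, key, traj_num, traj_den, time, vs_t0 = FALSE) {
  i <- traj_index(traj_num, time)
  num <- traj_num$conc[i, ]
  den <- if (vs_t0) traj_num$conc[1, ]
         else traj_den$conc[traj_index(traj_den, time), ]
  w <- compartment_volumes(model)[model$species$compartment[
    match(colnames(traj_num$conc), model$species$id)]]
  kk <- key[colnames(traj_num$conc)]
  numsum <- rowsum(w * num, kk)[, 1]
  densum <- rowsum(w * den, kk)[, 1]
  out <- numsum / densum
  out[densum < 1e-9] <- NA_real_
  out
}

#' Training observables as a function of parameters
#'
#' Convenience wrapper for [efast_sensitivity()]: returns a function mapping a
#' `bg_params` to the named vector of predicted fold-changes for every row of
#' `dataset` (names `comparison@time:metabolite`).
#'
#' @inheritParams predict_dataset
#' @return `function(bg_params) -> named numeric vector`.
#' @export
training_observables <- function(model, dataset, config = gsis_config()) {
  fn <- make_prediction_fn(model, model$params, dataset, config)
  nms <- paste0(dataset$comparison, "@", dataset$time_min, ":",
                dataset$metabolite)
  function(params) setNames(fn(as.numeric(params$values)), nms)
}

#' Weighted sum of squared residuals
#'
#' `WSSR = sum_i ((pred_i - obs_i) / (sd_i * obs_i))^2`: each residual is
#' weighted by the observation's standard deviation (confidence) and by its
#' magnitude (so small fold-changes are not drowned out by large ones).
#' Observations with `sd = 0` use the dataset's median relative sd
#' (`median(sd/fold_change)` over rows with positive sd; 0.1 if none).
#'
#' @param predictions numeric vector aligned with `dataset` rows (e.g. from
#'   [predict_dataset()]).
#' @param dataset a `bg_dataset`.
#' @return scalar WSSR (`Inf` if any prediction is missing/not finite).
#' @export
wssr <- function(predictions, dataset) {
  if (length(predictions) != nrow(dataset))
    stop("predictions length does not match dataset rows")
  if (anyNA(predictions) || any(!is.finite(predictions))) {
    i <- which(!is.finite(predictions))[1]
    stop("missing prediction for observation ", i, " (",
         dataset$metabolite[i], " @ ", dataset$time_min[i], " min, ",
         dataset$comparison[i], ")")
  }
  sd <- dataset$sd
  rel <- sd / dataset$fold_change
  med <- median(rel[sd > 0])
  if (!is.finite(med) || med <= 0) med <- 0.1
  sd[sd == 0] <- med * dataset$fold_change[sd == 0]
  sum(((predictions - dataset$fold_change) / (sd * dataset$fold_change))^2)
}

wssr_safe <- function(predictions, dataset) {
  if (anyNA(predictions) || any(!is.finite(predictions))) return(Inf)
  wssr(predictions, dataset)
}

#' Screen for correlated forward/reverse velocity pairs
#'
#' A-priori identifiability screen: for each reversible reaction with an
#' explicit reverse velocity, perturb Vf and Vr separately (finite
#' differences, +/-50 percent) and compare the resulting normalized
#' output-sensitivity vectors over all training observables. A pair whose
#' vectors have absolute cosine similarity above `threshold` carries only
#' ratio information in the data and is structurally non-identifiable; such
#' reactions should be reparameterized through their equilibrium constant
#' ([reparameterize_equilibrium()]).
#'
#' @param model a `bg_model`.
#' @param params baseline `bg_params`.
#' @param dataset a `bg_dataset` defining the observables.
#' @param config a [gsis_config()].
#' @param delta relative perturbation for the finite differences.
#' @param threshold cosine-similarity cut.
#' @return data.frame of flagged pairs (`reaction`, `vf`, `vr`, `cosine`);
#'   the full screening table is attached as attribute `"all"`.
#' @export
detect_correlated_velocity_pairs <- function(model, params = model$params,
                                             dataset, config = gsis_config(),
                                             delta = 0.5, threshold = 0.99) {
  fn <- make_prediction_fn(model, params, dataset, config)
  pv <- as.numeric(params$values)
  pn <- names(params$values)
  # symmetric multiplicative probe (x(1+delta) up, /(1+delta) down): outputs
  # that depend only on the Vf/Vr ratio then give exactly anti-parallel
  # sensitivity vectors, whatever the nonlinearity
  sens <- function(pname) {
    i <- match(pname, pn)
    up <- pv; up[i] <- pv[i] * (1 + delta)
    dn <- pv; dn[i] <- pv[i] / (1 + delta)
    (fn(up) - fn(dn)) / (2 * log(1 + delta))
  }
  rows <- list()
  for (r in model$reactions) {
    tpl <- TEMPLATES[[r$template]]
    if (!isTRUE(tpl$rev) || r$template == "facilitated_transport") next
    if (is.na(r$params$vr) || isTRUE(r$constrained)) next
    sf <- tryCatch(sens(r$params$vf), error = function(e) NULL)
    sr <- tryCatch(sens(r$params$vr), error = function(e) NULL)
    if (is.null(sf) || is.null(sr) || anyNA(sf) || anyNA(sr)) {
      warning("identifiability probe failed for reaction '", r$id, "'; skipped")
      next
    }
    nf <- sqrt(sum(sf^2)); nr <- sqrt(sum(sr^2))
    scale <- max(nf, nr)
    if (nr < 1e-10 * max(scale, 1e-300) || nf < 1e-10 * max(scale, 1e-300)) {
      co <- 0  # one velocity has (essentially) no effect: identifiable
    } else co <- abs(sum(sf * sr) / (nf * nr))
    rows[[r$id]] <- data.frame(reaction = r$id, vf = r$params$vf,
                               vr = r$params$vr, cosine = co)
  }
  all <- do.call(rbind, rows)
  rownames(all) <- NULL
  flagged <- all[all$cosine > threshold, , drop = FALSE]
  rownames(flagged) <- NULL
  attr(flagged, "all") <- all
  flagged
}

#' Fitting configuration
#'
#' Defaults follow the full calibration protocol (each free parameter varied
#' 100-fold above and below its start, 2000 PSO steps, 100 runs, best 8 kept);
#' scale `runs`/`iterations` down for desk-scale work.
#'
#' @param free_parameters names of the free parameters (default: chosen by
#'   the caller of [fit_pso()]).
#' @param bounds_factor multiplicative half-range of the search box.
#' @param iterations PSO steps per run.
#' @param runs independent PSO runs.
#' @param keep_best parameter sets kept (ranked by WSSR).
#' @param swarm_size particles per run.
#' @param inertia,cognitive,social PSO coefficients.
#' @param seed integer seed; run r uses `seed + r - 1`.
#' @return list of class `bg_fit_config`.
#' @export
fit_config <- function(free_parameters = NULL, bounds_factor = 100,
                       iterations = 2000, runs = 100, keep_best = 8,
                       swarm_size = 50, inertia = c(0.9, 0.4),
                       cognitive = 1.49, social = 1.49, seed = 1) {
  stopifnot(keep_best <= runs, bounds_factor > 1)
  structure(list(free_parameters = free_parameters,
                 bounds_factor = bounds_factor, iterations = iterations,
                 runs = runs, keep_best = keep_best, swarm_size = swarm_size,
                 inertia = inertia, cognitive = cognitive, social = social,
                 seed = seed), class = "bg_fit_config")
}

#' Fit free Vmax parameters by particle swarm optimization
#'
#' Minimizes the training [wssr()] over the free parameters in log space
#' within multiplicative bounds around the starting values. Each of
#' `config$runs` independent swarms is seeded differently; the `keep_best`
#' best final parameter sets (ranked by WSSR) form the fitted ensemble.
#'
#' @param model a `bg_model`.
#' @param dataset a `bg_dataset`; only `role == "train"` rows enter the
#'   objective.
#' @param config a [fit_config()]; `config$free_parameters` defaults to the
#'   model's free Vmax parameters.
#' @param params starting `bg_params` (default: the model's nominal set).
#' @param gsis a [gsis_config()].
#' @return object of class `bg_fit`: `par_sets` (list of `bg_params`, sorted
#'   by WSSR), `wssr` (sorted vector), `traces` (best-so-far per run),
#'   `free_parameters`, `config`.
#' @export
fit_pso <- function(model, dataset, config = fit_config(),
                    params = model$params, gsis = gsis_config()) {
  free <- config$free_parameters %||% vmax_names(model)
  train <- dataset[dataset$role == "train", , drop = FALSE]
  if (nrow(train) == 0) stop("dataset has no training rows")
  fn <- make_prediction_fn(model, params, train, gsis)
  pv <- as.numeric(params$values)
  idx <- match(free, names(params$values))
  if (anyNA(idx)) stop("unknown free parameter(s): ",
                       paste(free[is.na(idx)], collapse = ", "))
  objective <- function(x) {
    p <- pv; p[idx] <- x
    wssr_safe(fn(p), train)
  }
  lower <- pv[idx] / config$bounds_factor
  upper <- pv[idx] * config$bounds_factor
  results <- vector("list", config$runs)
  for (r in seq_len(config$runs)) {
    results[[r]] <- pso_minimize(objective, lower, upper,
                                 swarm_size = config$swarm_size,
                                 iterations = config$iterations,
                                 inertia = config$inertia,
                                 cognitive = config$cognitive,
                                 social = config$social,
                                 log_space = TRUE, init = pv[idx],
                                 seed = config$seed + r - 1)
  }
  vals <- vapply(results, `[[`, 0, "value")
  if (all(!is.finite(vals))) stop("all PSO runs failed to evaluate")
  ord <- order(vals)[seq_len(min(config$keep_best, config$runs))]
  par_sets <- lapply(ord, function(r) {
    p <- params
    p$values[idx] <- results[[r]]$par
    p$lower[idx] <- lower; p$upper[idx] <- upper
    p$provenance <- "fitted"
    p
  })
  structure(list(par_sets = par_sets, wssr = vals[ord],
                 traces = lapply(results[ord], `[[`, "trace"),
                 free_parameters = free, config = config),
            class = "bg_fit")
}

#' @export
print.bg_fit <- function(x, ...) {
  cat("<bg_fit> ", length(x$par_sets), " parameter sets kept; WSSR: ",
      paste(signif(x$wssr, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Evaluate an ensemble of fits against a dataset
#'
#' For every observation, computes the mean and sd of the predictions across
#' the fitted parameter sets, a Welch two-sample t statistic against the
#' observed value (using the observation sd and `n_obs` experimental
#' replicates), and a sign-agreement flag (predicted and observed fold-change
#' on the same side of 1).
#'
#' @param fit a `bg_fit` (or a list of `bg_params`).
#' @param model a `bg_model`.
#' @param dataset a `bg_dataset`.
#' @param gsis a [gsis_config()].
#' @param n_obs assumed experimental replicate count (degrees of freedom for
#'   the observation side of the t-test).
#' @param alpha significance level for the mismatch count.
#' @return list with `table` (per-observation data.frame) and `summary`
#'   (`n_significant_mismatch`, `sign_agreement`).
#' @export
evaluate_predictions <- function(fit, model, dataset, gsis = gsis_config(),
                                 n_obs = 3, alpha = 0.05) {
  par_sets <- if (inherits(fit, "bg_fit")) fit$par_sets else fit
  preds <- vapply(par_sets, function(p)
    predict_dataset(model, p, dataset, gsis), numeric(nrow(dataset)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(dataset))
  m <- rowMeans(preds)
  s <- apply(preds, 1, sd)
  n1 <- ncol(preds)
  tt <- pp <- rep(NA_real_, nrow(dataset))
  if (n1 >= 2) {
    for (i in seq_len(nrow(dataset))) {
      se2 <- s[i]^2 / n1 + dataset$sd[i]^2 / n_obs
      if (se2 > 0) {
        tt[i] <- (m[i] - dataset$fold_change[i]) / sqrt(se2)
        df <- se2^2 / (s[i]^4 / (n1^2 * (n1 - 1)) +
                       dataset$sd[i]^4 / (n_obs^2 * (n_obs - 1)))
        pp[i] <- 2 * pt(-abs(tt[i]), df)
      }
    }
  }
  sign_ok <- sign(m - 1) == sign(dataset$fold_change - 1)
  tab <- data.frame(dataset, pred_mean = m, pred_sd = s, t_stat = tt,
                    p_value = pp, sign_agreement = sign_ok)
  list(table = tab,
       summary = list(
         n_significant_mismatch = sum(pp < alpha, na.rm = TRUE),
         sign_agreement = mean(sign_ok)))
}
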