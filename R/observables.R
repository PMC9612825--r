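#' Per-species fold-changes between trajectories
#'
#' `high_vs_low` divides the state of `traj_num` by the state of `traj_den`
#' at the same protocol time; `vs_t0` divides the state of `traj_num` at
#' `time` by its own initial state (`traj_den` is ignored). References below
#' 1e-9 mM give an `undefined` flag rather than an error.
#'
#' @param traj_num,traj_den `bg_trajectory` objects.
#' @param time minutes (must lie on the output grid).
#' @param comparison `"high_vs_low"` or `"vs_t0"`.
#' @return data.frame with columns `species`, `fold_change`, `undefined`,
#'   `time`, `comparison`, `pooled` (FALSE).
#' @export
fold_change <- function(traj_num, traj_den = traj_num, time,
                        comparison = c("high_vs_low", "vs_t0")) {
  comparison <- match.arg(comparison)
  i <- traj_index(traj_num, time)
  num <- traj_num$conc[i, ]
  den <- if (comparison == "vs_t0") traj_num$conc[1, ]
         else traj_den$conc[traj_index(traj_den, time), ]
  undef <- den < 1e-9
  fc <- ifelse(undef, NA_real_, num / den)
  data.frame(species = colnames(traj_num$conc), fold_change = fc,
             undefined = undef, time = time, comparison = comparison,
             pooled = FALSE, row.names = NULL)
}

pool_key <- function(model) {
  # metabolite display name pools compartment-qualified species; only
  # intracellular (non-exchange) compartments are pooled together
  spec <- model$species[!model$species$boundary, ]
  ex <- model$compartments$id[model$compartments$exchange]
  key <- spec$name
  key[spec$compartment %in% ex] <- paste0(key[spec$compartment %in% ex], "_e")
  setNames(key, spec$id)
}

#' Compartment-pooled fold-changes
#'
#' Mass-spectrometry metabolomics measures the total metabolite pool; for a
#' metabolite present in both cytosol and mitochondria the pooled fold-change
#' is the ratio of amount-weighted sums, with the cytosol assumed three times
#' the mitochondrial volume (the volumes come from the model's compartment
#' table). Single-compartment metabolites pass through unchanged.
#'
#' @param model a `bg_model`.
#' @inheritParams fold_change
#' @return data.frame with columns `metabolite`, `fold_change`, `undefined`,
#'   `time`, `comparison`, `pooled` (TRUE).
#' @export
pooled_fold_change <- function(model, traj_num, traj_den = traj_num, time,
                               comparison = c("high_vs_low", "vs_t0")) {
  comparison <- match.arg(comparison)
  i <- traj_index(traj_num, time)
  num <- traj_num$conc[i, ]
  den <- if (comparison == "vs_t0") traj_num$conc[1, ]
         else traj_den$conc[traj_index(traj_den, time), ]
  key <- pool_key(model)[colnames(traj_num$conc)]
  vols <- compartment_volumes(model)
  w <- vols[model$species$compartment[match(colnames(traj_num$conc),
                                            model$species$id)]]
  mets <- unique(key)
  numsum <- vapply(mets, function(k) sum(w[key == k] * num[key == k]), 0)
  densum <- vapply(mets, function(k) sum(w[key == k] * den[key == k]), 0)
  undef <- densum < 1e-9
  data.frame(metabolite = mets,
             fold_change = ifelse(undef, NA_real_, numsum / densum),
             undefined = undef, time = time, comparison = comparison,
             pooled = TRUE, row.names = NULL)
}

#' Time-averaged reaction fluxes
#'
#' Trapezoidal mean of each reaction's instantaneous flux over a window of the
#' trajectory (the flux-to-insulin regression uses the average flux over the
#' stimulation period).
#'
#' @param traj a `bg_trajectory`.
#' @param window length-2 numeric `(from, to)` in minutes, or a single number
#'   meaning `(0, window)`.
#' @return named numeric vector, one mean flux per reaction (mM/min).
#' @export
time_averaged_fluxes <- function(traj, window) {
  if (length(window) == 1) window <- c(0, window)
  idx <- which(traj$times >= window[1] - 1e-9 & traj$times <= window[2] + 1e-9)
  if (length(idx) < 2) stop("window contains fewer than two grid points")
  tt <- traj$times[idx]
  f <- traj$flux[idx, , drop = FALSE]
  dt <- diff(tt)
  means <- colSums((f[-1, , drop = FALSE] + f[-length(idx), , drop = FALSE]) / 2 * dt) /
    (tt[length(tt)] - tt[1])
  setNames(means, colnames(traj$flux))
}

#' Normalize fluxes to the glucose transport flux
#'
#' Expresses each flux as a percentage of the glucose transport reaction flux
#' (glut maps to 100; reversed fluxes keep their sign).
#'
#' @param fluxes named numeric vector of fluxes.
#' @param reference id of the reference reaction (default `"glut"`).
#' @return named numeric vector of percentages.
#' @export
normalize_fluxes_to_glut <- function(fluxes, reference = "glut") {
  if (!reference %in% names(fluxes)) stop("no flux named '", reference, "'")
  ref <- fluxes[[reference]]
  if (ref == 0) stop("reference flux '", reference, "' is zero")
  100 * fluxes / ref
}

#' Latin hypercube samples of initial conditions
#'
#' Stratified uniform sampling: for each species, the `n` samples fall in `n`
#' distinct equal-width strata of its range (one per stratum), in randomized
#' order. Deterministic under a fixed seed.
#'
#' @param ranges data.frame with columns `species`, `low`, `high` (mM), or a
#'   named list of length-2 ranges.
#' @param n number of sample sets.
#' @param seed integer seed.
#' @return an `n` x species matrix with species as column names.
#' @export
lhs_initial_conditions <- function(ranges, n, seed = 1) {
  if (!is.data.frame(ranges))
    ranges <- data.frame(species = names(ranges),
                         low = vapply(ranges, `[`, 0, 1),
                         high = vapply(ranges, `[`, 0, 2))
  if (any(ranges$low <= 0) || any(ranges$low >= ranges$high))
    stop("ranges must be positive with low < high")
  stopifnot(n >= 1)
  set.seed(seed)
  out <- matrix(NA_real_, n, nrow(ranges), dimnames = list(NULL, ranges$species))
  for (j in seq_len(nrow(ranges))) {
    u <- (sample(n) - 1 + runif(n)) / n
    out[, j] <- ranges$low[j] + u * (ranges$high[j] - ranges$low[j])
  }
  out
}
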