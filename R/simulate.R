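#' Define a glucose-stimulation protocol
#'
#' A protocol is an ordered list of phases; each phase clamps the boundary
#' (extracellular / bookkeeping) species at given concentrations for a given
#' duration. Unspecified boundary species carry their previous (or default)
#' values forward.
#'
#' @param phases a data.frame with a `duration` column (minutes, > 0) and one
#'   column per boundary species to clamp (mM; `NA` = carry forward).
#' @param output_grid minutes (from protocol start) at which state and fluxes
#'   are reported; defaults to 1-minute spacing over the whole protocol.
#' @return object of class `bg_protocol`.
#' @examples
#' stimulation_protocol(data.frame(duration = c(120, 60),
#'                                 GLC_e = c(2.8, 16.7)))
#' @export
stimulation_protocol <- function(phases, output_grid = NULL) {
  stopifnot(is.data.frame(phases), "duration" %in% names(phases))
  if (any(phases$duration <= 0)) stop("phase durations must be > 0")
  total <- sum(phases$duration)
  if (is.null(output_grid)) output_grid <- seq(0, total, by = 1)
  if (any(output_grid < 0 | output_grid > total + 1e-9))
    stop("output grid outside protocol duration")
  structure(list(phases = phases, output_grid = sort(unique(output_grid)),
                 total = total), class = "bg_protocol")
}

#' @export
print.bg_protocol <- function(x, ...) {
  cat("<bg_protocol> ", nrow(x$phases), " phase(s), ", x$total, " min\n", sep = "")
  print(x$phases)
  invisible(x)
}

phase_boundaries <- function(model, protocol) {
  spec <- model$species
  bnd <- spec$id[spec$boundary]
  # extracellular dynamic species are NOT clamped; only true boundary species
  defaults <- setNames(spec$initial[match(bnd, spec$id)], bnd)
  cols <- intersect(names(protocol$phases), c(bnd))
  extra <- setdiff(names(protocol$phases), c("duration", bnd))
  if (length(extra))
    stop("protocol clamps non-boundary species: ", paste(extra, collapse = ", "))
  out <- vector("list", nrow(protocol$phases))
  cur <- defaults
  for (i in seq_len(nrow(protocol$phases))) {
    for (cn in cols) {
      v <- protocol$phases[[cn]][i]
      if (!is.na(v)) cur[cn] <- v
    }
    out[[i]] <- cur
  }
  out
}

#' Simulate the kinetic model under a stimulation protocol
#'
#' Integrates the stiff ODE system phase by phase (boundary concentrations are
#' reset instantaneously at phase switches) with an adaptive Rosenbrock(2,3)
#' method, reporting concentrations (mM) and instantaneous reaction fluxes
#' (mM/min, cytosol-referenced) on the protocol's output grid.
#'
#' Concentration excursions more negative than `-1e-9` mM force step
#' rejection; smaller ones are clamped to zero and counted (`nclamp`).
#'
#' @param model a `bg_model`.
#' @param params a `bg_params` (default: the model's nominal set).
#' @param init named initial concentrations for the dynamic species (default:
#'   the model's initial concentrations; all must be set).
#' @param protocol a `bg_protocol`.
#' @param rtol,atol relative / absolute integration tolerances.
#' @param hmax maximal step size (minutes).
#' @return object of class `bg_trajectory`: `times`, `conc` (time x species),
#'   `flux` (time x reactions), `nclamp`, `protocol`.
#' @export
simulate <- function(model, params = model$params, init = NULL, protocol,
                     rtol = 1e-8, atol = 1e-10, hmax = Inf) {
  compiled <- compile_model(model, params)
  simulate_compiled(model, compiled, as.numeric(params$values), init, protocol,
                    rtol, atol, hmax)
}

simulate_compiled <- function(model, compiled, parvec, init, protocol,
                              rtol = 1e-8, atol = 1e-10, hmax = Inf,
                              error_on_failure = TRUE) {
  dyn <- compiled$dyn_ids
  y0 <- state_vector(model, init, need = dyn)[dyn]
  bvals_by_phase <- phase_boundaries(model, protocol)
  edges <- cumsum(c(0, protocol$phases$duration))
  grid <- protocol$output_grid

  times_all <- conc_all <- flux_all <- NULL
  nclamp <- 0L
  y <- as.numeric(y0)
  for (i in seq_len(nrow(protocol$phases))) {
    t0 <- edges[i]; t1 <- edges[i + 1]
    tt <- unique(sort(c(t0, grid[grid > t0 + 1e-12 & grid <= t1 + 1e-12], t1)))
    b <- as.numeric(bvals_by_phase[[i]])
    hm <- if (is.finite(hmax)) hmax else t1 - t0
    res <- cpp_simulate(compiled, parvec, y, b, tt, rtol, atol, hm)
    status <- res$status
    if (status != 0) {
      msg <- paste0("integration failed (status ", status,
                    ") at t = ", signif(res$t_last, 6), " min")
      if (error_on_failure) stop(msg)
      return(structure(list(times = NA, failed = TRUE, message = msg),
                       class = "bg_trajectory"))
    }
    nclamp <- nclamp + res$nclamp
    keep <- tt %in% grid | (i == 1 & tt == t0)
    times_all <- c(times_all, tt[keep])
    conc_all <- rbind(conc_all, res$conc[keep, , drop = FALSE])
    flux_all <- rbind(flux_all, res$flux[keep, , drop = FALSE])
    y <- as.numeric(res$conc[length(tt), ])
  }
  dup <- duplicated(times_all)
  times_all <- times_all[!dup]
  conc_all <- conc_all[!dup, , drop = FALSE]
  flux_all <- flux_all[!dup, , drop = FALSE]
  colnames(conc_all) <- dyn
  colnames(flux_all) <- names(model$reactions)
  if (nclamp > 0)
    warning(nclamp, " tiny negative concentration excursions clamped to zero")
  structure(list(times = times_all, conc = conc_all, flux = flux_all,
                 nclamp = nclamp, failed = FALSE, protocol = protocol),
            class = "bg_trajectory")
}

#' @export
print.bg_trajectory <- function(x, ...) {
  if (isTRUE(x$failed)) { cat("<bg_trajectory> FAILED:", x$message, "\n"); return(invisible(x)) }
  cat("<bg_trajectory> ", length(x$times), " time points (",
      min(x$times), "-", max(x$times), " min), ", ncol(x$conc), " species, ",
      ncol(x$flux), " reactions\n", sep = "")
  invisible(x)
}

traj_index <- function(traj, time) {
  i <- which(abs(traj$times - time) < 1e-9)
  if (!length(i)) stop("time ", time, " not on the trajectory's output grid")
  i[1]
}

#' Simulate to steady state with a settling certificate
#'
#' Runs the model at a constant extracellular glucose level until `horizon`
#' and certifies steadiness: over the final `window` minutes, the largest
#' relative rate of change `|dC/dt| / max(C, 1e-9)` must stay below `tol`.
#' At the certified state the maximal absolute net production rate over
#' species (the infinity norm of the volume-scaled `S v`) is reported.
#'
#' @inheritParams simulate
#' @param glucose extracellular glucose (mM) clamped for the whole run.
#' @param boundary optional named overrides for other boundary species.
#' @param horizon run length in minutes (default 72 h).
#' @param window certificate window (minutes).
#' @param tol steadiness criterion on the relative rate (1/min).
#' @return list with `state` (named concentrations), `fluxes` (named),
#'   `converged`, `criterion` (worst relative rate in the window), `sv_inf`
#'   (infinity norm of net production at the final state), `trajectory`.
#' @export
steady_state <- function(model, params = model$params, init = NULL,
                         glucose = 16.7, boundary = NULL, horizon = 4320,
                         window = 60, tol = 1e-6, rtol = 1e-8, atol = 1e-10) {
  stopifnot(horizon > window)
  ph <- data.frame(duration = horizon)
  if ("GLC_e" %in% model$species$id[model$species$boundary]) ph$GLC_e <- glucose
  for (nm in names(boundary %||% c())) ph[[nm]] <- boundary[[nm]]
  prot <- stimulation_protocol(ph)
  traj <- simulate(model, params, init, prot, rtol = rtol, atol = atol)
  compiled <- compile_model(model, params)
  idx <- which(traj$times >= horizon - window - 1e-9)
  worst <- 0
  for (i in idx) {
    dC <- compiled$M %*% traj$flux[i, ]
    rel <- max(abs(dC) / pmax(traj$conc[i, ], 1e-9))
    worst <- max(worst, rel)
  }
  nf <- length(traj$times)
  sv <- compiled$M %*% traj$flux[nf, ]
  list(state = setNames(traj$conc[nf, ], colnames(traj$conc)),
       fluxes = setNames(traj$flux[nf, ], colnames(traj$flux)),
       converged = worst < tol, criterion = worst,
       sv_inf = max(abs(sv)), trajectory = traj)
}
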