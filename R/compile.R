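# Compile a bg_model + parameter names into the index structure consumed by
# the C++ kinetics core. The parameter VALUES are passed separately at call
# time, so fitting can reuse one compiled model across thousands of
# evaluations.

reference_volume <- function(model) {
  comps <- model$compartments
  ref <- comps$id[!comps$exchange]
  refc <- if ("c" %in% ref) "c" else if (length(ref)) ref[1] else comps$id[1]
  comps$relative_volume[comps$id == refc]
}

compile_model <- function(model, params = model$params) {
  spec <- model$species
  dyn <- rownames(model$S)
  bnd <- spec$id[spec$boundary]
  full_ids <- c(dyn, bnd)
  pn <- names(params$values)
  pidx <- function(nm) {
    if (is.null(nm) || is.na(nm)) return(0L)
    i <- match(nm, pn)
    if (is.na(i)) stop("unresolved parameter reference '", nm, "'")
    i
  }
  sidx <- function(ids) {
    i <- match(ids, full_ids)
    if (anyNA(i)) stop("unresolved species reference '", ids[is.na(i)][1], "'")
    as.integer(i)
  }

  vols <- compartment_volumes(model)
  vref <- reference_volume(model)
  vi <- vols[spec$compartment[match(dyn, spec$id)]]
  M <- model$S * (vref / vi)  # row-scaled: dC/dt = M %*% v

  rx <- lapply(model$reactions, function(r) {
    tpl <- TEMPLATES[[r$template]]
    p <- r$params
    ns <- length(r$substrates); np <- length(r$products)
    rev <- if (r$template == "mass_action") !is.na(p$vr) else isTRUE(tpl$rev)
    km_sub <- if (length(p$km_sub)) vapply(p$km_sub, pidx, 0L) else integer(0)
    km_prod <- if (length(p$km_prod)) vapply(p$km_prod, pidx, 0L) else integer(0)
    if (tpl$form == 2L) { # facilitated transport: one Km, both faces
      km_sub <- rep(pidx(p$km_sub[1]), 1L)
      km_prod <- rep(pidx(p$km_sub[1]), 1L)
    }
    if (tpl$form == 3L) { km_sub <- rep(0L, ns); km_prod <- rep(0L, np) }
    list(form = tpl$form, rev = as.integer(rev),
         constrained = as.integer(isTRUE(r$constrained)),
         sub_idx = sidx(names(r$substrates)),
         sub_st = as.numeric(r$substrates),
         sub_km = as.integer(km_sub),
         prod_idx = if (np) sidx(names(r$products)) else integer(0),
         prod_st = as.numeric(r$products),
         prod_km = as.integer(km_prod),
         vf = pidx(p$vf),
         vr = if (isTRUE(r$constrained)) 0L else pidx(p$vr),
         keq = pidx(p$keq),
         hill = pidx(p$hill),
         kia = pidx(p$kia), kib = pidx(p$kib), kiq = pidx(p$kiq),
         act_idx = if (is.na(r$activator)) 0L else sidx(r$activator),
         act_ka = pidx(p$act_ka),
         inh_idx = if (is.na(r$inhibitor)) 0L else sidx(r$inhibitor),
         inh_ki = pidx(p$inh_ki))
  })

  list(n_dyn = length(dyn), n_full = length(full_ids), M = M,
       reactions = unname(rx), dyn_ids = dyn, boundary_ids = bnd,
       param_names = pn, v_ref = vref)
}

state_vector <- function(model, state = NULL, need = NULL) {
  # full concentration vector [dynamic, boundary], defaults from initials
  spec <- model$species
  dyn <- rownames(model$S)
  bnd <- spec$id[spec$boundary]
  full <- setNames(spec$initial[match(c(dyn, bnd), spec$id)], c(dyn, bnd))
  if (!is.null(state)) {
    bad <- setdiff(names(state), names(full))
    if (length(bad)) stop("unknown species in state: ", paste(bad, collapse = ", "))
    full[names(state)] <- state
  }
  if (anyNA(full[need %||% character(0)]))
    stop("state incomplete: no value for ",
         paste(need[is.na(full[need])], collapse = ", "))
  full
}

#' Evaluate one reaction's rate law
#'
#' Evaluates the instantaneous rate (mM/min, referenced to the cytosolic
#' volume) of a single reaction at a given concentration state. Reversible
#' templates return the net (forward minus reverse) rate.
#'
#' @param model a `bg_model`.
#' @param reaction reaction id.
#' @param state named concentration vector (mM); species not named default to
#'   the model's initial concentrations.
#' @param params a `bg_params` (default: the model's nominal set).
#' @return scalar rate.
#' @examples
#' fx <- make_fixture_network()
#' reaction_rate(fx, "gk", c(GLC_c = 5))
#' @export
reaction_rate <- function(model, reaction, state = NULL, params = model$params) {
  r <- model$reactions[[reaction]]
  if (is.null(r)) stop("unknown reaction: ", reaction)
  need <- unique(c(names(r$substrates), names(r$products),
                   r$activator[!is.na(r$activator)], r$inhibitor[!is.na(r$inhibitor)]))
  full <- state_vector(model, state, need)
  if (any(full[need] < -1e-9))
    stop("negative concentration beyond tolerance in state: ",
         paste(need[full[need] < -1e-9], collapse = ", "))
  compiled <- compile_model(model, params)
  v <- cpp_rates(compiled, as.numeric(full), as.numeric(params$values))
  v[match(reaction, names(model$reactions))]
}

#' ODE right-hand side
#'
#' Time derivative of every dynamic species (mM/min) at a state:
#' `dC/dt = M v(C)` where `M` is the stoichiometric matrix with each row
#' scaled by (reference volume / compartment volume) so that amounts balance
#' across compartments of unequal size.
#'
#' @inheritParams reaction_rate
#' @param state named concentrations for the dynamic species (boundary species
#'   may be included to override protocol defaults).
#' @return named derivative vector over the dynamic species.
#' @export
rhs <- function(model, state = NULL, params = model$params) {
  dyn <- rownames(model$S)
  full <- state_vector(model, state, need = dyn)
  compiled <- compile_model(model, params)
  y <- as.numeric(full[dyn])
  b <- as.numeric(full[compiled$boundary_ids])
  d <- cpp_rhs(compiled, y, b, as.numeric(params$values))
  d <- as.numeric(d)
  if (any(!is.finite(d))) {
    v <- cpp_rates(compiled, as.numeric(full), as.numeric(params$values))
    bad <- names(model$reactions)[!is.finite(as.numeric(v))]
    stop("non-finite rate in reaction(s): ", paste(bad, collapse = ", "))
  }
  setNames(d, dyn)
}
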