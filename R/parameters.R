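#' Construct a kinetic parameter set
#'
#' A parameter set holds named kinetic constants (Vf/Vr in mM/min, Km in mM,
#' Keq dimensionless, plus misc constants such as Hill exponents), optional
#' box bounds and a provenance tag.
#'
#' @param values named numeric vector.
#' @param lower,upper named numeric vectors of bounds (defaults: unbounded).
#' @param kind named character vector tagging each entry as one of
#'   `"Vmax"`, `"Km"`, `"Keq"`, `"Ki"`, `"misc"`.
#' @param provenance one of `"nominal"`, `"fitted"`, `"sampled"`.
#' @return an object of class `bg_params`.
#' @export
parameter_set <- function(values, lower = NULL, upper = NULL, kind = NULL,
                          provenance = "nominal") {
  stopifnot(is.numeric(values), !is.null(names(values)))
  n <- names(values)
  if (is.null(lower)) lower <- setNames(rep(-Inf, length(values)), n)
  if (is.null(upper)) upper <- setNames(rep(Inf, length(values)), n)
  if (is.null(kind)) kind <- setNames(rep("misc", length(values)), n)
  lower <- lower[n]; upper <- upper[n]; kind <- kind[n]
  names(lower) <- names(upper) <- names(kind) <- n
  if (any(values < lower - 1e-12) || any(values > upper + 1e-12))
    stop("parameter values outside their bounds: ",
         paste(n[values < lower | values > upper], collapse = ", "))
  if (any(kind == "Vmax" & values < 0))
    stop("Vmax-class parameters must be >= 0")
  structure(list(values = values, lower = lower, upper = upper, kind = kind,
                 provenance = provenance), class = "bg_params")
}

#' @export
print.bg_params <- function(x, ...) {
  cat("<bg_params> ", length(x$values), " parameters (", x$provenance, ")\n",
      sep = "")
  k <- table(x$kind)
  cat(paste(names(k), as.integer(k), sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

parameter_set_from_definition <- function(definition) {
  pl <- definition$parameters
  if (is.null(pl) || length(pl) == 0) definition_error("definition has no parameters")
  nm <- vapply(pl, function(p) p$name, character(1))
  if (anyDuplicated(nm))
    definition_error("duplicate parameter name: ", nm[duplicated(nm)][1])
  val <- setNames(vapply(pl, function(p) as.numeric(p$value), numeric(1)), nm)
  low <- setNames(vapply(pl, function(p) as.numeric(p$low %||% -Inf), numeric(1)), nm)
  upp <- setNames(vapply(pl, function(p) as.numeric(p$high %||% Inf), numeric(1)), nm)
  kind <- setNames(vapply(pl, function(p) p$kind %||% "misc", character(1)), nm)
  parameter_set(val, low, upp, kind, provenance = "nominal")
}

#' Update parameter values
#'
#' @param params a `bg_params`.
#' @param values named numeric vector of replacements (subset allowed).
#' @param provenance new provenance tag (default: keep).
#' @return the updated `bg_params`.
#' @export
update_params <- function(params, values, provenance = params$provenance) {
  bad <- setdiff(names(values), names(params$values))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  params$values[names(values)] <- values
  params$provenance <- provenance
  params
}

#' Multiplicative fitting bounds around current values
#'
#' The fitting protocol lets each free parameter vary a fixed factor above and
#' below its initial estimate (default 100, i.e. four orders of magnitude of
#' total range, searched in log space).
#'
#' @param params a `bg_params`.
#' @param free character vector of free parameter names.
#' @param factor multiplicative half-range (> 1).
#' @return `bg_params` with bounds set on the free parameters.
#' @export
set_fit_bounds <- function(params, free, factor = 100) {
  stopifnot(factor > 1)
  bad <- setdiff(free, names(params$values))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  params$lower[free] <- params$values[free] / factor
  params$upper[free] <- params$values[free] * factor
  params
}

#' Names of the model's Vmax parameters
#'
#' @param model a `bg_model`.
#' @param free_only drop Vr entries eliminated by equilibrium constraints.
#' @return character vector of parameter names.
#' @export
vmax_names <- function(model, free_only = TRUE) {
  nm <- names(model$params$kind)[model$params$kind == "Vmax"]
  if (free_only) {
    constrained <- Filter(function(r) isTRUE(r$constrained), model$reactions)
    drop <- vapply(constrained, function(r) r$params$vr, character(1))
    nm <- setdiff(nm, drop)
  }
  nm
}

#' Constrain correlated velocity pairs through equilibrium constants
#'
#' For each reaction in `pairs`, the reverse maximal velocity is removed from
#' the free parameters and the compiled rate law uses `Vr = Vf / Keq` instead.
#' The reaction must be reversible and must reference a Keq parameter. With
#' `Keq` equal to the nominal `Vf/Vr` ratio, the constrained model reproduces
#' the unconstrained rates exactly.
#'
#' @param model a `bg_model`.
#' @param pairs reaction ids to constrain (or the data.frame returned by
#'   [detect_correlated_velocity_pairs()]).
#' @return the constrained `bg_model`.
#' @export
reparameterize_equilibrium <- function(model, pairs) {
  if (is.data.frame(pairs)) pairs <- pairs$reaction
  for (rid in pairs) {
    r <- model$reactions[[rid]]
    if (is.null(r)) stop("unknown reaction: ", rid)
    tpl <- TEMPLATES[[r$template]]
    if (!isTRUE(tpl$rev) || is.na(r$params$vr))
      stop("reaction '", rid, "' is not reversible with an explicit Vr")
    if (is.na(r$params$keq))
      definition_error("reaction '", rid,
                       "': no Keq parameter available for the constraint")
    model$reactions[[rid]]$constrained <- TRUE
  }
  model
}
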