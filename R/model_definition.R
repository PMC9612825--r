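`%||%` <- function(a, b) if (is.null(a)) b else a

# Rate-law template registry. Each template maps onto one of three compiled
# forms; the constraints say what a definition must provide.
#  - generic: reversible/irreversible Michaelis-Menten family with saturating
#    denominator (convenience-kinetics style), optional Hill exponent on the
#    first substrate, optional dead-end-complex constants (Kia/Kib/Kiq),
#    optional saturating activator and non-competitive inhibitor modifiers.
#  - fac: symmetric facilitated transport, one Km for both faces.
#  - mass: elementary mass action.
TEMPLATES <- list(
  irreversible_mm_1s = list(form = 1L, rev = FALSE, ns = 1L, np = NA),
  irreversible_mm_2s = list(form = 1L, rev = FALSE, ns = 2L, np = NA),
  reversible_uni_uni_haldane = list(form = 1L, rev = TRUE, ns = 1L, np = 1L),
  ordered_bi_bi = list(form = 1L, rev = TRUE, ns = NA, np = NA),
  facilitated_transport = list(form = 2L, rev = TRUE, ns = 1L, np = 1L),
  mass_action = list(form = 3L, rev = NA, ns = NA, np = NA),
  etc_complex = list(form = 1L, rev = FALSE, ns = 1L, np = NA)
)

definition_error <- function(...) {
  stop(structure(class = c("bg_definition_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Read a model-definition document
#'
#' The definition is a structured JSON text file with sections
#' `compartments`, `species`, `reactions` and `parameters` (plus optional
#' `notes` and `equilibrium_candidates`). [write_model_definition()] is its
#' exact inverse, so definitions round-trip.
#'
#' @param path path to a definition file.
#' @return a definition list.
#' @seealso [build_network()]
#' @export
read_model_definition <- function(path) {
  if (!file.exists(path)) definition_error("definition file not found: ", path)
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Write a model-definition document
#'
#' @param definition a definition list as returned by
#'   [read_model_definition()] or built in code.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_definition <- function(definition, path) {
  jsonlite::write_json(definition, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

as_named_int <- function(x, what, rid) {
  if (is.null(x) || length(x) == 0) return(setNames(integer(0), character(0)))
  v <- vapply(x, function(z) as.numeric(z), numeric(1))
  if (any(v != round(v)) || any(v == 0))
    definition_error("reaction '", rid, "': ", what,
                     " stoichiometric coefficients must be nonzero integers")
  setNames(as.integer(v), names(x))
}

chr_or_na <- function(x) if (is.null(x)) NA_character_ else as.character(x)

normalize_reaction <- function(r) {
  rid <- r$id %||% definition_error("reaction without an id")
  pr <- r$params %||% list()
  list(
    id = rid,
    name = r$name %||% rid,
    pathway = r$pathway %||% "other",
    template = r$template %||% definition_error("reaction '", rid, "': missing template"),
    substrates = as_named_int(r$substrates, "substrate", rid),
    products = as_named_int(r$products, "product", rid),
    activator = chr_or_na(r$modifiers$activator),
    inhibitor = chr_or_na(r$modifiers$inhibitor),
    params = list(
      vf = chr_or_na(pr$vf), vr = chr_or_na(pr$vr), keq = chr_or_na(pr$keq),
      km_sub = vapply(pr$km_sub %||% list(), chr_or_na, character(1)),
      km_prod = vapply(pr$km_prod %||% list(), chr_or_na, character(1)),
      kia = chr_or_na(pr$kia), kib = chr_or_na(pr$kib), kiq = chr_or_na(pr$kiq),
      hill = chr_or_na(pr$hill),
      act_ka = chr_or_na(pr$act_ka), inh_ki = chr_or_na(pr$inh_ki)
    )
  )
}

validate_reaction <- function(r, species_ids, param_names) {
  tpl <- TEMPLATES[[r$template]]
  if (is.null(tpl))
    definition_error("reaction '", r$id, "': unknown rate-law template '",
                     r$template, "'")
  ns <- length(r$substrates); np <- length(r$products)
  if (ns + np == 0)
    definition_error("reaction '", r$id, "': empty reaction (no substrates or products)")
  if (!is.na(tpl$ns) && ns != tpl$ns)
    definition_error("reaction '", r$id, "': template ", r$template,
                     " expects ", tpl$ns, " substrate(s), got ", ns)
  if (!is.na(tpl$np) && np != tpl$np)
    definition_error("reaction '", r$id, "': template ", r$template,
                     " expects ", tpl$np, " product(s), got ", np)
  for (sp in c(names(r$substrates), names(r$products)))
    if (!sp %in% species_ids)
      definition_error("reaction '", r$id, "': unresolved species reference '", sp, "'")
  for (m in c(r$activator, r$inhibitor))
    if (!is.na(m) && !m %in% species_ids)
      definition_error("reaction '", r$id, "': unresolved modifier species '", m, "'")
  p <- r$params
  refs <- c(p$vf, p$vr, p$keq, p$km_sub, p$km_prod, p$kia, p$kib, p$kiq,
            p$hill, p$act_ka, p$inh_ki)
  for (nm in refs[!is.na(refs)])
    if (!nm %in% param_names)
      definition_error("reaction '", r$id, "': unresolved parameter reference '", nm, "'")
  if (is.na(p$vf)) definition_error("reaction '", r$id, "': missing Vf/kf parameter")
  if (isTRUE(tpl$rev) && r$template != "facilitated_transport") {
    if (is.na(p$vr) && is.na(p$keq))
      definition_error("reaction '", r$id,
                       "': reversible template needs Vr or Keq")
  }
  if (!is.na(p$vr) && !is.na(p$keq) && isTRUE(tpl$rev)) {
    # both present is allowed in the document (Keq kept as a constant for the
    # equilibrium reparameterization); the compiled law uses Vr unless the
    # reaction is constrained.
  }
  tplform <- tpl$form
  if (tplform == 1L) {
    if (length(p$km_sub) != ns)
      definition_error("reaction '", r$id, "': need one substrate Km per substrate")
    if (length(p$km_prod) != np)
      definition_error("reaction '", r$id,
                       "': km_prod must have one entry per product (use null for absent)")
  }
  invisible(TRUE)
}

#' Build and validate a metabolic network model
#'
#' Assembles a network model from a model-definition document: validates all
#' cross references (species in reactions, parameters in rate laws, modifier
#' species), rejects duplicate identifiers and empty reactions, and builds the
#' integer stoichiometric matrix `S` with one row per compartment-qualified
#' dynamic species and one column per reaction. Boundary (clamped) species are
#' excluded from the ODE state and from `S`.
#'
#' @param definition a definition list or a path to a definition JSON file.
#' @return an object of class `bg_model` with elements `species`,
#'   `reactions`, `compartments`, `S`, `params` (the nominal
#'   [parameter_set()]) and `definition`.
#' @examples
#' model <- build_network(betacell_definition())
#' dim(model$S)
#' @export
build_network <- function(definition) {
  if (is.character(definition)) definition <- read_model_definition(definition)

  comps <- do.call(rbind, lapply(definition$compartments, function(cc)
    data.frame(id = cc$id, name = cc$name %||% cc$id,
               relative_volume = as.numeric(cc$relative_volume),
               exchange = isTRUE(cc$exchange), stringsAsFactors = FALSE)))
  if (is.null(comps) || nrow(comps) == 0)
    definition_error("definition has no compartments")
  if (anyDuplicated(comps$id))
    definition_error("duplicate compartment id: ",
                     comps$id[duplicated(comps$id)][1])
  if (any(comps$relative_volume <= 0))
    definition_error("compartment relative volumes must be strictly positive")

  spec <- do.call(rbind, lapply(definition$species, function(s)
    data.frame(id = s$id, name = s$name %||% s$id, compartment = s$compartment,
               initial = if (identical(s$initial_concentration, "sampled"))
                 NA_real_ else as.numeric(s$initial_concentration),
               boundary = isTRUE(s$boundary),
               pathway = s$pathway %||% "other", stringsAsFactors = FALSE)))
  if (is.null(spec) || nrow(spec) == 0) definition_error("definition has no species")
  if (anyDuplicated(spec$id))
    definition_error("duplicate species id: ", spec$id[duplicated(spec$id)][1])
  bad <- setdiff(spec$compartment, comps$id)
  if (length(bad))
    definition_error("species reference unknown compartment: ", bad[1])
  if (any(!is.na(spec$initial) & spec$initial < 0))
    definition_error("initial concentrations must be >= 0")

  pars <- parameter_set_from_definition(definition)

  reactions <- lapply(definition$reactions, normalize_reaction)
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(names(reactions)))
    definition_error("duplicate reaction id: ",
                     names(reactions)[duplicated(names(reactions))][1])
  for (r in reactions) validate_reaction(r, spec$id, names(pars$values))

  # transport reactions must connect exactly two compartments
  for (r in reactions) {
    cc <- unique(spec$compartment[match(c(names(r$substrates), names(r$products)),
                                        spec$id)])
    if (r$template == "facilitated_transport" && length(cc) != 2)
      definition_error("reaction '", r$id,
                       "': transport must connect exactly two compartments")
  }

  dyn <- spec$id[!spec$boundary]
  S <- matrix(0L, nrow = length(dyn), ncol = length(reactions),
              dimnames = list(dyn, names(reactions)))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    for (sp in names(r$substrates))
      if (sp %in% dyn) S[sp, j] <- S[sp, j] - r$substrates[[sp]]
    for (sp in names(r$products))
      if (sp %in% dyn) S[sp, j] <- S[sp, j] + r$products[[sp]]
  }

  orphan <- dyn[rowSums(S != 0) == 0]
  # participation in >= 1 reaction is required for dynamic species
  if (length(orphan))
    warning("dynamic species participate in no reaction: ",
            paste(orphan, collapse = ", "))

  structure(list(species = spec, reactions = reactions, compartments = comps,
                 S = S, params = pars,
                 equilibrium_candidates =
                   vapply(definition$equilibrium_candidates %||% list(),
                          as.character, character(1)),
                 definition = definition),
            class = "bg_model")
}

#' @export
print.bg_model <- function(x, ...) {
  dyn <- sum(!x$species$boundary)
  cat("<bg_model> ", dyn, " dynamic species (+",
      sum(x$species$boundary), " boundary), ",
      length(x$reactions), " reactions, ",
      nrow(x$compartments), " compartments\n", sep = "")
  pw <- pathway_counts(x)
  print(pw)
  inv <- parameter_inventory(x)
  cat("parameters: ", inv$total, " total, ", inv$vmax, " Vmax\n", sep = "")
  invisible(x)
}

#' Species and reaction counts per pathway
#'
#' @param model a `bg_model`.
#' @return a data.frame with one row per pathway tag and columns `species`
#'   (dynamic species carrying the tag) and `reactions`.
#' @export
pathway_counts <- function(model) {
  sp <- model$species[!model$species$boundary, ]
  rp <- vapply(model$reactions, `[[`, character(1), "pathway")
  tags <- sort(unique(c(sp$pathway, rp)))
  data.frame(pathway = tags,
             species = vapply(tags, function(t) sum(sp$pathway == t), integer(1)),
             reactions = vapply(tags, function(t) sum(rp == t), integer(1)),
             row.names = NULL)
}

#' Parameter inventory of a model
#'
#' Counts the parameter entries of the model's nominal parameter set by kind.
#' `free_vmax` is the number of Vmax entries that remain free parameters after
#' any equilibrium constraints applied to the model (see
#' [reparameterize_equilibrium()]).
#'
#' @param model a `bg_model`.
#' @return list with `total`, `vmax`, `km`, `keq`, `ki`, `misc`, `free_vmax`.
#' @export
parameter_inventory <- function(model) {
  kind <- model$params$kind
  constrained <- vapply(model$reactions, function(r)
    isTRUE(r$constrained), logical(1))
  dropped <- vapply(model$reactions[constrained], function(r)
    r$params$vr, character(1))
  vmax_names <- names(kind)[kind == "Vmax"]
  list(total = length(kind),
       vmax = sum(kind == "Vmax"),
       km = sum(kind == "Km"),
       keq = sum(kind == "Keq"),
       ki = sum(kind == "Ki"),
       misc = sum(!kind %in% c("Vmax", "Km", "Keq", "Ki")),
       free_vmax = length(setdiff(vmax_names, dropped)))
}
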