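#' Export a model as SBML Level 3
#'
#' Writes species, compartments, reactions (with reversibility flags,
#' stoichiometries and modifier references) and kinetic laws as MathML
#' `<ci>` parameter references wrapped in a `<csymbol>`-free rate call; the
#' kinetic law body is emitted for the Michaelis-Menten family templates and
#' omitted (structure only) for templates without a closed MathML form here.
#' Import is not supported.
#'
#' @param model a `bg_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model",
    id = gsub("[^A-Za-z0-9_]", "_", model$definition$name %||% "model"))

  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (i in seq_len(nrow(model$compartments)))
    xml2::xml_add_child(lc, "compartment",
      id = model$compartments$id[i],
      size = as.character(model$compartments$relative_volume[i]),
      constant = "true")

  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$species))) {
    s <- model$species[i, ]
    xml2::xml_add_child(ls, "species",
      id = sbml_id(s$id), name = s$name, compartment = s$compartment,
      initialConcentration = as.character(s$initial),
      boundaryCondition = tolower(as.character(s$boundary)),
      hasOnlySubstanceUnits = "false", constant = "false")
  }

  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (nm in names(model$params$values))
    xml2::xml_add_child(lp, "parameter", id = sbml_id(nm),
      value = as.character(model$params$values[[nm]]), constant = "true")

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    tpl <- TEMPLATES[[r$template]]
    rev <- isTRUE(tpl$rev) || (r$template == "mass_action" && !is.na(r$params$vr))
    rx <- xml2::xml_add_child(lr, "reaction", id = sbml_id(r$id), name = r$name,
                              reversible = tolower(as.character(rev)))
    if (length(r$substrates)) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (sp in names(r$substrates))
        xml2::xml_add_child(lre, "speciesReference", species = sbml_id(sp),
          stoichiometry = as.character(r$substrates[[sp]]), constant = "true")
    }
    if (length(r$products)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (sp in names(r$products))
        xml2::xml_add_child(lpr, "speciesReference", species = sbml_id(sp),
          stoichiometry = as.character(r$products[[sp]]), constant = "true")
    }
    mods <- c(r$activator, r$inhibitor)
    mods <- mods[!is.na(mods)]
    if (length(mods)) {
      lm <- xml2::xml_add_child(rx, "listOfModifiers")
      for (sp in mods)
        xml2::xml_add_child(lm, "modifierSpeciesReference", species = sbml_id(sp))
    }
    math <- kinetic_law_mathml(r)
    if (!is.null(math)) {
      kl <- xml2::xml_add_child(rx, "kineticLaw")
      xml2::xml_add_child(kl, xml2::read_xml(math))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

sbml_id <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[0-9]", x), paste0("_", x), x)
}

# MathML for the irreversible / reversible MM family; NULL for templates whose
# closed form is not emitted
kinetic_law_mathml <- function(r) {
  p <- r$params
  if (r$template == "irreversible_mm_1s") {
    s <- sbml_id(names(r$substrates)[1])
    sprintf(
      '<math xmlns="http://www.w3.org/1998/Math/MathML"><apply><divide/><apply><times/><ci>%s</ci><ci>%s</ci></apply><apply><plus/><ci>%s</ci><ci>%s</ci></apply></apply></math>',
      sbml_id(p$vf), s, sbml_id(p$km_sub[1]), s)
  } else if (r$template == "reversible_uni_uni_haldane" && !is.na(p$vr)) {
    s <- sbml_id(names(r$substrates)[1]); pr <- sbml_id(names(r$products)[1])
    sprintf(
      '<math xmlns="http://www.w3.org/1998/Math/MathML"><apply><divide/><apply><minus/><apply><times/><ci>%s</ci><apply><divide/><ci>%s</ci><ci>%s</ci></apply></apply><apply><times/><ci>%s</ci><apply><divide/><ci>%s</ci><ci>%s</ci></apply></apply></apply><apply><plus/><cn>1</cn><apply><divide/><ci>%s</ci><ci>%s</ci></apply><apply><divide/><ci>%s</ci><ci>%s</ci></apply></apply></apply></math>',
      sbml_id(p$vf), s, sbml_id(p$km_sub[1]), sbml_id(p$vr), pr,
      sbml_id(p$km_prod[1]), s, sbml_id(p$km_sub[1]), pr, sbml_id(p$km_prod[1]))
  } else NULL
}
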