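#' The shipped beta-cell network definition
#'
#' Path of the package's model-definition document for the full beta-cell
#' central-carbon network: 56 compartment-qualified dynamic species and 65
#' enzyme-catalyzed reactions across glycolysis (12 species / 13 reactions),
#' the pentose phosphate pathway (7/7), the TCA cycle with glutaminolysis and
#' shuttles (20/25), the polyol pathway (2/3), the electron transport chain
#' (6/4) and cofactor/energy bookkeeping reactions, with 385 kinetic
#' parameters of which 96 are maximal velocities.
#'
#' @return path to the definition JSON (pass to [build_network()] or
#'   [read_model_definition()]).
#' @export
betacell_definition <- function() {
  system.file("extdata", "betacell_model.json", package = "betaGSIS",
              mustWork = TRUE)
}

#' Build the full beta-cell network model
#'
#' Convenience wrapper: `build_network(betacell_definition())`.
#'
#' @return a `bg_model`.
#' @export
betacell_model <- function() build_network(betacell_definition())

#' Stimulation protocols of the emulated experiments
#'
#' `"spegel"`: 120 min at 2.8 mM glucose, then high glucose for `minutes`;
#' `"malmgren"`: constant glucose for 60 min; `"steady"`: constant high
#' glucose for 72 h.
#'
#' @param design protocol name.
#' @param glucose stimulated glucose level (mM).
#' @param minutes stimulation length for `"spegel"`.
#' @return a `bg_protocol`.
#' @export
betacell_protocol <- function(design = c("spegel", "malmgren", "steady"),
                              glucose = 16.7, minutes = 60) {
  design <- match.arg(design)
  switch(design,
    spegel = stimulation_protocol(
      data.frame(duration = c(120, minutes), GLC_e = c(2.8, glucose))),
    malmgren = stimulation_protocol(data.frame(duration = 60, GLC_e = glucose)),
    steady = stimulation_protocol(
      data.frame(duration = 4320, GLC_e = glucose)))
}
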