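## Dissolved-organic-carbon secretion scoring: per-metabolite maximal
## carbon-scaled production at fixed optimal growth, abundance-scaled
## intensity, and a diversity count under a relative production threshold.

#' Maximal carbon-scaled production of candidate DOC metabolites
#'
#' For each candidate metabolite, opens a secretion-only exchange if none
#' exists, takes the upper end of its auxiliary flux range at fixed
#' optimal growth, and scales it by the metabolite's carbon atom count
#' (units: mmol C/gDW/h). Metabolites are handled sequentially and
#' independently, so the resulting per-metabolite maxima form an upper
#' envelope of simultaneous secretion. Candidates absent from the network
#' are skipped with a warning.
#'
#' @param model A `metabolic_model`.
#' @param bioavailability Named non-negative uptake limits.
#' @param metabolites Character vector of candidate metabolite ids.
#' @param carbon_table Optional named vector overriding/augmenting the
#'   model's carbon coefficients (e.g. from [read_doc_candidates()]).
#' @return Named numeric vector, metabolite -> carbon-scaled maximal
#'   production (absent candidates omitted).
#' @export
doc_metabolite_fluxes <- function(model, bioavailability, metabolites,
                                  carbon_table = NULL) {
  coefs <- model$carbon_coefficient
  if (!is.null(carbon_table)) coefs[names(carbon_table)] <- carbon_table
  out <- numeric(0)
  for (met in metabolites) {
    if (!met %in% model$metabolite_ids) {
      warning("DOC candidate '", met, "' is not in the network; skipped")
      next
    }
    if (!met %in% names(coefs) || is.na(coefs[[met]])) {
      stop("no carbon atom count for DOC candidate '", met,
           "'; supply it via the model's carbon coefficients or a ",
           "carbon side-table (metabolite,carbon_atoms)")
    }
    es <- ensure_secretion_exchange(model, met)
    rng <- auxiliary_flux_range(es$model, bioavailability, es$reaction)
    out[met] <- rng[["max"]] * coefs[[met]]
  }
  out
}

#' DOC production intensity
#'
#' Sums the per-metabolite carbon-scaled maximal production fluxes and
#' scales by organism abundance, giving mmol C/h: the local intensity of
#' dissolved-organic-carbon production a grid cell could sustain.
#'
#' @param per_metabolite Named vector from [doc_metabolite_fluxes()].
#' @param abundance Organism abundance (gDW, `>= 0`).
#' @return Intensity in mmol C/h.
#' @export
doc_intensity <- function(per_metabolite, abundance) {
  if (length(abundance) != 1L || !is.finite(abundance) || abundance < 0) {
    stop("abundance must be a single non-negative number")
  }
  sum(per_metabolite) * abundance
}

#' DOC metabolite diversity count
#'
#' Counts the metabolites whose production strictly exceeds
#' `threshold_fraction` times the maximal per-metabolite production
#' (default 5%). The maximum is taken over the full candidate map
#' including each metabolite itself, so the top producer is always
#' counted when nonzero; the count is invariant under positive rescaling
#' of all productions and non-increasing in the threshold.
#'
#' @inheritParams doc_intensity
#' @param threshold_fraction Fraction of the maximal production a
#'   metabolite must strictly exceed to be counted.
#' @return Integer count.
#' @export
doc_diversity <- function(per_metabolite, threshold_fraction = 0.05) {
  if (!length(per_metabolite)) {
    warning("empty metabolite map; diversity is 0")
    return(0L)
  }
  stopifnot(threshold_fraction >= 0)
  mx <- max(per_metabolite)
  sum(per_metabolite > threshold_fraction * mx)
}
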