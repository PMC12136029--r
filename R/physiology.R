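## Physiological diagnostics derived from the bi-level optimisation:
## auxiliary flux ranges at fixed optimal growth, variable biomass
## composition in carbon equivalents, per-nutrient slacks and resource
## constraints, and the glycogen storage index.

#' Auxiliary flux range at fixed optimal growth
#'
#' The two-step bi-level procedure: (1) maximise growth under the
#' bioavailability bounds; (2) pin the biomass flux at that maximum and
#' minimise/maximise the auxiliary reaction's flux. Auxiliary metabolites
#' are handled sequentially and independently of one another. An
#' environment outside the niche yields the flagged zero-growth convention
#' `(0, 0)`.
#'
#' @param model A `metabolic_model`.
#' @param bioavailability Named non-negative vector, reaction -> maximal
#'   uptake flux (see [bioavailability_overrides()]).
#' @param aux_reaction Reaction id to range (use
#'   [add_secretion_exchange()] first for a metabolite without an export).
#' @return Numeric `c(min, max)` with attributes `growth` and
#'   `outside_niche`.
#' @export
auxiliary_flux_range <- function(model, bioavailability, aux_reaction) {
  if (!aux_reaction %in% model$reaction_ids) {
    stop("unknown reaction '", aux_reaction, "'")
  }
  ov <- bioavailability_overrides(model, bioavailability)
  g <- fba_max_biomass(model, ov, canonical = FALSE)
  if (g$status != "optimal") {
    out <- c(min = 0, max = 0)
    attr(out, "growth") <- 0
    attr(out, "outside_niche") <- TRUE
    return(out)
  }
  rng <- fva_at_optimum(model, aux_reaction, ov)
  if (inherits(rng, "fva_result")) {  # infeasible at the pin: degenerate
    out <- c(min = 0, max = 0)
    attr(out, "growth") <- 0
    attr(out, "outside_niche") <- TRUE
    return(out)
  }
  attr(rng, "growth") <- g$growth
  attr(rng, "outside_niche") <- FALSE
  rng
}

#' Carbon-equivalent component-to-biomass ratio
#'
#' The biomass reaction fixes a component's stoichiometric share `a`; an
#' export flux `x_M` on top of it makes the composition variable. The
#' total production flux of component M is `x_M + a * x_bio`, and dividing
#' by the biomass flux and scaling by the component's carbon stoichiometry
#' `c_M` gives the carbon-equivalent ratio
#' `c_M * (x_M + a * x_bio) / x_bio` (mol C per unit biomass flux) —
#' e.g. a lipid pool with 33 carbons and biomass share 0.128, or glycogen
#' with 7 carbons and no biomass share.
#'
#' @param model A `metabolic_model` carrying `carbon_coefficient` and
#'   `biomass_coefficient` entries for `component`.
#' @param growth Biomass flux `x_bio` (> 0).
#' @param component_flux Export flux `x_M` of the component.
#' @param component Component name.
#' @return The ratio, or `NA_real_` (undefined, not infinite) when
#'   `growth <= 0`.
#' @export
component_ratio <- function(model, growth, component_flux, component) {
  if (!component %in% names(model$carbon_coefficient)) {
    stop("no carbon coefficient for component '", component, "'")
  }
  if (!is.finite(growth) || growth <= 0) return(NA_real_)
  cM <- model$carbon_coefficient[[component]]
  aM <- if (component %in% names(model$biomass_coefficient))
    model$biomass_coefficient[[component]] else 0
  cM * (component_flux + aM * growth) / growth
}

#' Per-nutrient slack at maximal growth
#'
#' The slack `d_n` is the quantity of bioavailable nutrient n the organism
#' can divert to something other than growth: bioavailability minus the
#' minimum feasible uptake of n with the biomass flux pinned at its
#' maximum (a per-nutrient minimum-uptake LP, so the slack does not depend
#' on which optimal flux vector the solver happened to return).
#'
#' @inheritParams auxiliary_flux_range
#' @param method `"min-uptake"` (default; per-nutrient LP) or
#'   `"canonical"` (slack at the parsimonious canonical optimum).
#' @return Named vector of slacks `d_n >= 0` over
#'   `names(bioavailability)`, with attribute `growth`; infeasible
#'   environments propagate as an error.
#' @export
nutrient_slack <- function(model, bioavailability,
                           method = c("min-uptake", "canonical")) {
  method <- match.arg(method)
  ov <- bioavailability_overrides(model, bioavailability)
  if (method == "canonical") {
    r <- fba_max_biomass(model, ov, canonical = TRUE)
    if (r$status != "optimal") stop("environment is outside the niche; no slack defined")
    d <- vapply(names(bioavailability), function(rid)
      bioavailability[[rid]] - r$flux[[rid]], numeric(1))
    g <- r$growth
  } else {
    g <- NA_real_
    d <- vapply(names(bioavailability), function(rid) {
      rng <- fva_at_optimum(model, rid, ov)
      if (inherits(rng, "fva_result")) stop("environment is outside the niche; no slack defined")
      bioavailability[[rid]] - rng[["min"]]
    }, numeric(1))
    g <- fba_max_biomass(model, ov, canonical = FALSE)$growth
  }
  d <- pmax(d, 0)
  names(d) <- names(bioavailability)
  attr(d, "growth") <- g
  d
}

#' Resource constraints from an ensemble of slacks
#'
#' Normalises the distribution of each nutrient's slack across an ensemble
#' of environments into a 0-100% resource constraint, oriented so that the
#' smallest slack maps to 100% (the nutrient limits growth: no divertible
#' surplus) and the largest to 0%:
#' `RC_n = (max d_n - d_n) / (max d_n - min d_n) * 100`.
#' A nutrient whose slack is constant across the ensemble carries no
#' information and is flagged instead of normalised.
#'
#' @param slacks Data frame or matrix, one row per environment, one column
#'   per nutrient, entries `d_n`.
#' @param tol Absolute spread below which a slack distribution is declared
#'   degenerate.
#' @return Data frame of `RC` values in percent (columns as input;
#'   flagged nutrients are all-`NA`), with attributes `uninformative`
#'   (character vector of flagged nutrients) and `normalization`
#'   (per-nutrient min/max used, so values are reproducible and
#'   comparable).
#' @export
resource_constraint <- function(slacks, tol = 1e-9) {
  slacks <- as.data.frame(slacks)
  if (nrow(slacks) < 2L) stop("resource constraints need an ensemble of >= 2 environments")
  rc <- slacks
  uninformative <- character(0)
  norm <- list()
  for (cn in names(slacks)) {
    d <- slacks[[cn]]
    lo <- min(d); hi <- max(d)
    norm[[cn]] <- c(min = lo, max = hi)
    if (hi - lo <= tol * max(1, abs(hi))) {
      rc[[cn]] <- NA_real_
      uninformative <- c(uninformative, cn)
    } else {
      rc[[cn]] <- (hi - d) / (hi - lo) * 100
    }
  }
  attr(rc, "uninformative") <- uninformative
  attr(rc, "normalization") <- norm
  rc
}

#' Glycogen storage index over an ensemble
#'
#' The storage ratio `r_stor` is carbon routed to glycogen divided by
#' carbon fixed — the fraction of fixed carbon used to build glycogen.
#' Min-max normalising `r_stor` over the ensemble gives the storage index
#' in `[0, 1]`; entries at or above the ensemble mean index are in the
#' storage regime (growing at full potential and banking the surplus),
#' entries below it in the consumption regime, where the shortfall is read
#' as glycogen consumption supporting growth: the implied consumption is
#' `v_tilde = v_bar - v`, with `v_bar` the glycogen production that would
#' correspond to the mean index under each entry's own carbon fixation.
#' The energetic cost of storing or mobilising glycogen is not accounted
#' for.
#'
#' @param glycogen_carbon Carbon-scaled glycogen production per entry
#'   (mmol C/gDW/h).
#' @param carbon_fixed Bioavailable carbon-fixation flux per entry
#'   (mmol C/gDW/h, > 0).
#' @return Data frame with `r_stor`, `index`, `regime`
#'   (`"storage"`/`"consumption"`) and `implied_consumption` (mmol
#'   C/gDW/h; 0 in the storage regime), with attributes `mean_index` and
#'   `normalization` (`c(min, max)` of `r_stor`).
#' @export
glycogen_storage_index <- function(glycogen_carbon, carbon_fixed) {
  stopifnot(length(glycogen_carbon) == length(carbon_fixed))
  bad <- carbon_fixed <= 0 & glycogen_carbon > 0
  if (any(bad)) {
    stop("inconsistent entries: glycogen produced with no carbon fixed (",
         sum(bad), " entries)")
  }
  r_stor <- ifelse(carbon_fixed > 0, glycogen_carbon / carbon_fixed, 0)
  lo <- min(r_stor); hi <- max(r_stor)
  if (hi - lo <= 1e-12) {
    index <- rep(NA_real_, length(r_stor))
    out <- data.frame(r_stor = r_stor, index = index,
                      regime = NA_character_,
                      implied_consumption = NA_real_)
    attr(out, "mean_index") <- NA_real_
    attr(out, "normalization") <- c(min = lo, max = hi)
    attr(out, "uninformative") <- TRUE
    return(out)
  }
  index <- (r_stor - lo) / (hi - lo)
  mean_index <- mean(index)
  regime <- ifelse(index >= mean_index, "storage", "consumption")
  r_bar <- lo + mean_index * (hi - lo)
  v_bar <- r_bar * carbon_fixed
  implied <- ifelse(regime == "consumption",
                    pmax(0, v_bar - glycogen_carbon), 0)
  out <- data.frame(r_stor = r_stor, index = index, regime = regime,
                    implied_consumption = implied)
  attr(out, "mean_index") <- mean_index
  attr(out, "normalization") <- c(min = lo, max = hi)
  attr(out, "uninformative") <- FALSE
  out
}
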