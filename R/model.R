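## Constraint-based model container and structural operations.

#' @keywords internal
BIG_BOUND <- 1e6

#' Construct a constraint-based metabolic model
#'
#' A metabolic model is the steady-state constraint set `S v = 0`,
#' `lb <= v <= ub`: `S` is the stoichiometric matrix (metabolites x
#' reactions), `v` the flux vector, and the bounds encode reversibility and
#' environmental limits. One reaction is the biomass reaction whose flux is
#' the growth rate (1/h); exchange reactions connect the network to the
#' environment and each touches exactly one boundary metabolite. Infinite
#' bounds are clamped to `+-1e6` so that every flux polytope handled
#' downstream (in particular the niche projection) is bounded.
#'
#' @param S Numeric matrix, metabolites in rows, reactions in columns; must
#'   carry dimnames.
#' @param lb,ub Flux bounds (mmol/gDW/h; biomass in 1/h), recycled and
#'   matched to columns of `S`.
#' @param biomass Identifier of the biomass reaction (its lower bound must
#'   be `>= 0`).
#' @param exchanges Character vector of exchange reaction identifiers; each
#'   must have exactly one nonzero stoichiometric entry.
#' @param carbon_fixation Optional identifier of the carbon-fixation
#'   reaction (e.g. RuBisCO), bounded by the photosynthetically fixed
#'   carbon when coupling to an environment.
#' @param carbon_coef Named numeric, carbon atoms per unit of a metabolite
#'   or storage component (e.g. glycogen 7, lipid 33); all `>= 0`.
#' @param biomass_coef Named numeric, stoichiometric coefficient of a
#'   component in the biomass reaction (e.g. lipid 0.128, glycogen 0).
#' @param id Model identifier used in provenance records.
#'
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(S, lb, ub, biomass, exchanges = character(),
                            carbon_fixation = NULL,
                            carbon_coef = numeric(), biomass_coef = numeric(),
                            id = "model") {
  S <- as.matrix(S)
  if (is.null(rownames(S)) || is.null(colnames(S))) {
    stop("S must have metabolite row names and reaction column names")
  }
  rxns <- colnames(S)
  lb <- rep_len(as.numeric(lb), ncol(S))
  ub <- rep_len(as.numeric(ub), ncol(S))
  names(lb) <- names(ub) <- rxns
  lb[lb < -BIG_BOUND | !is.finite(lb)] <- -BIG_BOUND
  ub[ub > BIG_BOUND | !is.finite(ub)] <- BIG_BOUND
  m <- structure(
    list(metabolite_ids = rownames(S), reaction_ids = rxns,
         S = S, lb = lb, ub = ub,
         biomass_reaction = biomass,
         exchange_reactions = exchanges,
         carbon_fixation_reaction = carbon_fixation,
         carbon_coefficient = carbon_coef,
         biomass_coefficient = biomass_coef,
         sign_map = stats::setNames(rep(1, length(rxns)), rxns),
         id = id),
    class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate the structural invariants of a metabolic model
#'
#' Checks `lb <= ub`, a non-negative biomass lower bound, that every
#' exchange reaction touches exactly one metabolite, and non-negative
#' carbon coefficients. Called by all constructors; exported so readers can
#' re-validate after manual edits.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly; stops on violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  if (any(model$lb > model$ub)) {
    stop("bound inversion: lb > ub for ",
         paste(model$reaction_ids[model$lb > model$ub], collapse = ", "))
  }
  if (!model$biomass_reaction %in% model$reaction_ids) {
    stop("biomass reaction '", model$biomass_reaction, "' not in model")
  }
  if (model$lb[model$biomass_reaction] < 0) {
    stop("biomass reaction cannot have a negative lower bound")
  }
  bad <- setdiff(model$exchange_reactions, model$reaction_ids)
  if (length(bad)) stop("unknown exchange reactions: ", paste(bad, collapse = ", "))
  for (ex in model$exchange_reactions) {
    nz <- sum(abs(model$S[, ex]) > 0)
    if (nz != 1L) {
      stop("exchange reaction '", ex, "' touches ", nz,
           " metabolites; exactly one boundary metabolite is required")
    }
  }
  if (length(model$carbon_coefficient) && any(model$carbon_coefficient < 0)) {
    stop("carbon coefficients must be >= 0")
  }
  if (!is.null(model$carbon_fixation_reaction) &&
      !model$carbon_fixation_reaction %in% model$reaction_ids) {
    stop("carbon fixation reaction '", model$carbon_fixation_reaction,
         "' not in model")
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  ", length(x$metabolite_ids), " metabolites, ",
      length(x$reaction_ids), " reactions (",
      length(x$exchange_reactions), " exchanges)\n", sep = "")
  cat("  biomass: ", x$biomass_reaction,
      if (!is.null(x$carbon_fixation_reaction))
        paste0("; carbon fixation: ", x$carbon_fixation_reaction), "\n", sep = "")
  invisible(x)
}

#' Metabolite touched by an exchange reaction
#' @param model A `metabolic_model`.
#' @param reaction An exchange reaction identifier.
#' @return The boundary metabolite identifier.
#' @keywords internal
#' @export
exchange_metabolite <- function(model, reaction) {
  col <- model$S[, reaction]
  model$metabolite_ids[which(abs(col) > 0)]
}

#' Orient exchange reactions uptake-positive
#'
#' SBML convention writes exchanges as `metabolite -> (boundary)` so that
#' uptake is a negative flux; environmental bioavailability, in contrast, is
#' an upper bound on a non-negative uptake flux. This pass negates every
#' uptake-capable exchange column written uptake-negative (single nonzero
#' stoichiometric entry `< 0` together with a negative lower bound) and
#' mirrors its bounds, so that afterwards uptake is always a positive flux.
#' Secretion-only exchanges (lower bound `>= 0` on an exporting column) are
#' left export-positive: their production flux is already non-negative. The
#' applied signs are recorded in `sign_map` so flux vectors can be mapped
#' back to the original convention; the feasible set, and hence the growth
#' optimum, is unchanged.
#'
#' @param model A `metabolic_model`.
#' @return An equivalent, oriented `metabolic_model`.
#' @export
orient_exchanges_uptake_positive <- function(model) {
  validate_model(model)
  for (ex in model$exchange_reactions) {
    s <- model$S[, ex]
    coef <- s[abs(s) > 0]
    if (coef < 0 && model$lb[ex] < 0) {
      model$S[, ex] <- -model$S[, ex]
      old_lb <- model$lb[ex]; old_ub <- model$ub[ex]
      model$lb[ex] <- -old_ub
      model$ub[ex] <- -old_lb
      model$sign_map[ex] <- -model$sign_map[ex]
    }
  }
  validate_model(model)
  model
}

#' Add a secretion-only exchange for a metabolite
#'
#' Opens an export route (`metabolite -> boundary`, flux in `[0, cap]`) so
#' that the production of an internal component can be quantified by flux
#' variability at fixed optimal growth. The lower bound of 0 restricts the
#' model to producing the component, never consuming it from the
#' environment, and since zero flux remains feasible the growth optimum is
#' unchanged. If any exchange for the metabolite already exists the model
#' is returned unchanged with a message; calling twice is a no-op.
#'
#' @param model A `metabolic_model`.
#' @param metabolite Metabolite identifier to open an export for.
#' @param cap Upper bound on the secretion flux.
#' @return The augmented `metabolic_model`.
#' @export
add_secretion_exchange <- function(model, metabolite, cap = BIG_BOUND) {
  validate_model(model)
  if (!metabolite %in% model$metabolite_ids) {
    stop("unknown metabolite '", metabolite, "'")
  }
  has_ex <- vapply(model$exchange_reactions, function(ex)
    identical(exchange_metabolite(model, ex), metabolite), logical(1))
  if (any(has_ex)) {
    message("metabolite '", metabolite, "' already has an exchange (",
            model$exchange_reactions[has_ex][1], "); model unchanged")
    return(model)
  }
  rid <- paste0("SEC_", metabolite)
  col <- stats::setNames(numeric(length(model$metabolite_ids)), model$metabolite_ids)
  col[metabolite] <- -1
  model$S <- cbind(model$S, col)
  colnames(model$S)[ncol(model$S)] <- rid
  model$reaction_ids <- c(model$reaction_ids, rid)
  model$lb <- c(model$lb, stats::setNames(0, rid))
  model$ub <- c(model$ub, stats::setNames(min(cap, BIG_BOUND), rid))
  model$exchange_reactions <- c(model$exchange_reactions, rid)
  model$sign_map <- c(model$sign_map, stats::setNames(1, rid))
  validate_model(model)
  model
}

#' Secretion exchange reaction id for a metabolite, creating it if needed
#' @inheritParams add_secretion_exchange
#' @return List with `model` (possibly augmented) and `reaction`.
#' @keywords internal
#' @export
ensure_secretion_exchange <- function(model, metabolite, cap = BIG_BOUND) {
  if (!metabolite %in% model$metabolite_ids) {
    stop("unknown metabolite '", metabolite, "'")
  }
  has_ex <- vapply(model$exchange_reactions, function(ex)
    identical(exchange_metabolite(model, ex), metabolite), logical(1))
  if (any(has_ex)) {
    return(list(model = model, reaction = model$exchange_reactions[has_ex][1]))
  }
  model2 <- suppressMessages(add_secretion_exchange(model, metabolite, cap))
  list(model = model2, reaction = paste0("SEC_", metabolite))
}

#' Merge per-reaction bound overrides into the model's bound vectors
#' @param model A `metabolic_model`.
#' @param bound_overrides Named list `reaction -> c(lo, hi)`.
#' @return List with vectors `lb` and `ub`.
#' @keywords internal
#' @export
apply_bound_overrides <- function(model, bound_overrides = list()) {
  lb <- model$lb; ub <- model$ub
  for (rid in names(bound_overrides)) {
    if (!rid %in% model$reaction_ids) stop("unknown reaction '", rid, "' in bound overrides")
    bo <- as.numeric(bound_overrides[[rid]])
    if (length(bo) != 2L || bo[1] > bo[2]) {
      stop("bound override for '", rid, "' must be c(lo, hi) with lo <= hi")
    }
    lb[rid] <- max(bo[1], -BIG_BOUND)
    ub[rid] <- min(bo[2], BIG_BOUND)
  }
  list(lb = lb, ub = ub)
}

#' Translate a bioavailability vector into bound overrides
#'
#' Bioavailability is the upper limit of nutrient uptake: each named flux
#' becomes the bounds `c(0, value)` on the corresponding uptake exchange (or
#' on the carbon-fixation reaction for the fixed-carbon entry), in the
#' uptake-positive orientation. The organism may always take up less.
#'
#' @param model A `metabolic_model`.
#' @param bioavailability Named numeric vector, reaction id -> maximal flux
#'   (all `>= 0`).
#' @return Named list of bound overrides suitable for [fba_max_biomass()].
#' @export
bioavailability_overrides <- function(model, bioavailability) {
  if (length(bioavailability) == 0) return(list())
  if (any(bioavailability < 0)) stop("bioavailability fluxes must be >= 0")
  if (is.null(names(bioavailability)) || any(!nzchar(names(bioavailability)))) {
    stop("bioavailability must be a named vector of reaction ids")
  }
  out <- list()
  for (rid in names(bioavailability)) {
    if (!rid %in% model$reaction_ids) stop("unknown reaction '", rid, "' in bioavailability")
    ## the environment can only restrict the model's own uptake capacity
    hi <- min(model$ub[rid], as.numeric(bioavailability[[rid]]))
    out[[rid]] <- c(max(0, min(model$lb[rid], hi)), hi)
  }
  out
}
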