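## Offline coupling driver: sweep an environment grid through the
## niche/physiology/DOC computations point by point, then run the
## ensemble-level normalisation passes (resource constraints, glycogen
## storage index). The niche is projected once per model and reused across
## grid points — the efficiency rationale of the niche abstraction.

#' Run a model over an environment grid
#'
#' Per grid point: growth under the bioavailability bounds (Liebig-style
#' extraction on the projected niche), realized uptakes, per-resource
#' slacks (minimum-uptake LPs at pinned optimal growth), per-component
#' maximal production and carbon-equivalent composition ratios, and DOC
#' production/diversity for a candidate list. Afterwards two ensemble
#' passes normalise slacks into resource constraints and storage ratios
#' into the glycogen storage index over the configured scope. The sweep is
#' deterministic and point-independent: permuting grid rows permutes
#' result rows identically.
#'
#' @param model A `metabolic_model`.
#' @param grid An `environment_grid` (or plain data frame with the same
#'   columns).
#' @param nutrient_map Named character vector mapping grid columns to
#'   model reactions, e.g. `c(N = "EX_N", P = "EX_P", carbon_fixed =
#'   "CFIX")`. Every nutrient column must be mapped (configuration error
#'   before any LP is solved), except columns listed in
#'   `ignore_nutrients`.
#' @param components Components (names into the model's carbon
#'   coefficients) whose production and composition ratio to compute;
#'   defaults to all components the model declares carbon atoms for.
#' @param storage_component Component feeding the glycogen storage index
#'   (`NULL` to skip; must be among `components`).
#' @param doc_candidates Optional named vector metabolite -> carbon atoms
#'   (see [read_doc_candidates()]); enables the DOC columns.
#' @param thermal_min Optional thermal viability threshold in degC; grid
#'   points strictly colder are masked post hoc (values retained, flag
#'   set). Metabolism itself carries no temperature response.
#' @param ensemble_scope `"grid"` (normalise over the whole grid incl.
#'   all months, the default) or `"per-month"`.
#' @param ignore_nutrients Nutrient columns to skip with a warning
#'   (micronutrients the model cannot utilise, e.g. iron).
#' @param use_niche Compute growth on the projected niche (default) or by
#'   direct per-point FBA; both give identical results and the choice is
#'   recorded in the output attributes.
#' @param niche Optionally a pre-projected `niche_projection` to reuse.
#' @return A data frame of class `grid_results`, one row per grid point:
#'   coordinates, `growth`, `outside_niche`, per-resource
#'   `uptake_*`/`slack_*`/`rc_*`, per-component `prod_*`/`ratio_*`,
#'   storage index columns, DOC columns, and `masked`.
#' @export
run_grid <- function(model, grid, nutrient_map,
                     components = names(model$carbon_coefficient),
                     storage_component = intersect("glycogen", components),
                     doc_candidates = NULL,
                     thermal_min = NULL,
                     ensemble_scope = c("grid", "per-month"),
                     ignore_nutrients = c("Fe", "iron"),
                     use_niche = TRUE, niche = NULL) {
  ensemble_scope <- match.arg(ensemble_scope)
  grid <- as.data.frame(grid)
  meta_cols <- c("env_id", "lat", "lon", "depth", "month", "temperature",
                 "abundance", "designed_limitation")
  nutrient_cols <- setdiff(names(grid), meta_cols)
  skipped <- intersect(nutrient_cols, ignore_nutrients)
  if (length(skipped)) {
    warning("ignoring nutrient columns with no model counterpart: ",
            paste(skipped, collapse = ", "))
    nutrient_cols <- setdiff(nutrient_cols, skipped)
  }
  unmapped <- setdiff(nutrient_cols, names(nutrient_map))
  if (length(unmapped)) {
    stop("unmapped nutrient columns: ", paste(unmapped, collapse = ", "),
         " — every nutrient column needs an entry in nutrient_map")
  }
  nutrient_map <- nutrient_map[nutrient_cols]
  bad_r <- setdiff(unname(nutrient_map), model$reaction_ids)
  if (length(bad_r)) stop("nutrient_map targets unknown reactions: ",
                          paste(bad_r, collapse = ", "))
  if (length(storage_component) && !all(storage_component %in% components)) {
    stop("storage_component must be among the computed components")
  }

  if (use_niche && is.null(niche)) {
    niche <- project_niche(model, c(unname(nutrient_map), model$biomass_reaction))
  }

  ## pre-open secretion exchanges once so every point sees the same network
  aux_model <- model
  comp_rxn <- character(0)
  for (comp in components) {
    es <- ensure_secretion_exchange(aux_model, comp)
    aux_model <- es$model
    comp_rxn[comp] <- es$reaction
  }
  doc_models <- NULL
  if (!is.null(doc_candidates)) {
    doc_present <- intersect(names(doc_candidates), aux_model$metabolite_ids)
    for (met in doc_present) {
      es <- ensure_secretion_exchange(aux_model, met)
      aux_model <- es$model
    }
  }

  npts <- nrow(grid)
  res <- grid[, intersect(meta_cols, names(grid)), drop = FALSE]
  res$growth <- NA_real_
  res$outside_niche <- FALSE
  for (cn in nutrient_cols) {
    res[[paste0("uptake_", cn)]] <- NA_real_
    res[[paste0("slack_", cn)]] <- NA_real_
  }
  for (comp in components) {
    res[[paste0("prod_", comp)]] <- NA_real_
    res[[paste0("ratio_", comp)]] <- NA_real_
  }
  if (!is.null(doc_candidates)) {
    res$doc_carbon <- NA_real_
    res$doc_intensity <- NA_real_
    res$doc_diversity <- NA_integer_
  }

  S <- aux_model$S
  n_rx <- length(aux_model$reaction_ids)
  bio_i <- match(aux_model$biomass_reaction, aux_model$reaction_ids)

  for (i in seq_len(npts)) {
    b <- stats::setNames(as.numeric(grid[i, nutrient_cols]), unname(nutrient_map))
    if (use_niche) {
      gr <- max_biomass_on_niche(niche, b)
    } else {
      f <- fba_max_biomass(model, bioavailability_overrides(model, b),
                           canonical = FALSE)
      gr <- if (f$status == "optimal")
        list(growth = f$growth, outside_niche = FALSE)
      else list(growth = 0, outside_niche = TRUE)
    }
    res$growth[i] <- gr$growth
    res$outside_niche[i] <- gr$outside_niche
    if (gr$outside_niche) next

    ## pinned bound set on the secretion-augmented model, reused below
    bnd <- apply_bound_overrides(aux_model, bioavailability_overrides(aux_model, b))
    lb <- bnd$lb; ub <- bnd$ub
    g2 <- lp_solve(replace(numeric(n_rx), bio_i, 1), A_eq = S,
                   b_eq = rep(0, nrow(S)), lb = lb, ub = ub, maximize = TRUE)
    if (g2$status != "optimal") { res$outside_niche[i] <- TRUE; res$growth[i] <- 0; next }
    lbp <- lb; ubp <- ub
    lbp[bio_i] <- g2$value; ubp[bio_i] <- g2$value
    probe <- lp_solve(numeric(n_rx), A_eq = S, b_eq = rep(0, nrow(S)),
                      lb = lbp, ub = ubp)
    if (probe$status != "optimal") {
      eps <- EPS_FIX * max(1, abs(g2$value))
      lbp[bio_i] <- g2$value - eps; ubp[bio_i] <- min(ub[bio_i], g2$value + eps)
    }
    opt_flux <- function(rid, maximize) {
      o <- replace(numeric(n_rx), match(rid, aux_model$reaction_ids), 1)
      r <- lp_solve(o, A_eq = S, b_eq = rep(0, nrow(S)), lb = lbp, ub = ubp,
                    maximize = maximize)
      if (r$status != "optimal") NA_real_ else r$value
    }
    for (cn in nutrient_cols) {
      rid <- nutrient_map[[cn]]
      mn <- opt_flux(rid, FALSE)
      res[[paste0("uptake_", cn)]][i] <- mn
      res[[paste0("slack_", cn)]][i] <- max(0, grid[i, cn] - mn)
    }
    for (comp in components) {
      mx <- opt_flux(comp_rxn[[comp]], TRUE)
      res[[paste0("prod_", comp)]][i] <- mx
      res[[paste0("ratio_", comp)]][i] <-
        component_ratio(aux_model, gr$growth, mx, comp)
    }
    if (!is.null(doc_candidates)) {
      per_met <- doc_metabolite_fluxes(aux_model, b, names(doc_candidates),
                                       carbon_table = doc_candidates)
      res$doc_carbon[i] <- sum(per_met)
      res$doc_intensity[i] <- doc_intensity(per_met, grid$abundance[i])
      res$doc_diversity[i] <- doc_diversity(per_met)
    }
  }

  ## ensemble passes: resource constraints and storage index
  scope_key <- if (ensemble_scope == "per-month") res$month else rep(1L, npts)
  for (cn in nutrient_cols) res[[paste0("rc_", cn)]] <- NA_real_
  if (length(storage_component) == 1L) {
    res$r_stor <- NA_real_; res$storage_index <- NA_real_
    res$regime <- NA_character_; res$implied_consumption <- NA_real_
  }
  for (key in unique(scope_key)) {
    sel <- which(scope_key == key & !res$outside_niche)
    if (length(sel) >= 2L) {
      sl <- res[sel, paste0("slack_", nutrient_cols), drop = FALSE]
      names(sl) <- nutrient_cols
      rc <- resource_constraint(sl)
      for (cn in nutrient_cols) res[[paste0("rc_", cn)]][sel] <- rc[[cn]]
      if (length(storage_component) == 1L) {
        cfx_col <- if (!is.null(model$carbon_fixation_reaction))
          names(nutrient_map)[nutrient_map == model$carbon_fixation_reaction]
        else intersect("carbon_fixed", nutrient_cols)
        if (length(cfx_col) != 1L) {
          stop("cannot locate the carbon-fixed column for the storage index; ",
               "designate the model's carbon_fixation_reaction")
        }
        glyc_c <- res[[paste0("prod_", storage_component)]][sel] *
          model$carbon_coefficient[[storage_component]]
        cfix <- as.numeric(grid[sel, cfx_col])
        gsi <- glycogen_storage_index(glyc_c, cfix)
        res$r_stor[sel] <- gsi$r_stor
        res$storage_index[sel] <- gsi$index
        res$regime[sel] <- gsi$regime
        res$implied_consumption[sel] <- gsi$implied_consumption
      }
    }
  }

  if (!is.null(thermal_min)) res <- thermal_mask(res, thermal_min) else res$masked <- FALSE
  attr(res, "nutrients") <- nutrient_cols
  attr(res, "nutrient_map") <- nutrient_map
  attr(res, "ensemble_scope") <- ensemble_scope
  attr(res, "growth_engine") <- if (use_niche) "niche" else "fba"
  class(res) <- c("grid_results", "data.frame")
  res
}

#' Mask grid results outside the organism's thermal range
#'
#' Metabolic models predict growth outside an organism's thermal
#' tolerance because metabolism alone carries no temperature response;
#' this post-hoc mask flags rows whose temperature is strictly below the
#' threshold (the boundary temperature itself is viable). Values are
#' retained for inspection; only the `masked` flag is set.
#'
#' @param results A `grid_results` data frame with a `temperature` column.
#' @param thermal_min Threshold in degC (`-Inf` masks nothing).
#' @return The results with a logical `masked` column.
#' @export
thermal_mask <- function(results, thermal_min) {
  if (!"temperature" %in% names(results)) stop("results lack a temperature column")
  results$masked <- results$temperature < thermal_min
  results
}

#' Write grid results to CSV
#' @param results A `grid_results` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
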