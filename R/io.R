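## Readers and writers: JSON toy-model dialect, niche JSON, SBML L3 FBC
## (a minimal reader/writer built on xml2 — enough for flux-bounds +
## objective annotated models and round-tripping the synthetic toys), DOC
## candidate side-tables.

#' Write / read a metabolic model in the JSON toy-model dialect
#'
#' Schema: `metabolites` (id, carbon_atoms, biomass_coefficient),
#' `reactions` (id, stoichiometry map, lb, ub, is_exchange, is_biomass,
#' is_carbon_fixation) and `metadata` (name, version, orientation).
#' `read_toy_json(write_toy_json(m))` reproduces the model exactly.
#'
#' @param model A `metabolic_model`.
#' @param path File path.
#' @return `path` (write) / a `metabolic_model` (read).
#' @export
write_toy_json <- function(model, path) {
  validate_model(model)
  mets <- lapply(model$metabolite_ids, function(mid) {
    list(id = mid,
         carbon_atoms = if (mid %in% names(model$carbon_coefficient))
           model$carbon_coefficient[[mid]] else NULL,
         biomass_coefficient = if (mid %in% names(model$biomass_coefficient))
           model$biomass_coefficient[[mid]] else NULL)
  })
  rxns <- lapply(model$reaction_ids, function(rid) {
    col <- model$S[, rid]
    nz <- which(abs(col) > 0)
    list(id = rid,
         stoichiometry = as.list(stats::setNames(col[nz], model$metabolite_ids[nz])),
         lb = model$lb[[rid]], ub = model$ub[[rid]],
         is_exchange = rid %in% model$exchange_reactions,
         is_biomass = rid == model$biomass_reaction,
         is_carbon_fixation = identical(rid, model$carbon_fixation_reaction))
  })
  doc <- list(metabolites = mets, reactions = rxns,
              metadata = list(name = model$id, version = "1",
                              orientation = "uptake-positive"))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_toy_json
#' @export
read_toy_json <- function(path) {
  doc <- jsonlite::read_json(path)
  met_ids <- vapply(doc$metabolites, `[[`, character(1), "id")
  rxn_ids <- vapply(doc$reactions, `[[`, character(1), "id")
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  lb <- ub <- stats::setNames(numeric(length(rxn_ids)), rxn_ids)
  exchanges <- character(0); biomass <- NULL; cfix <- NULL
  for (rx in doc$reactions) {
    for (mid in names(rx$stoichiometry)) S[mid, rx$id] <- rx$stoichiometry[[mid]]
    lb[rx$id] <- rx$lb; ub[rx$id] <- rx$ub
    if (isTRUE(rx$is_exchange)) exchanges <- c(exchanges, rx$id)
    if (isTRUE(rx$is_biomass)) {
      if (!is.null(biomass)) stop("toy model declares more than one biomass reaction")
      biomass <- rx$id
    }
    if (isTRUE(rx$is_carbon_fixation)) cfix <- rx$id
  }
  if (is.null(biomass)) stop("toy model declares no biomass reaction")
  cc <- bc <- numeric(0)
  for (mt in doc$metabolites) {
    if (!is.null(mt$carbon_atoms)) cc[mt$id] <- mt$carbon_atoms
    if (!is.null(mt$biomass_coefficient)) bc[mt$id] <- mt$biomass_coefficient
  }
  metabolic_model(S, lb, ub, biomass = biomass, exchanges = exchanges,
                  carbon_fixation = cfix, carbon_coef = cc,
                  biomass_coef = bc,
                  id = doc$metadata$name %||% "toy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a niche projection as JSON
#'
#' Serialises reactions of interest, vertices, halfspaces, affine-hull
#' equalities, tolerance and provenance; reading restores a
#' `niche_projection` that answers membership queries identically.
#'
#' @param niche A `niche_projection`.
#' @param path File path.
#' @return `path` (write) / a `niche_projection` (read).
#' @export
write_niche_json <- function(niche, path) {
  doc <- list(reactions_of_interest = niche$reactions,
              vertices = niche$vertices,
              halfspaces = list(A = niche$A, b = niche$b),
              equalities = list(A = niche$A_eq, b = niche$b_eq),
              rank = niche$rank, basis = niche$basis,
              biomass = niche$biomass, bbox = niche$bbox,
              tolerance = list(relative = niche$tol, absolute = niche$tol_abs,
                               scale = niche$scale),
              provenance = niche$provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_niche_json
#' @export
read_niche_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(d$reactions_of_interest)
  as_mat <- function(x, ncol_default = p) {
    if (is.null(x) || length(x) == 0) return(matrix(numeric(0), 0, ncol_default))
    matrix(as.numeric(as.matrix(x)), ncol = ncol_default)
  }
  verts <- as_mat(d$vertices); colnames(verts) <- d$reactions_of_interest
  bbox <- as_mat(d$bbox); rownames(bbox) <- c("lo", "hi")
  colnames(bbox) <- d$reactions_of_interest
  structure(list(reactions = d$reactions_of_interest,
                 vertices = verts,
                 A = as_mat(d$halfspaces$A), b = as.numeric(d$halfspaces$b %||% numeric(0)),
                 A_eq = as_mat(d$equalities$A), b_eq = as.numeric(d$equalities$b %||% numeric(0)),
                 rank = d$rank, basis = as_mat(d$basis, d$rank),
                 biomass = d$biomass %||% NA_character_, bbox = bbox,
                 tol = d$tolerance$relative, tol_abs = d$tolerance$absolute,
                 scale = d$tolerance$scale,
                 provenance = d$provenance),
            class = "niche_projection")
}

#' Read a DOC candidate side-table
#'
#' Plain CSV with columns `metabolite,carbon_atoms`, standing in for a
#' curated list of dissolved-organic-carbon compounds with their carbon
#' contents.
#'
#' @param path CSV path.
#' @return Named numeric vector metabolite -> carbon atoms.
#' @export
read_doc_candidates <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("metabolite", "carbon_atoms") %in% names(d))) {
    stop("DOC candidate table needs columns metabolite,carbon_atoms")
  }
  stats::setNames(as.numeric(d$carbon_atoms), d$metabolite)
}

## ---------------------------------------------------------------- SBML ----

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Read an SBML Level 3 (FBC) model
#'
#' Minimal reader for flux-bound/objective annotated SBML: species,
#' reactions with stoichiometry, fbc flux bounds (parameter references),
#' the active fbc objective (mapped to the biomass reaction), and carbon
#' coefficients parsed from fbc chemical formulas where present (a DOC
#' side-table can supplement them). Exchange reactions are auto-detected
#' as reactions touching exactly one species; the model is returned in
#' the uptake-positive orientation.
#'
#' @param path SBML file.
#' @param carbon_table Optional named vector metabolite -> carbon atoms
#'   overriding formula-derived counts.
#' @param carbon_fixation Optional id of the carbon-fixation reaction
#'   (SBML has no standard annotation for it; e.g. `"RUBISC_h"` in
#'   published diatom models).
#' @return A `metabolic_model`.
#' @export
read_sbml <- function(path, carbon_table = NULL, carbon_fixation = NULL) {
  x <- xml2::read_xml(path)
  xml2::xml_ns_strip(x)
  params <- xml2::xml_find_all(x, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  species <- xml2::xml_find_all(x, ".//listOfSpecies/species")
  met_ids <- xml2::xml_attr(species, "id")
  formulas <- xml2::xml_attr(species, "chemicalFormula")
  rxn_nodes <- xml2::xml_find_all(x, ".//listOfReactions/reaction")
  rxn_ids <- xml2::xml_attr(rxn_nodes, "id")
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  lb <- ub <- stats::setNames(numeric(length(rxn_ids)), rxn_ids)
  for (i in seq_along(rxn_nodes)) {
    rn <- rxn_nodes[[i]]
    for (sr in xml2::xml_find_all(rn, "./listOfReactants/speciesReference")) {
      sp <- xml2::xml_attr(sr, "species")
      st <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      S[sp, i] <- S[sp, i] - (if (is.na(st)) 1 else st)
    }
    for (sr in xml2::xml_find_all(rn, "./listOfProducts/speciesReference")) {
      sp <- xml2::xml_attr(sr, "species")
      st <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      S[sp, i] <- S[sp, i] + (if (is.na(st)) 1 else st)
    }
    lref <- xml2::xml_attr(rn, "lowerFluxBound")
    uref <- xml2::xml_attr(rn, "upperFluxBound")
    lb[i] <- if (!is.na(lref) && lref %in% names(pval)) pval[[lref]] else -BIG_BOUND
    ub[i] <- if (!is.na(uref) && uref %in% names(pval)) pval[[uref]] else BIG_BOUND
  }
  objectives <- xml2::xml_find_all(
    x, ".//*[local-name()='listOfObjectives']/*[local-name()='objective']")
  if (length(objectives) == 0L) {
    stop("SBML model has no objective; candidate biomass reactions: ",
         paste(grep("bio", rxn_ids, ignore.case = TRUE, value = TRUE),
               collapse = ", "))
  }
  if (length(objectives) > 1L) stop("SBML model declares more than one objective")
  fo <- xml2::xml_find_first(objectives[[1]], ".//*[local-name()='fluxObjective']")
  biomass <- xml2::xml_attr(fo, "reaction")
  exchanges <- rxn_ids[colSums(abs(S) > 0) == 1L]
  cc <- numeric(0)
  for (i in seq_along(met_ids)) {
    f <- formulas[i]
    if (!is.na(f) && nzchar(f)) {
      mm <- regmatches(f, regexec("C([0-9]*)(?![a-z])", f, perl = TRUE))[[1]]
      if (length(mm)) cc[met_ids[i]] <- if (nzchar(mm[2])) as.numeric(mm[2]) else 1
    }
  }
  if (!is.null(carbon_table)) cc[names(carbon_table)] <- carbon_table
  if (!length(cc)) {
    warning("no chemical formulas in SBML and no carbon side-table: ",
            "DOC operations will refuse until carbon atom counts are supplied")
  }
  model <- metabolic_model(S, lb, ub, biomass = biomass, exchanges = exchanges,
                           carbon_fixation = carbon_fixation,
                           carbon_coef = cc,
                           id = xml2::xml_attr(xml2::xml_find_first(x, ".//model"), "id") %||% "sbml")
  orient_exchanges_uptake_positive(model)
}

#' Export a model as SBML Level 3 with FBC annotations
#'
#' Writes species (with chemical formulas `C<k>` for metabolites carrying
#' carbon coefficients), reactions with stoichiometry and flux-bound
#' parameters, and the biomass objective. Intended for round-trip tests
#' of the synthetic toy models, not for arbitrary curated models.
#'
#' @param model A `metabolic_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  esc <- function(s) gsub("&", "&amp;", s, fixed = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_NS, FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)),
    '    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    "    <listOfSpecies>")
  for (mid in model$metabolite_ids) {
    formula <- if (mid %in% names(model$carbon_coefficient))
      sprintf(' fbc:chemicalFormula="C%d"',
              as.integer(model$carbon_coefficient[[mid]])) else ""
    lines <- c(lines, sprintf(
      '      <species id="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"%s/>',
      esc(mid), formula))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  for (rid in model$reaction_ids) {
    lines <- c(lines,
               sprintf('      <parameter id="lb_%s" value="%.17g" constant="true"/>', esc(rid), model$lb[[rid]]),
               sprintf('      <parameter id="ub_%s" value="%.17g" constant="true"/>', esc(rid), model$ub[[rid]]))
  }
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  for (rid in model$reaction_ids) {
    col <- model$S[, rid]
    reac <- which(col < 0); prod <- which(col > 0)
    lines <- c(lines, sprintf(
      '      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="lb_%s" fbc:upperFluxBound="ub_%s">',
      esc(rid), tolower(model$lb[[rid]] < 0), esc(rid), esc(rid)))
    if (length(reac)) {
      lines <- c(lines, "        <listOfReactants>",
                 sprintf('          <speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
                         esc(model$metabolite_ids[reac]), -col[reac]),
                 "        </listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "        <listOfProducts>",
                 sprintf('          <speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
                         esc(model$metabolite_ids[prod]), col[prod]),
                 "        </listOfProducts>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines,
             "    </listOfReactions>",
             '    <fbc:listOfObjectives fbc:activeObjective="obj">',
             '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
             sprintf('        <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
                     esc(model$biomass_reaction)),
             "      </fbc:objective>",
             "    </fbc:listOfObjectives>",
             "  </model>",
             "</sbml>")
  writeLines(lines, path)
  invisible(path)
}
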