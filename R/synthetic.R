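## Synthetic fixtures with known ground truth: quota-chain toy models whose
## FBA optimum has a closed Liebig form, random feasible networks for
## fuzzing the projection against the LP oracle, and environment grids with
## designed limitation structure for parameter-recovery tests.

## Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a quota-chain toy model
#'
#' A quota chain is the smallest constraint-based model with Liebig
#' behaviour: each nutrient enters through its own uptake exchange and is
#' consumed by the biomass reaction with stoichiometry `a_n`; fixed carbon
#' enters through a carbon-fixation reaction and is consumed by biomass
#' (`carbon_per_biomass` units) and, optionally, by storage-component
#' synthesis (each storage unit costs `carbon_cost` fixed carbon and may
#' itself appear in biomass with coefficient `a`). Its FBA maximum is the
#' analytic minimum `min_n(x_n / a_n, c_fix / cpb_eff)` where `cpb_eff`
#' adds the carbon routed through biomass-bound storage.
#'
#' @param nutrients Named numeric; biomass stoichiometric coefficient per
#'   nutrient (all `> 0`).
#' @param carbon_per_biomass Fixed carbon consumed per unit biomass (`> 0`).
#' @param storage Data frame with columns `name`, `carbon_atoms`,
#'   `carbon_cost`, `biomass_coef`.
#' @param id Model identifier.
#' @return Object of class `quota_chain_spec`.
#' @export
quota_chain_spec <- function(nutrients = c(N = 1, P = 0.2),
                             carbon_per_biomass = 5,
                             storage = data.frame(name = "glycogen",
                                                  carbon_atoms = 7,
                                                  carbon_cost = 7,
                                                  biomass_coef = 0),
                             id = "TOY1") {
  if (length(nutrients) < 1 || any(nutrients <= 0)) {
    stop("nutrient biomass coefficients must be > 0")
  }
  if (carbon_per_biomass <= 0) stop("carbon_per_biomass must be > 0")
  storage <- as.data.frame(storage)
  if (nrow(storage) && any(storage$carbon_cost <= 0)) {
    stop("storage carbon cost must be > 0")
  }
  structure(list(nutrients = nutrients, carbon_per_biomass = carbon_per_biomass,
                 storage = storage, id = id),
            class = "quota_chain_spec")
}

#' Build a quota-chain metabolic model
#'
#' @param spec A [quota_chain_spec()].
#' @param uptake_cap,cfix_cap Physiological capacity bounds on nutrient
#'   uptake and carbon fixation (mmol/gDW/h); they cap growth even under
#'   replete environments and keep the niche polytope at a realistic
#'   scale.
#' @return A `metabolic_model` with uptake exchanges `EX_<nutrient>`, the
#'   carbon-fixation reaction `CFIX`, biomass reaction `BIO`, and per
#'   storage component a synthesis reaction `SYN_<name>` plus a
#'   secretion-only exchange `EX_<name>`. The closed-form optimum is
#'   available through [quota_chain_growth()].
#' @export
make_quota_chain_model <- function(spec = quota_chain_spec(), uptake_cap = 10,
                                   cfix_cap = 50) {
  stopifnot(inherits(spec, "quota_chain_spec"))
  nuts <- names(spec$nutrients)
  stor <- spec$storage
  mets <- c(nuts, "Cfix", if (nrow(stor)) stor$name)
  rxns <- c(paste0("EX_", nuts), "CFIX", "BIO",
            if (nrow(stor)) c(paste0("SYN_", stor$name), paste0("EX_", stor$name)))
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (nu in nuts) S[nu, paste0("EX_", nu)] <- 1
  S["Cfix", "CFIX"] <- 1
  S[nuts, "BIO"] <- -spec$nutrients
  S["Cfix", "BIO"] <- -spec$carbon_per_biomass
  if (nrow(stor)) {
    for (i in seq_len(nrow(stor))) {
      s <- stor$name[i]
      S["Cfix", paste0("SYN_", s)] <- -stor$carbon_cost[i]
      S[s, paste0("SYN_", s)] <- 1
      S[s, paste0("EX_", s)] <- -1
      if (stor$biomass_coef[i] > 0) S[s, "BIO"] <- -stor$biomass_coef[i]
    }
  }
  ub <- stats::setNames(rep(BIG_BOUND, length(rxns)), rxns)
  ub[paste0("EX_", nuts)] <- uptake_cap
  ub["CFIX"] <- cfix_cap
  model <- metabolic_model(
    S, lb = 0, ub = ub,
    biomass = "BIO",
    exchanges = c(paste0("EX_", nuts), if (nrow(stor)) paste0("EX_", stor$name)),
    carbon_fixation = "CFIX",
    carbon_coef = if (nrow(stor)) stats::setNames(stor$carbon_atoms, stor$name) else numeric(),
    biomass_coef = if (nrow(stor)) stats::setNames(stor$biomass_coef, stor$name) else numeric(),
    id = spec$id)
  model$quota <- list(
    nutrients = spec$nutrients,
    uptake_cap = uptake_cap, cfix_cap = cfix_cap,
    cpb_eff = spec$carbon_per_biomass +
      if (nrow(stor)) sum(stor$biomass_coef * stor$carbon_cost) else 0)
  model
}

#' The TOY1 reference model
#'
#' Two nutrients (N with biomass coefficient 1, P with 0.2), 5 fixed carbon
#' per unit biomass, and a glycogen storage component (7 carbon atoms,
#' synthesis cost 7 fixed carbon, absent from biomass). Its growth optimum
#' under bioavailability `(N, P, C)` is `min(N, P/0.2, C/5)`.
#'
#' @return A `metabolic_model`.
#' @export
toy1_model <- function() make_quota_chain_model(quota_chain_spec())

#' Closed-form Liebig growth of a quota-chain model
#'
#' @param model A model built by [make_quota_chain_model()].
#' @param bioavailability Named vector with entries `EX_<nutrient>` and
#'   `CFIX` (missing entries are treated as unlimited).
#' @return The analytic growth rate.
#' @export
quota_chain_growth <- function(model, bioavailability) {
  if (is.null(model$quota)) stop("not a quota-chain model")
  q <- model$quota
  lims <- c()
  for (nu in names(q$nutrients)) {
    key <- paste0("EX_", nu)
    avail <- if (key %in% names(bioavailability))
      min(bioavailability[[key]], q$uptake_cap) else q$uptake_cap
    lims <- c(lims, avail / q$nutrients[[nu]])
  }
  cfix <- if ("CFIX" %in% names(bioavailability))
    min(bioavailability[["CFIX"]], q$cfix_cap) else q$cfix_cap
  lims <- c(lims, cfix / q$cpb_eff)
  min(lims)
}

#' Generate a random feasible metabolic model
#'
#' Builds a sparse acyclic network by composing conversion chains from
#' uptake exchanges to the biomass reaction, so that a strictly positive
#' growth optimum at unit bioavailability is guaranteed by construction and
#' futile cycles (and hence unbounded projections) cannot occur. Intended
#' for fuzzing the niche projection against the full LP oracle.
#'
#' @param n_mets,n_rxns Network size (`n_rxns >= n_mets >= 2`); `n_rxns`
#'   counts internal reactions plus exchanges plus biomass.
#' @param seed Integer seed; the same seed yields an identical model.
#' @param n_uptakes Number of uptake exchanges (capped by `n_mets`).
#' @param uptake_bound Default upper bound on uptake fluxes.
#' @return A `metabolic_model` whose uptake exchanges are named
#'   `EX_met<i>`.
#' @export
make_random_feasible_model <- function(n_mets, n_rxns, seed,
                                       n_uptakes = 2L, uptake_bound = 10) {
  stopifnot(n_rxns >= n_mets, n_mets >= 2L)
  with_seed(seed, {
    nu <- max(2L, min(n_uptakes, n_mets - 1L))
    mets <- paste0("met", seq_len(n_mets))
    n_chain <- n_mets - nu
    n_extra <- max(0L, n_rxns - nu - n_chain - 1L)
    rxns <- c(paste0("EX_met", seq_len(nu)),
              if (n_chain > 0) paste0("R", seq_len(n_chain)),
              if (n_extra > 0) paste0("X", seq_len(n_extra)),
              "BIO")
    S <- matrix(0, n_mets, length(rxns), dimnames = list(mets, rxns))
    for (i in seq_len(nu)) S[i, i] <- 1
    ## chain: met_j produced from one earlier metabolite
    if (n_chain > 0) {
      for (k in seq_len(n_chain)) {
        j <- nu + k
        src <- sample.int(j - 1L, 1L)
        S[src, paste0("R", k)] <- -round(stats::runif(1, 0.5, 2), 2)
        S[j, paste0("R", k)] <- round(stats::runif(1, 0.5, 2), 2)
      }
    }
    ## extra parallel conversions, always earlier -> later (acyclic)
    if (n_extra > 0) {
      for (k in seq_len(n_extra)) {
        ij <- sort(sample.int(n_mets, 2L))
        S[ij[1], paste0("X", k)] <- -round(stats::runif(1, 0.5, 2), 2)
        S[ij[2], paste0("X", k)] <- round(stats::runif(1, 0.5, 2), 2)
      }
    }
    ## biomass consumes the terminal metabolite plus a random subset
    sinks <- unique(c(n_mets, sample.int(n_mets, min(2L, n_mets))))
    S[sinks, "BIO"] <- -round(stats::runif(length(sinks), 0.2, 1.5), 2)
    lb <- rep(0, length(rxns))
    ub <- rep(BIG_BOUND, length(rxns))
    names(ub) <- rxns
    ub[paste0("EX_met", seq_len(nu))] <- uptake_bound
    metabolic_model(S, lb, ub, biomass = "BIO",
                    exchanges = paste0("EX_met", seq_len(nu)),
                    id = paste0("random", seed))
  })
}

#' Specification of a synthetic environment grid
#'
#' Describes smooth latitudinal nutrient gradients, an exponentially
#' light-limited carbon-fixation profile with seasonal modulation, a
#' temperature field, an abundance field, multiplicative noise, and
#' designed limitation boxes in which a chosen nutrient is made scarce
#' relative to the organism's biomass stoichiometry (ground-truth labels
#' are stored for recovery tests).
#'
#' @param nlat,nlon,ndepth,nmonth Grid dimensions.
#' @param nutrients Named list; per nutrient a list with `base` (surface
#'   flux level) and `gradient` (relative latitudinal modulation in
#'   `[0, 1)`).
#' @param stoichiometry Named vector of biomass requirements per nutrient
#'   plus `carbon_fixed` (fixed carbon per biomass); used to enforce the
#'   designed limitation boxes.
#' @param limitation_boxes List of lists with `nutrient`, `lat` (range),
#'   `lon` (range), and optional `factor` (< 1): inside the box the
#'   nutrient's availability-to-requirement ratio is forced below `factor`
#'   times the smallest ratio among the other resources.
#' @param carbon_surface,carbon_efold,carbon_seasonal Carbon-fixation
#'   profile: surface flux, e-folding depth (m), relative seasonal
#'   amplitude.
#' @param noise_sd Relative (lognormal) noise on nutrient and carbon
#'   fields.
#' @param seed Integer seed; the same seed yields a bit-identical grid.
#' @return Object of class `synthetic_grid_spec`.
#' @export
synthetic_grid_spec <- function(nlat = 12L, nlon = 12L, ndepth = 2L, nmonth = 2L,
                                nutrients = list(N = list(base = 2.5, gradient = 0.4),
                                                 P = list(base = 0.5, gradient = 0.4)),
                                stoichiometry = c(N = 1, P = 0.2, carbon_fixed = 5),
                                limitation_boxes = list(
                                  list(nutrient = "P", lat = c(5, 30), lon = c(-60, 0)),
                                  list(nutrient = "N", lat = c(-45, -15), lon = c(60, 150))),
                                carbon_surface = 12, carbon_efold = 60,
                                carbon_seasonal = 0.3, noise_sd = 0.05, seed = 1L) {
  stopifnot(nlat >= 2, nlon >= 2, ndepth >= 1, nmonth >= 1, nmonth <= 12)
  for (nu in names(nutrients)) {
    if (nutrients[[nu]]$base < 0) stop("nutrient base levels must be >= 0")
  }
  ## reject contradictory overlapping boxes (two nutrients limiting at once)
  if (length(limitation_boxes) > 1) {
    for (i in seq_along(limitation_boxes)) {
      for (j in seq_len(i - 1L)) {
        a <- limitation_boxes[[i]]; b <- limitation_boxes[[j]]
        overlap <- a$lat[1] <= b$lat[2] && b$lat[1] <= a$lat[2] &&
          a$lon[1] <= b$lon[2] && b$lon[1] <= a$lon[2]
        if (overlap && !identical(a$nutrient, b$nutrient)) {
          stop("contradictory limitation boxes: '", a$nutrient, "' and '",
               b$nutrient, "' overlap")
        }
      }
    }
  }
  structure(list(nlat = nlat, nlon = nlon, ndepth = ndepth, nmonth = nmonth,
                 nutrients = nutrients, stoichiometry = stoichiometry,
                 limitation_boxes = limitation_boxes,
                 carbon_surface = carbon_surface, carbon_efold = carbon_efold,
                 carbon_seasonal = carbon_seasonal,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_grid_spec")
}

#' Generate a synthetic environment grid
#'
#' @param spec A [synthetic_grid_spec()].
#' @return An `environment_grid`: a data frame with one row per grid point
#'   and columns `env_id`, `lat`, `lon`, `depth`, `month`, `temperature`,
#'   `abundance`, `carbon_fixed`, one column per nutrient, and
#'   `designed_limitation` (the ground-truth limiting nutrient inside a
#'   designed box, `NA` elsewhere). The nutrient schema is stored in
#'   attribute `nutrients`.
#' @export
make_environment_grid <- function(spec = synthetic_grid_spec()) {
  stopifnot(inherits(spec, "synthetic_grid_spec"))
  with_seed(spec$seed, {
    lat <- seq(-60, 60, length.out = spec$nlat)
    lon <- seq(-170, 170, length.out = spec$nlon)
    depth <- 5 + 55 * (seq_len(spec$ndepth) - 1L)
    month <- seq_len(spec$nmonth)
    g <- expand.grid(lat = lat, lon = lon, depth = depth, month = month,
                     KEEP.OUT.ATTRS = FALSE)
    npts <- nrow(g)
    season <- cos(2 * pi * (g$month - 1) / 12)
    g$temperature <- round(28 - 0.36 * abs(g$lat) - 0.02 * g$depth +
                             2 * season * sign(g$lat + 1e-9) +
                             stats::rnorm(npts, 0, 0.3), 3)
    light <- exp(-g$depth / spec$carbon_efold) *
      (1 + spec$carbon_seasonal * season * sign(g$lat + 1e-9)) *
      (1 - 0.5 * (abs(g$lat) / 90)^2)
    g$carbon_fixed <- pmax(0, spec$carbon_surface * light *
                             exp(stats::rnorm(npts, 0, spec$noise_sd)))
    for (nu in names(spec$nutrients)) {
      p <- spec$nutrients[[nu]]
      field <- p$base * (1 + p$gradient * sin(pi * g$lat / 120)) *
        exp(stats::rnorm(npts, 0, spec$noise_sd))
      g[[nu]] <- pmax(0, field)
    }
    ## designed limitation boxes: force the labeled nutrient's
    ## availability-to-requirement ratio strictly below all others
    g$designed_limitation <- NA_character_
    st <- spec$stoichiometry
    resources <- c(names(spec$nutrients), "carbon_fixed")
    for (box in spec$limitation_boxes) {
      fac <- if (is.null(box$factor)) 0.5 else box$factor
      inside <- g$lat >= box$lat[1] & g$lat <= box$lat[2] &
        g$lon >= box$lon[1] & g$lon <= box$lon[2]
      if (!any(inside)) next
      others <- setdiff(resources, box$nutrient)
      ratio_other <- do.call(pmin, lapply(others, function(r) g[[r]][inside] / st[[r]]))
      g[[box$nutrient]][inside] <- fac * ratio_other * st[[box$nutrient]]
      g$designed_limitation[inside] <- box$nutrient
    }
    g$abundance <- pmax(0, 10 * exp(-g$depth / 120) *
                          (1 - 0.4 * (abs(g$lat) / 90)) *
                          exp(stats::rnorm(npts, 0, spec$noise_sd)))
    num <- setdiff(names(g), c("month", "designed_limitation"))
    for (cn in num) g[[cn]] <- round(g[[cn]], 6)
    g <- cbind(env_id = seq_len(npts), g)
    g <- g[, c("env_id", "lat", "lon", "depth", "month", "temperature",
               "abundance", "carbon_fixed", names(spec$nutrients),
               "designed_limitation")]
    structure(g, class = c("environment_grid", "data.frame"),
              nutrients = names(spec$nutrients), seed = spec$seed)
  })
}

#' Write / read an environment grid as CSV
#'
#' The CSV schema is `env_id, lat, lon, depth, month, temperature,
#' abundance, carbon_fixed, <one column per nutrient>,
#' designed_limitation`. Writing then reading restores the grid exactly;
#' the same spec and seed always produce identical file bytes.
#'
#' @param grid An `environment_grid`.
#' @param path File path.
#' @return `path` (write) or an `environment_grid` (read).
#' @export
write_environment_csv <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_environment_csv
#' @export
read_environment_csv <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("env_id", "lat", "lon", "depth", "month", "temperature",
            "abundance", "carbon_fixed")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("environment CSV lacks columns: ", paste(miss, collapse = ", "))
  if (!"designed_limitation" %in% names(g)) g$designed_limitation <- NA_character_
  g$designed_limitation[g$designed_limitation %in% ""] <- NA_character_
  nuts <- setdiff(names(g), c(need, "designed_limitation"))
  structure(g, class = c("environment_grid", "data.frame"), nutrients = nuts)
}
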