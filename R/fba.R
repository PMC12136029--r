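## Flux balance analysis and flux variability at a fixed optimum: the
## direct, full-model LP oracle against which the niche abstraction is
## validated.

EPS_FIX <- 1e-6  # relative tolerance when pinning a flux to its optimum

#' Maximise growth by flux balance analysis
#'
#' Solves `max v_bio` subject to `S v = 0`, `lb <= v <= ub` (with optional
#' per-reaction overrides, typically environmental bioavailability bounds).
#' The reported flux vector is canonicalised parsimoniously: among all
#' optima, the one minimising the total absolute flux is returned, which
#' makes results deterministic and reproducible under degenerate optima.
#'
#' @param model A `metabolic_model`.
#' @param bound_overrides Named list `reaction -> c(lo, hi)`; see
#'   [bioavailability_overrides()].
#' @param canonical Logical; run the parsimonious secondary minimisation.
#'   Disable when only the optimal growth value is needed.
#'
#' @return A list of class `fba_result`: `status` (`"optimal"` or
#'   `"infeasible"`), `growth` (`NA` when infeasible — a "no growth state"
#'   is distinct from growth 0), and `flux` (named vector over all
#'   reactions). An unbounded biomass flux is an error naming the unbounded
#'   reaction.
#' @export
fba_max_biomass <- function(model, bound_overrides = list(), canonical = TRUE) {
  bnd <- apply_bound_overrides(model, bound_overrides)
  n <- length(model$reaction_ids)
  obj <- numeric(n)
  bi <- match(model$biomass_reaction, model$reaction_ids)
  obj[bi] <- 1
  r <- lp_solve(obj, A_eq = model$S, b_eq = rep(0, nrow(model$S)),
                lb = bnd$lb, ub = bnd$ub, maximize = TRUE)
  if (r$status == "infeasible") {
    return(structure(list(status = "infeasible", growth = NA_real_, flux = NULL),
                     class = "fba_result"))
  }
  if (r$status == "unbounded") {
    dir <- if (is.na(r$unbounded_var)) "<slack>" else model$reaction_ids[r$unbounded_var]
    stop("biomass flux is unbounded (unbounded direction involves reaction '",
         dir, "')")
  }
  growth <- r$value
  flux <- r$x
  if (canonical) {
    flux <- pfba_canonical_flux(model, bnd, growth)
  }
  names(flux) <- model$reaction_ids
  structure(list(status = "optimal", growth = growth, flux = flux),
            class = "fba_result")
}

#' @export
print.fba_result <- function(x, ...) {
  if (x$status == "optimal") {
    cat("<fba_result> growth =", format(x$growth, digits = 8), "1/h\n")
  } else {
    cat("<fba_result> infeasible (no growth state)\n")
  }
  invisible(x)
}

## Parsimonious canonicalisation: min sum(|v|) subject to S v = 0, bounds,
## and biomass pinned at its optimum (within EPS_FIX relative).
pfba_canonical_flux <- function(model, bnd, growth) {
  n <- length(model$reaction_ids)
  bi <- match(model$biomass_reaction, model$reaction_ids)
  ## variables (v, t), minimise sum(t), t_j >= |v_j|
  obj <- c(numeric(n), rep(1, n))
  A_eq <- cbind(model$S, matrix(0, nrow(model$S), n))
  A_in <- rbind(cbind(diag(n), -diag(n)),    #  v - t <= 0
                cbind(-diag(n), -diag(n)))   # -v - t <= 0
  solve_pinned <- function(eps) {
    lb <- bnd$lb; ub <- bnd$ub
    lb[bi] <- max(lb[bi], growth - eps)
    ub[bi] <- min(ub[bi], growth + eps)
    lp_solve(obj, A_eq = A_eq, b_eq = rep(0, nrow(model$S)),
             A_in = A_in, b_in = rep(0, 2 * n),
             lb = c(lb, rep(0, n)), ub = c(ub, rep(Inf, n)),
             maximize = FALSE)
  }
  r <- solve_pinned(0)  # exact pin first; relax by eps_fix if rounding bites
  if (r$status != "optimal") r <- solve_pinned(EPS_FIX * max(1, abs(growth)))
  if (r$status != "optimal") stop("parsimonious canonicalisation failed: ", r$status)
  r$x[seq_len(n)]
}

#' Flux variability of one reaction at fixed optimal growth
#'
#' The brute-force bi-level oracle: first maximise biomass, then pin the
#' biomass flux at its maximum (within a relative tolerance of 1e-6) and
#' minimise/maximise the flux of `reaction`.
#'
#' @inheritParams fba_max_biomass
#' @param reaction Reaction identifier to range.
#' @param pin_biomass Logical; drop the biomass pin to obtain plain flux
#'   variability instead.
#' @return Numeric `c(min, max)`, or an `fba_result`-style infeasible
#'   signal when the environment admits no feasible state.
#' @export
fva_at_optimum <- function(model, reaction, bound_overrides = list(),
                           pin_biomass = TRUE) {
  if (!reaction %in% model$reaction_ids) stop("unknown reaction '", reaction, "'")
  bnd <- apply_bound_overrides(model, bound_overrides)
  n <- length(model$reaction_ids)
  bi <- match(model$biomass_reaction, model$reaction_ids)
  lb <- bnd$lb; ub <- bnd$ub
  if (pin_biomass) {
    step1 <- lp_solve(replace(numeric(n), bi, 1), A_eq = model$S,
                      b_eq = rep(0, nrow(model$S)), lb = lb, ub = ub,
                      maximize = TRUE)
    if (step1$status == "infeasible") {
      return(structure(list(status = "infeasible", range = NULL), class = "fva_result"))
    }
    if (step1$status != "optimal") stop("biomass LP ", step1$status)
    g <- step1$value
    ## exact pin; relax by the relative fixing tolerance if rounding bites
    probe <- lp_solve(numeric(n), A_eq = model$S, b_eq = rep(0, nrow(model$S)),
                      lb = replace(lb, bi, g), ub = replace(pmin(ub, Inf), bi, g))
    eps <- if (probe$status == "optimal") 0 else EPS_FIX * max(1, abs(g))
    lb[bi] <- max(lb[bi], g - eps)
    ub[bi] <- min(ub[bi], g + eps)
  }
  obj <- replace(numeric(n), match(reaction, model$reaction_ids), 1)
  lo <- lp_solve(obj, A_eq = model$S, b_eq = rep(0, nrow(model$S)),
                 lb = lb, ub = ub, maximize = FALSE)
  hi <- lp_solve(obj, A_eq = model$S, b_eq = rep(0, nrow(model$S)),
                 lb = lb, ub = ub, maximize = TRUE)
  if (lo$status != "optimal" || hi$status != "optimal") {
    if (lo$status == "infeasible" || hi$status == "infeasible") {
      return(structure(list(status = "infeasible", range = NULL), class = "fva_result"))
    }
    stop("flux variability LP ", lo$status, "/", hi$status)
  }
  rng <- c(min = lo$value, max = hi$value)
  if (rng[1] > rng[2]) rng <- rev(rng)  # guard tol-level inversion
  rng
}

#' Check the steady-state mass balance of a flux vector
#' @param model A `metabolic_model`.
#' @param flux Named (or model-ordered) flux vector.
#' @param tol Relative tolerance.
#' @return Logical.
#' @export
is_mass_balanced <- function(model, flux, tol = 1e-6) {
  if (!is.null(names(flux))) flux <- flux[model$reaction_ids]
  resid <- max(abs(model$S %*% flux))
  resid <= tol * max(1, max(abs(flux)))
}
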