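## The metabolic niche: projection of the steady-state flux polytope onto
## the reactions of interest (nutrient exchanges, carbon fixation, biomass),
## and growth extraction on the projected polytope under bioavailability
## bounds.

#' Project the flux polytope onto reactions of interest
#'
#' Computes the metabolic niche: the exact projection of
#' `{v : S v = 0, lb <= v <= ub}` onto the coordinates of
#' `reactions_of_interest`, as both a vertex set and a halfspace system.
#' The construction is support-function refinement: seed the vertex set
#' with lexicographically purified support points along the positive and
#' negative coordinate axes, build the convex hull, then solve one support
#' LP over the full polytope per hull facet and insert every support point
#' that exceeds its facet offset by more than the tolerance; repeat to
#' fixpoint. Because each purified support point is an extreme point of the
#' projection, the loop terminates at the exact projection after finitely
#' many rounds. Rank-deficient (thin) projections are detected and stored
#' with an explicit affine-hull basis and equality constraints.
#'
#' @param model A `metabolic_model`.
#' @param reactions_of_interest Character vector of 1-6 reaction ids
#'   (typically nutrient uptake exchanges, the carbon-fixation reaction and
#'   the biomass reaction).
#' @param tol Relative geometric tolerance (fraction of the projection
#'   diameter).
#' @param max_rounds Refinement round cap (safety net).
#' @return An object of class `niche_projection` with elements
#'   `reactions`, `vertices` (matrix, one vertex per row, columns named by
#'   reaction), `A`, `b` (halfspaces `A x <= b`), `A_eq`, `b_eq`
#'   (affine-hull equalities, possibly empty), `biomass` (id or `NA`),
#'   `bbox`, `tol_abs`, and `provenance`.
#' @export
project_niche <- function(model, reactions_of_interest, tol = 1e-6,
                          max_rounds = 60L) {
  validate_model(model)
  p <- length(reactions_of_interest)
  if (p < 1L) stop("at least one reaction of interest is required")
  if (p > 6L) stop("projections with more than 6 reactions of interest are not supported")
  missing_r <- setdiff(reactions_of_interest, model$reaction_ids)
  if (length(missing_r)) stop("unknown reactions: ", paste(missing_r, collapse = ", "))
  idx <- match(reactions_of_interest, model$reaction_ids)

  ## seed with +-axis support points
  pts <- NULL
  for (j in seq_len(p)) {
    for (sgn in c(1, -1)) {
      u <- numeric(p); u[j] <- sgn
      sp <- support_point(model, idx, u)
      pts <- rbind(pts, sp$x)
    }
  }
  scale <- max(stats::dist(pts), 1e-9)
  atol <- tol * scale
  pts <- dedupe_points(pts, atol)

  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    if (round_i > max_rounds) stop("projection did not converge in ", max_rounds, " rounds")
    hull <- convex_hull_points(pts, atol)
    added <- FALSE
    ## verify thin directions really are thin; widen the point set if not
    if (hull$rank < p && nrow(hull$A_eq)) {
      for (i in seq_len(nrow(hull$A_eq))) {
        for (sgn in c(1, -1)) {
          sp <- support_point(model, idx, sgn * hull$A_eq[i, ])
          if (sgn * sum(hull$A_eq[i, ] * sp$x) > sgn * hull$b_eq[i] + atol) {
            pts <- rbind(pts, sp$x); added <- TRUE
          }
        }
      }
    }
    ## per-facet support LPs
    if (!added && nrow(hull$A)) {
      for (i in seq_len(nrow(hull$A))) {
        sp <- support_point(model, idx, hull$A[i, ])
        if (sp$value > hull$b[i] + atol) {
          pts <- rbind(pts, sp$x); added <- TRUE
        }
      }
    }
    if (!added) break
    pts <- dedupe_points(pts, atol)
  }

  verts <- hull$vertices
  colnames(verts) <- reactions_of_interest
  biomass <- if (model$biomass_reaction %in% reactions_of_interest)
    model$biomass_reaction else NA_character_
  bbox <- rbind(lo = apply(verts, 2, min), hi = apply(verts, 2, max))
  structure(list(reactions = reactions_of_interest,
                 vertices = verts,
                 A = hull$A, b = hull$b,
                 A_eq = hull$A_eq, b_eq = hull$b_eq,
                 rank = hull$rank, basis = hull$basis,
                 biomass = biomass, bbox = bbox,
                 tol = tol, tol_abs = atol, scale = scale,
                 provenance = list(model = model$id, tol = tol,
                                   algorithm = "support-refinement",
                                   rounds = round_i)),
            class = "niche_projection")
}

#' @export
print.niche_projection <- function(x, ...) {
  cat("<niche_projection> over (", paste(x$reactions, collapse = ", "), ")\n", sep = "")
  cat("  ", nrow(x$vertices), " vertices, ", nrow(x$A), " facets, rank ",
      x$rank, "/", length(x$reactions), "\n", sep = "")
  invisible(x)
}

## Lexicographically purified support point: maximise u.x over the
## projection, then break ties by maximising each coordinate in turn, so
## that the result is a uniquely determined extreme point of the projection.
support_point <- function(model, idx, u) {
  n <- length(model$reaction_ids)
  obj <- numeric(n); obj[idx] <- u
  A_extra <- NULL; b_extra <- NULL
  r <- lp_solve(obj, A_eq = model$S, b_eq = rep(0, nrow(model$S)),
                lb = model$lb, ub = model$ub, maximize = TRUE)
  if (r$status == "infeasible") stop("flux polytope is empty")
  if (r$status == "unbounded") stop("unbounded support direction in projection")
  val <- r$value
  A_extra <- matrix(obj, 1); b_extra <- val
  for (j in seq_along(idx)) {
    ej <- numeric(n); ej[idx[j]] <- 1
    rj <- lp_solve(ej, A_eq = rbind(model$S, A_extra),
                   b_eq = c(rep(0, nrow(model$S)), b_extra),
                   lb = model$lb, ub = model$ub, maximize = TRUE)
    if (rj$status != "optimal") stop("lexicographic purification failed: ", rj$status)
    A_extra <- rbind(A_extra, ej); b_extra <- c(b_extra, rj$value)
  }
  list(x = rj$x[idx], value = val, full = rj$x)
}

#' Test membership of a point in a niche projection
#'
#' A point belongs to the niche iff it satisfies every stored halfspace and
#' every affine-hull equality within the construction tolerance.
#'
#' @param niche A `niche_projection`.
#' @param point Numeric vector of the niche's dimension.
#' @param tol_abs Absolute tolerance; defaults to the niche's own.
#' @return Logical.
#' @export
niche_membership <- function(niche, point, tol_abs = niche$tol_abs) {
  point <- as.numeric(point)
  if (length(point) != length(niche$reactions)) {
    stop("point has dimension ", length(point), ", niche has ",
         length(niche$reactions))
  }
  ok_eq <- !nrow(niche$A_eq) ||
    all(abs(niche$A_eq %*% point - niche$b_eq) <= tol_abs)
  ok_in <- !nrow(niche$A) ||
    all(niche$A %*% point - niche$b <= tol_abs)
  ok_eq && ok_in
}

#' Maximal growth on the niche under bioavailability bounds
#'
#' Solves the small LP `max x_bio` subject to the niche halfspaces and
#' `0 <= x_env <= x_env_b`: bioavailability is the upper limit of uptake,
#' not a fixed uptake. When the environment is incompatible with the niche
#' the growth rate is reported as 0 with an outside-niche flag. The
#' realized uptake is canonicalised by a secondary LP minimising total
#' uptake at the fixed optimal growth.
#'
#' @param niche A `niche_projection` whose reactions include the biomass
#'   reaction.
#' @param bioavailability Named non-negative vector over (a subset of) the
#'   non-biomass niche reactions.
#' @return List with `growth`, `realized_uptake` (named vector over the
#'   niche's non-biomass reactions), and `outside_niche` flag.
#' @export
max_biomass_on_niche <- function(niche, bioavailability) {
  if (is.na(niche$biomass)) stop("niche does not include the biomass reaction")
  if (any(bioavailability < 0)) stop("bioavailability fluxes must be >= 0")
  extra <- setdiff(names(bioavailability), niche$reactions)
  if (length(extra)) stop("bioavailability names outside the niche: ",
                          paste(extra, collapse = ", "))
  if (niche$biomass %in% names(bioavailability)) {
    stop("bioavailability cannot constrain the biomass reaction")
  }
  p <- length(niche$reactions)
  bi <- match(niche$biomass, niche$reactions)
  lb <- niche$bbox["lo", ]; ub <- niche$bbox["hi", ]
  for (rid in names(bioavailability)) {
    j <- match(rid, niche$reactions)
    lb[j] <- 0
    ub[j] <- min(ub[j], bioavailability[[rid]])
  }
  lb[bi] <- max(0, lb[bi])
  if (any(lb > ub + niche$tol_abs)) {
    return(list(growth = 0, realized_uptake = NULL, outside_niche = TRUE))
  }
  lb <- pmin(lb, ub)
  obj <- numeric(p); obj[bi] <- 1
  A_in <- if (nrow(niche$A)) niche$A else NULL
  b_in <- if (nrow(niche$A)) niche$b + niche$tol_abs * 0 else NULL
  A_eq <- if (nrow(niche$A_eq)) niche$A_eq else NULL
  b_eq <- if (nrow(niche$A_eq)) niche$b_eq else NULL
  r <- lp_solve(obj, A_eq = A_eq, b_eq = b_eq, A_in = A_in, b_in = b_in,
                lb = lb, ub = ub, maximize = TRUE)
  if (r$status != "optimal") {
    return(list(growth = 0, realized_uptake = NULL, outside_niche = TRUE))
  }
  g <- r$value
  ## canonical realized uptake: minimal total uptake at the optimum
  env_idx <- setdiff(seq_len(p), bi)
  obj2 <- numeric(p); obj2[env_idx] <- 1
  solve_pinned <- function(eps) {
    lb2 <- lb; ub2 <- ub
    lb2[bi] <- max(lb2[bi], g - eps); ub2[bi] <- min(ub2[bi], g + eps)
    lp_solve(obj2, A_eq = A_eq, b_eq = b_eq, A_in = A_in, b_in = b_in,
             lb = lb2, ub = ub2, maximize = FALSE)
  }
  r2 <- solve_pinned(0)
  if (r2$status != "optimal") r2 <- solve_pinned(EPS_FIX * max(1, abs(g)))
  x <- if (r2$status == "optimal") r2$x else r$x
  realized <- stats::setNames(x[env_idx], niche$reactions[env_idx])
  list(growth = g, realized_uptake = realized, outside_niche = FALSE)
}

#' Lift a niche point to a complete feasible flux vector
#'
#' Finds a full flux vector, feasible for the model, whose restriction to
#' the niche's reactions equals the given point within tolerance; used as a
#' feasibility witness that projected vertices are genuine. The lift is
#' canonicalised by minimising the total absolute flux.
#'
#' @param model The `metabolic_model` the niche was projected from.
#' @param niche A `niche_projection`.
#' @param point Niche point (vector of the niche's dimension).
#' @return Named full flux vector.
#' @export
lift_to_full_flux <- function(model, niche, point) {
  point <- as.numeric(point)
  if (!niche_membership(niche, point)) {
    stop("point is not a member of the niche; cannot lift")
  }
  idx <- match(niche$reactions, model$reaction_ids)
  atol <- max(niche$tol_abs, 1e-9)
  n <- length(model$reaction_ids)
  lb <- model$lb; ub <- model$ub
  lb[idx] <- pmax(lb[idx], point - atol)
  ub[idx] <- pmin(ub[idx], point + atol)
  ## minimise sum |v| for determinism
  obj <- c(numeric(n), rep(1, n))
  A_eq <- cbind(model$S, matrix(0, nrow(model$S), n))
  A_in <- rbind(cbind(diag(n), -diag(n)), cbind(-diag(n), -diag(n)))
  r <- lp_solve(obj, A_eq = A_eq, b_eq = rep(0, nrow(model$S)),
                A_in = A_in, b_in = rep(0, 2 * n),
                lb = c(lb, rep(0, n)), ub = c(ub, rep(Inf, n)))
  if (r$status != "optimal") {
    stop("lift infeasible at tolerance ", format(atol),
         ": projection inconsistency (escalate tolerance to inspect)")
  }
  stats::setNames(r$x[seq_len(n)], model$reaction_ids)
}
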