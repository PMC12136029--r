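## Convex hull of a point set in up to ~5 dimensions, by exhaustive facet
## enumeration: every affinely independent d-subset of points defines a
## hyperplane, and a hyperplane with all points on one side is a supporting
## facet. O(C(n,d)·n), which is perfectly adequate for the tens of vertices
## a metabolic niche has, and — unlike incremental hull algorithms — immune
## to the coplanar-vertex degeneracies that box-like flux polytopes produce
## (no joggling needed). Rank-deficient point sets are detected and handled
## in their affine hull, reported as explicit equality constraints.

#' Convex hull of points with explicit affine-hull handling
#'
#' @param X Numeric matrix, one point per row.
#' @param atol Absolute geometric tolerance (distance units of `X`).
#' @return A list with `vertices` (matrix of extreme points), `A`, `b`
#'   (halfspaces `A x <= b`, outward normals of unit length; empty when the
#'   hull is a single point), `A_eq`, `b_eq` (affine-hull equalities when
#'   the point set is rank-deficient), `rank`, `basis` (orthonormal basis
#'   of the affine hull), `center`, and `scale` (diameter estimate).
#' @keywords internal
#' @export
convex_hull_points <- function(X, atol = 1e-8) {
  X <- as.matrix(X)
  d <- ncol(X)
  X <- dedupe_points(X, atol)
  k <- nrow(X)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  scale <- max(sqrt(rowSums(Xc^2)), 1e-12) * 2
  sv <- svd(Xc, nu = 0)
  svals <- sv$d
  rank <- sum(svals > max(atol, 1e-12 * scale) * 2)
  ## complete sv$v (min(k,d) columns) to a full orthonormal d x d basis
  V <- qr.Q(qr(cbind(sv$v, diag(d))))[, seq_len(d), drop = FALSE]
  Q <- if (rank > 0) sv$v[, seq_len(rank), drop = FALSE] else matrix(0, d, 0)
  Qc <- if (rank < d) V[, seq.int(rank + 1L, d), drop = FALSE] else matrix(0, d, 0)
  A_eq <- t(Qc); b_eq <- as.vector(A_eq %*% center)

  if (rank == 0L) {
    return(list(vertices = X[1, , drop = FALSE],
                A = matrix(0, 0, d), b = numeric(0),
                A_eq = A_eq, b_eq = b_eq, rank = 0L,
                basis = Q, center = center, scale = scale))
  }
  Y <- Xc %*% Q  # reduced coordinates, k x rank

  if (rank == 1L) {
    i_lo <- which.min(Y[, 1]); i_hi <- which.max(Y[, 1])
    A_red <- rbind(1, -1); b_red <- c(Y[i_hi, 1], -Y[i_lo, 1])
    vid <- unique(c(i_lo, i_hi))
  } else {
    fac <- enumerate_facets(Y, atol)
    A_red <- fac$A; b_red <- fac$b
    ## extreme points: those attaining >= rank facets of full normal rank;
    ## decided robustly via an in-hull LP against the other points
    vid <- which(vapply(seq_len(k), function(i)
      !point_in_hull(Y[i, ], Y[-i, , drop = FALSE], atol), logical(1)))
    if (!length(vid)) vid <- seq_len(k)  # safety net; should not happen
  }
  ## lift halfspaces back to full coordinates: n_red . y <= b  with
  ## y = Q'(x - center)  =>  (Q n_red) . x <= b + n_red . Q' center
  A_full <- A_red %*% t(Q)
  b_full <- b_red + as.vector(A_red %*% t(Q) %*% center)
  list(vertices = X[vid, , drop = FALSE],
       A = A_full, b = b_full,
       A_eq = A_eq, b_eq = b_eq, rank = rank,
       basis = Q, center = center, scale = scale)
}

## Deduplicate rows within atol (keeps first occurrence; deterministic).
dedupe_points <- function(X, atol) {
  if (nrow(X) <= 1L) return(X)
  keep <- rep(TRUE, nrow(X))
  for (i in 2:nrow(X)) {
    prev <- X[seq_len(i - 1L)[keep[seq_len(i - 1L)]], , drop = FALSE]
    if (any(sqrt(rowSums(sweep(prev, 2, X[i, ])^2)) <= atol)) keep[i] <- FALSE
  }
  X[keep, , drop = FALSE]
}

## All supporting hyperplanes of full-dimensional point set Y (k x r, r >= 2)
## found by r-subset enumeration. Returns outward unit normals.
enumerate_facets <- function(Y, atol) {
  k <- nrow(Y); r <- ncol(Y)
  A <- matrix(numeric(0), 0, r); b <- numeric(0)
  if (k <= r) {
    ## simplex or degenerate: handle k == r + 1 simplex via same loop below
  }
  subsets <- utils::combn(k, r, simplify = FALSE)
  for (ss in subsets) {
    P <- Y[ss, , drop = FALSE]
    M <- sweep(P[-1, , drop = FALSE], 2, P[1, ])  # (r-1) x r
    qrM <- qr(t(M))
    if (qrM$rank < r - 1L) next  # affinely dependent subset
    nrm <- qr.Q(qrM, complete = TRUE)[, r]
    off <- sum(nrm * P[1, ])
    s <- as.vector(Y %*% nrm) - off
    tol_here <- atol * max(1, max(abs(off)))
    if (max(s) <= tol_here) {
      # nrm is outward
    } else if (min(s) >= -tol_here) {
      nrm <- -nrm; off <- -off
    } else next
    ## dedupe against collected facets
    if (nrow(A)) {
      same <- sqrt(rowSums(sweep(A, 2, nrm)^2)) < 1e-6 & abs(b - off) < tol_here + 1e-6 * max(1, abs(off))
      if (any(same)) next
    }
    A <- rbind(A, nrm); b <- c(b, off)
  }
  if (!nrow(A)) stop("facet enumeration found no supporting hyperplanes (degenerate input)")
  list(A = A, b = b)
}

## Is point q in the convex hull of rows of P? (feasibility LP over the
## convex-combination weights.)
point_in_hull <- function(q, P, atol) {
  n <- nrow(P)
  if (n == 0L) return(FALSE)
  ## weights w >= 0, sum w = 1, P'w = q
  A_eq <- rbind(t(P), rep(1, n))
  b_eq <- c(q, 1)
  r <- lp_solve(rep(0, n), A_eq = A_eq, b_eq = b_eq, lb = 0, ub = 1,
                tol = max(atol, 1e-9))
  r$status == "optimal"
}
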