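## Dense bounded-variable two-phase simplex.
##
## This is the exact LP oracle the rest of the package is built on: flux
## balance, flux variability at a fixed optimum, support functions for the
## niche projection and the per-grid-point growth extraction all reduce to
## calls into lp_solve(). Problems are small (tens of variables), so the
## implementation favours determinism and transparency over speed: the basis
## is refactorised at every iteration and all pivoting rules are
## deterministic (Dantzig with a Bland anti-cycling fallback, smallest-index
## tie-breaks), so identical inputs always produce bit-identical solutions.

#' Solve a small dense linear program
#'
#' Minimises (or maximises) `obj %*% x` subject to `A_eq %*% x == b_eq`,
#' `A_in %*% x <= b_in` and `lb <= x <= ub`. Bounds may be infinite.
#'
#' @param obj Numeric objective vector (length `n`).
#' @param A_eq,b_eq Equality constraints (matrix with `n` columns, vector).
#' @param A_in,b_in Inequality (`<=`) constraints.
#' @param lb,ub Variable bounds, recycled to length `n`.
#' @param maximize Logical; maximise instead of minimise.
#' @param tol Feasibility/optimality tolerance at solver level.
#' @param maxit Iteration cap (safety net; never reached on the problem
#'   sizes this package generates).
#'
#' @return A list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `x` (primal solution, `NULL` unless optimal), `value`
#'   and, when unbounded, `unbounded_var` (the 1-based index of the entering
#'   structural variable that admits an infinite ray, `NA` for slacks).
#' @keywords internal
#' @export
lp_solve <- function(obj, A_eq = NULL, b_eq = NULL, A_in = NULL, b_in = NULL,
                     lb = -Inf, ub = Inf, maximize = FALSE,
                     tol = 1e-9, maxit = 20000L) {
  n_struct <- length(obj)
  stopifnot(n_struct >= 1L)
  lb <- rep_len(as.numeric(lb), n_struct)
  ub <- rep_len(as.numeric(ub), n_struct)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  lb <- pmin(lb, ub)  # clamp tol-level inversions

  A <- matrix(numeric(0), nrow = 0L, ncol = n_struct)
  b <- numeric(0)
  n_eq <- 0L
  if (!is.null(A_eq)) {
    A_eq <- matrix(as.numeric(A_eq), ncol = n_struct)
    A <- rbind(A, A_eq); b <- c(b, as.numeric(b_eq)); n_eq <- nrow(A_eq)
  }
  n_in <- 0L
  if (!is.null(A_in)) {
    A_in <- matrix(as.numeric(A_in), ncol = n_struct)
    A <- rbind(A, A_in); b <- c(b, as.numeric(b_in)); n_in <- nrow(A_in)
  }
  m <- nrow(A)
  cc <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  ## No constraints beyond bounds: optimum sits at a bound componentwise.
  if (m == 0L) {
    x <- ifelse(cc > 0, lb, ifelse(cc < 0, ub, ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0))))
    if (any(!is.finite(x))) {
      j <- which(!is.finite(x))[1L]
      return(list(status = "unbounded", x = NULL, value = NA_real_, unbounded_var = j))
    }
    val <- sum(obj * x)
    return(list(status = "optimal", x = x, value = val))
  }

  ## Append slacks for inequality rows, then artificials for every row.
  n_slack <- n_in
  n <- n_struct + n_slack
  Afull <- cbind(A, matrix(0, m, n_slack))
  if (n_slack > 0L) {
    for (i in seq_len(n_in)) Afull[n_eq + i, n_struct + i] <- 1
  }
  l <- c(lb, rep(0, n_slack))
  u <- c(ub, rep(Inf, n_slack))
  costs <- c(cc, rep(0, n_slack))

  ## Initial nonbasic placement: finite lower bound, else finite upper, else
  ## free at zero. status: 1 at lb, 2 at ub, 3 free, 0 basic.
  status <- ifelse(is.finite(l), 1L, ifelse(is.finite(u), 2L, 3L))
  z <- ifelse(status == 1L, l, ifelse(status == 2L, u, 0))

  r <- b - as.vector(Afull %*% z)
  art_sign <- ifelse(r >= 0, 1, -1)
  n_art <- m
  Afull <- cbind(Afull, diag(art_sign, m, m))
  l <- c(l, rep(0, m))
  u <- c(u, rep(Inf, m))
  costs <- c(costs, rep(0, m))
  z <- c(z, abs(r))
  status <- c(status, rep(0L, m))
  basis <- n + seq_len(m)
  ntot <- n + n_art

  phase <- 1L
  pc <- c(rep(0, n), rep(1, m))  # phase-1 cost
  degen_run <- 0L
  it <- 0L
  unbounded_var <- NA_integer_

  repeat {
    it <- it + 1L
    if (it > maxit) stop("lp_solve: iteration limit reached")
    B <- Afull[, basis, drop = FALSE]
    nonbasic <- which(status != 0L)
    xB <- tryCatch(solve(B, b - Afull[, nonbasic, drop = FALSE] %*% z[nonbasic]),
                   error = function(e) NULL)
    if (is.null(xB)) stop("lp_solve: singular basis encountered")
    z[basis] <- as.vector(xB)
    cur_cost <- if (phase == 1L) pc else costs
    y <- tryCatch(solve(t(B), cur_cost[basis]), error = function(e) NULL)
    if (is.null(y)) stop("lp_solve: singular basis encountered")
    dN <- cur_cost[nonbasic] - as.vector(t(Afull[, nonbasic, drop = FALSE]) %*% y)

    st <- status[nonbasic]
    cand <- (st == 1L & dN < -tol) | (st == 2L & dN > tol) | (st == 3L & abs(dN) > tol)
    if (!any(cand)) {
      ## Optimal for current phase.
      if (phase == 1L) {
        p1 <- sum(z[n + seq_len(n_art)])
        if (p1 > tol * max(1, max(abs(b)))) {
          return(list(status = "infeasible", x = NULL, value = NA_real_))
        }
        ## Fix artificials at zero and switch to phase 2.
        u[n + seq_len(n_art)] <- 0
        z[n + seq_len(n_art)][status[n + seq_len(n_art)] != 0L] <- 0
        phase <- 2L
        degen_run <- 0L
        next
      }
      x <- z[seq_len(n_struct)]
      val <- sum(obj * x)
      return(list(status = "optimal", x = x, value = val))
    }

    idx <- which(cand)
    if (degen_run > 2L * m + 20L) {
      j_rel <- idx[1L]  # Bland: smallest index among candidates
    } else {
      j_rel <- idx[which.max(abs(dN[idx]))]
    }
    j <- nonbasic[j_rel]
    sigma <- if (status[j] == 1L) 1 else if (status[j] == 2L) -1 else if (dN[j_rel] < 0) 1 else -1

    w <- as.vector(solve(B, Afull[, j]))
    delta <- -sigma * w  # change in basic values per unit increase of t

    ## Ratio test.
    t_basic <- rep(Inf, m)
    hit_upper <- logical(m)
    for (i in seq_len(m)) {
      bi <- basis[i]
      if (delta[i] < -tol) {
        if (is.finite(l[bi])) t_basic[i] <- (z[bi] - l[bi]) / (-delta[i])
      } else if (delta[i] > tol) {
        if (is.finite(u[bi])) { t_basic[i] <- (u[bi] - z[bi]) / delta[i]; hit_upper[i] <- TRUE }
      }
    }
    t_basic <- pmax(t_basic, 0)
    t_flip <- if (status[j] != 3L && is.finite(u[j]) && is.finite(l[j])) u[j] - l[j] else Inf
    t_min_basic <- if (m > 0L) min(t_basic) else Inf
    t_star <- min(t_min_basic, t_flip)

    if (!is.finite(t_star)) {
      if (phase == 1L) stop("lp_solve: unbounded phase-1 (internal error)")
      return(list(status = "unbounded", x = NULL, value = NA_real_,
                  unbounded_var = if (j <= n_struct) j else NA_integer_))
    }

    degen_run <- if (t_star < tol) degen_run + 1L else 0L

    if (t_flip <= t_min_basic) {
      ## Bound flip: entering variable crosses to its other bound.
      z[j] <- if (sigma > 0) u[j] else l[j]
      status[j] <- if (sigma > 0) 2L else 1L
      z[basis] <- z[basis] + delta * t_star
    } else {
      leave_i <- which(t_basic <= t_star + tol)
      leave_i <- leave_i[which.min(basis[leave_i])]  # deterministic tie-break
      bl <- basis[leave_i]
      z[j] <- z[j] + sigma * t_star
      z[basis] <- z[basis] + delta * t_star
      status[bl] <- if (hit_upper[leave_i]) 2L else 1L
      z[bl] <- if (hit_upper[leave_i]) u[bl] else l[bl]
      basis[leave_i] <- j
      status[j] <- 0L
    }
  }
}

#' Brute-force LP solution by basis enumeration (test oracle)
#'
#' Enumerates every choice of basic variables for the system
#' `A %*% x == b`, `lb <= x <= ub` with the remaining variables placed at
#' either bound, keeps the feasible points and returns the best objective
#' value. Exponential; intended only as an independent oracle for very small
#' instances in the test-suite.
#'
#' @inheritParams lp_solve
#' @param A,b Equality constraints.
#' @return List with `status`, `value`, `x` (a best vertex).
#' @keywords internal
#' @export
lp_enumerate <- function(obj, A, b, lb, ub, maximize = FALSE, tol = 1e-7) {
  n <- length(obj)
  A <- matrix(as.numeric(A), ncol = n)
  m <- nrow(A)
  stopifnot(m <= n, n <= 12L)
  best <- NULL; best_x <- NULL
  basic_sets <- utils::combn(n, m, simplify = FALSE)
  for (bs in basic_sets) {
    nb <- setdiff(seq_len(n), bs)
    k <- length(nb)
    Bm <- A[, bs, drop = FALSE]
    if (abs(det(Bm)) < 1e-12) next
    for (mask in seq_len(max(1L, 2L^k)) - 1L) {
      at_ub <- as.logical(bitwAnd(mask, 2L^(seq_len(k) - 1L)))
      xn <- ifelse(at_ub, ub[nb], lb[nb])
      if (any(!is.finite(xn))) next
      xb <- tryCatch(solve(Bm, b - A[, nb, drop = FALSE] %*% xn), error = function(e) NULL)
      if (is.null(xb)) next
      x <- numeric(n); x[bs] <- xb; x[nb] <- xn
      if (any(x < lb - tol) || any(x > ub + tol)) next
      v <- sum(obj * x)
      if (is.null(best) || (maximize && v > best) || (!maximize && v < best)) {
        best <- v; best_x <- x
      }
      if (k == 0L) break
    }
  }
  if (is.null(best)) return(list(status = "infeasible", value = NA_real_, x = NULL))
  list(status = "optimal", value = best, x = best_x)
}
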