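# Shared fixtures. Everything is generated in code; the TOY1 quota chain
# (Liebig growth min(N, P/0.2, C/5), glycogen storage at 7 C per unit) and
# its niche over (EX_N, EX_P, CFIX, BIO) are built once per test run.

toy_env <- function(N, P, C) c(EX_N = N, EX_P = P, CFIX = C)

TOY1 <- toy1_model()
TOY1_NICHE <- project_niche(TOY1, c("EX_N", "EX_P", "CFIX", "BIO"))

# Independent support function of the full flux polytope restricted to a
# coordinate subset: a direct LP over the model, coded here so projection
# tests do not go through the niche construction path.
full_support <- function(model, reactions, u) {
  obj <- numeric(length(model$reaction_ids))
  obj[match(reactions, model$reaction_ids)] <- u
  r <- lp_solve(obj, A_eq = model$S, b_eq = rep(0, nrow(model$S)),
                lb = model$lb, ub = model$ub, maximize = TRUE)
  stopifnot(r$status == "optimal")
  r$value
}

# Brute-force bi-level oracle: growth LP, exact biomass pin, then min/max
# of the target reaction — written against lp_solve directly, independent
# of fva_at_optimum's implementation details.
brute_fva_at_optimum <- function(model, overrides, reaction) {
  bnd <- apply_bound_overrides(model, overrides)
  n <- length(model$reaction_ids)
  bi <- match(model$biomass_reaction, model$reaction_ids)
  g <- lp_solve(replace(numeric(n), bi, 1), A_eq = model$S,
                b_eq = rep(0, nrow(model$S)), lb = bnd$lb, ub = bnd$ub,
                maximize = TRUE)
  if (g$status != "optimal") return(NULL)
  lb <- bnd$lb; ub <- bnd$ub
  lb[bi] <- g$value; ub[bi] <- g$value  # fix biomass at its maximum

  obj <- replace(numeric(n), match(reaction, model$reaction_ids), 1)
  lo <- lp_solve(obj, A_eq = model$S, b_eq = rep(0, nrow(model$S)),
                 lb = lb, ub = ub, maximize = FALSE)
  hi <- lp_solve(obj, A_eq = model$S, b_eq = rep(0, nrow(model$S)),
                 lb = lb, ub = ub, maximize = TRUE)
  c(lo$value, hi$value)
}

# A TOY1 variant written in the SBML uptake-negative convention: nutrient
# exchanges consume their metabolite and uptake runs at negative flux.
toy1_uptake_negative <- function() {
  m <- toy1_model()
  for (ex in c("EX_N", "EX_P")) {
    m$S[, ex] <- -m$S[, ex]
    old_lb <- m$lb[ex]; old_ub <- m$ub[ex]
    m$lb[ex] <- -old_ub; m$ub[ex] <- -old_lb
  }
  m
}

random_toy_bioavailability <- function() {
  c(EX_N = stats::runif(1, 0, 4), EX_P = stats::runif(1, 0, 0.6),
    CFIX = stats::runif(1, 0, 25))
}
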