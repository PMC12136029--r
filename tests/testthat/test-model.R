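# Model container: structural validation, exchange orientation, secretion
# exchanges.

test_that("structural invariants are enforced", {
  S <- matrix(c(1, -1), 1, 2, dimnames = list("m", c("EX_m", "BIO")))
  expect_error(metabolic_model(S, lb = c(0, 0), ub = c(-1, 10), biomass = "BIO",
                               exchanges = "EX_m"), "bound inversion")
  expect_error(metabolic_model(S, lb = c(0, -1), ub = 10, biomass = "BIO",
                               exchanges = "EX_m"), "negative lower bound")
  S2 <- matrix(c(1, 0, -1, -2), 2, 2,
               dimnames = list(c("m", "n"), c("EX_m", "BIO")))
  expect_error(metabolic_model(S2, lb = 0, ub = 10, biomass = "BIO",
                               exchanges = "BIO"), "exactly one boundary metabolite")
  expect_error(metabolic_model(S, lb = 0, ub = 10, biomass = "BIO",
                               exchanges = "EX_m", carbon_coef = c(m = -1)),
               "carbon coefficients")
  # infinite bounds are clamped
  m <- metabolic_model(S, lb = c(-Inf, 0), ub = Inf, biomass = "BIO",
                       exchanges = "EX_m")
  expect_equal(unname(m$lb[["EX_m"]]), -1e6)
  expect_equal(unname(m$ub[["BIO"]]), 1e6)
})

test_that("uptake-negative exchanges are flipped to uptake-positive", {
  S <- matrix(c(-1, -1), 1, 2, dimnames = list("m", c("EX_m", "BIO")))
  m <- metabolic_model(S, lb = c(-10, 0), ub = c(0, 100), biomass = "BIO",
                       exchanges = "EX_m")
  o <- orient_exchanges_uptake_positive(m)
  expect_equal(unname(o$lb[["EX_m"]]), 0)
  expect_equal(unname(o$ub[["EX_m"]]), 10)
  expect_equal(unname(o$S["m", "EX_m"]), 1)
  expect_equal(unname(o$sign_map[["EX_m"]]), -1)
})

test_that("an already-oriented model passes through unchanged", {
  o <- orient_exchanges_uptake_positive(TOY1)
  expect_identical(o$S, TOY1$S)
  expect_identical(o$lb, TOY1$lb)
  expect_identical(o$ub, TOY1$ub)
})

test_that("orientation preserves the FBA optimum", {
  neg <- toy1_uptake_negative()
  oriented <- orient_exchanges_uptake_positive(neg)
  # uptake-negative convention: availability N=2, P=0.2 means lb = -value
  g_neg <- fba_max_biomass(neg, list(EX_N = c(-2, 0), EX_P = c(-0.2, 0),
                                     CFIX = c(0, 12)), canonical = FALSE)
  g_pos <- fba_max_biomass(oriented,
                           bioavailability_overrides(oriented, toy_env(2, 0.2, 12)),
                           canonical = FALSE)
  expect_equal(g_neg$growth, g_pos$growth, tolerance = 1e-9)
  expect_equal(g_pos$growth, 1, tolerance = 1e-9)
})

test_that("secretion exchanges are export-only, optional and idempotent", {
  S <- matrix(c(1, 0, -1, 1, 0, -1), 2, 3,
              dimnames = list(c("a", "b"), c("EX_a", "CONV", "BIO")))
  m <- metabolic_model(S, lb = 0, ub = c(5, 100, 100), biomass = "BIO")
  g0 <- fba_max_biomass(m, canonical = FALSE)$growth
  m2 <- add_secretion_exchange(m, "b")
  expect_true("SEC_b" %in% m2$exchange_reactions)
  expect_equal(unname(m2$lb[["SEC_b"]]), 0)  # producing only, never uptaking
  # adding an optional export cannot change the optimum
  expect_equal(fba_max_biomass(m2, canonical = FALSE)$growth, g0, tolerance = 1e-9)
  # second call is a no-op with a notice
  expect_message(m3 <- add_secretion_exchange(m2, "b"), "already has an exchange")
  expect_identical(m3$reaction_ids, m2$reaction_ids)
  expect_error(add_secretion_exchange(m, "nope"), "unknown metabolite")
})

test_that("bioavailability can only restrict the model's own capacity", {
  ov <- bioavailability_overrides(TOY1, toy_env(2, 0.2, 100))
  expect_equal(ov$CFIX[2], 50)  # capped by the model's fixation capacity
  expect_equal(ov$EX_N, c(0, 2))
  expect_error(bioavailability_overrides(TOY1, c(EX_N = -1)), ">= 0")
  expect_error(bioavailability_overrides(TOY1, c(NOPE = 1)), "unknown reaction")
})
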