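# Niche projection: geometry of the TOY1 niche, membership, growth
# extraction under bioavailability, and lifting back to full flux vectors.

test_that("the TOY1 niche captures the quota structure exactly", {
  ni <- TOY1_NICHE
  # nutrient uptakes are stoichiometrically slaved to biomass, so the
  # 4-coordinate projection is a 2D polytope (growth x glycogen drain)
  expect_equal(ni$rank, 2L)
  # the maximal-biomass vertex realises the Liebig minimum of the
  # capacity quotas: min(10/1, 10/0.2, 50/5) = 10 at (10, 2, 50, 10)
  top <- ni$vertices[which.max(ni$vertices[, "BIO"]), ]
  expect_equal(unname(top), c(10, 2, 50, 10), tolerance = 1e-6)
  # every vertex satisfies every stored halfspace and equality
  for (i in seq_len(nrow(ni$vertices))) {
    expect_true(niche_membership(ni, ni$vertices[i, ]))
  }
})

test_that("membership separates stoichiometrically consistent points", {
  expect_true(niche_membership(TOY1_NICHE, c(1, 0.2, 5, 1)))   # exact balance
  expect_false(niche_membership(TOY1_NICHE, c(0, 0.2, 5, 1)))  # growth w/o N
  expect_error(niche_membership(TOY1_NICHE, c(1, 2)), "dimension")
})

test_that("growth extraction on the niche follows the Liebig optimum", {
  r <- max_biomass_on_niche(TOY1_NICHE, toy_env(2, 0.2, 12))
  expect_equal(r$growth, 1, tolerance = 1e-9)
  expect_false(r$outside_niche)
  expect_equal(unname(r$realized_uptake), c(1, 0.2, 5), tolerance = 1e-6)
  expect_equal(max_biomass_on_niche(TOY1_NICHE, toy_env(0.5, 1, 100))$growth,
               0.5, tolerance = 1e-9)
  expect_equal(max_biomass_on_niche(TOY1_NICHE, toy_env(0, 0, 0))$growth,
               0, tolerance = 1e-9)
  expect_error(max_biomass_on_niche(TOY1_NICHE, c(EX_N = -1)), ">= 0")
})

test_that("bioavailability beyond the niche box reports outside-niche growth 0", {
  # force an unreachable biomass floor through a model with obligatory growth
  m <- TOY1
  m$lb["BIO"] <- 2
  ni <- project_niche(m, c("EX_N", "EX_P", "CFIX", "BIO"))
  r <- max_biomass_on_niche(ni, toy_env(0.5, 1, 100))  # N allows only 0.5
  expect_true(r$outside_niche)
  expect_equal(r$growth, 0)
})

test_that("niche points lift to feasible full flux vectors", {
  lf <- lift_to_full_flux(TOY1, TOY1_NICHE, c(1, 0.2, 5, 1))
  expect_true(is_mass_balanced(TOY1, lf))
  expect_equal(unname(lf[["BIO"]]), 1, tolerance = 1e-4)
  expect_equal(unname(lf[["SYN_glycogen"]]), 0, tolerance = 1e-4)
  # an interior point between two vertices lifts too (convexity)
  v <- TOY1_NICHE$vertices
  mid <- (v[1, ] + v[2, ]) / 2
  expect_true(is_mass_balanced(TOY1, lift_to_full_flux(TOY1, TOY1_NICHE, mid)))
  expect_error(lift_to_full_flux(TOY1, TOY1_NICHE, c(0, 0.2, 5, 1)),
               "not a member")
})

test_that("degenerate and identity projections behave", {
  # single fixed-bound coordinate collapses to a point
  m <- TOY1
  ni1 <- project_niche(m, "CFIX", tol = 1e-6)
  expect_equal(ni1$rank, 1L)  # CFIX still ranges over [0, 50]
  m$lb["CFIX"] <- 12; m$ub["CFIX"] <- 12
  ni0 <- project_niche(m, "CFIX")
  expect_equal(ni0$rank, 0L)
  expect_equal(unname(ni0$vertices[1, 1]), 12)
  # projecting a 3-reaction chain onto all of its reactions reproduces the
  # full polytope: membership must agree with direct LP feasibility
  S <- matrix(c(1, 0, -1, 1, 0, -1), 2, 3,
              dimnames = list(c("a", "b"), c("EX_a", "CONV", "BIO")))
  m3 <- metabolic_model(S, lb = 0, ub = c(2, 10, 10), biomass = "BIO")
  ni3 <- project_niche(m3, c("EX_a", "CONV", "BIO"))
  # the polytope is the segment v1=v2=v3 in [0,2]
  expect_equal(ni3$rank, 1L)
  expect_true(niche_membership(ni3, c(1.5, 1.5, 1.5)))
  expect_false(niche_membership(ni3, c(1.5, 1.5, 1.0)))
  expect_false(niche_membership(ni3, c(3, 3, 3)))
  expect_error(project_niche(TOY1, rep("BIO", 7)), "more than 6")
  expect_error(project_niche(TOY1, "NOPE"), "unknown reactions")
})

test_that("growth is monotone and concave in bioavailability", {
  set.seed(23)
  for (k in 1:20) {
    a <- random_toy_bioavailability()
    b <- random_toy_bioavailability()
    hi <- pmax(a, b)
    g <- function(env) max_biomass_on_niche(TOY1_NICHE, env)$growth
    expect_gte(g(hi), max(g(a), g(b)) - 1e-9)          # monotonicity
    expect_gte(g((a + b) / 2), (g(a) + g(b)) / 2 - 1e-9)  # concavity
  }
})
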