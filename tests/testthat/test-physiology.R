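# Physiology diagnostics: bi-level auxiliary ranges, carbon-equivalent
# composition ratios, slacks, resource constraints and the storage index.

test_that("auxiliary flux ranges follow the carbon-slack arithmetic", {
  rng <- auxiliary_flux_range(TOY1, toy_env(2, 0.2, 12), "SYN_glycogen")
  expect_equal(as.numeric(rng), c(0, 1), tolerance = 1e-6)
  expect_equal(attr(rng, "growth"), 1, tolerance = 1e-9)
  # no slack: all fixed carbon is needed for growth
  rng0 <- auxiliary_flux_range(TOY1, toy_env(1, 0.2, 5), "SYN_glycogen")
  expect_equal(as.numeric(rng0), c(0, 0), tolerance = 1e-8)
  # unreachable obligatory growth -> flagged empty-range convention
  m <- TOY1; m$lb["BIO"] <- 2
  rngf <- auxiliary_flux_range(m, toy_env(0.5, 1, 100), "SYN_glycogen")
  expect_true(attr(rngf, "outside_niche"))
  expect_equal(as.numeric(rngf), c(0, 0))
})

test_that("auxiliary ranges equal the brute-force bi-level oracle", {
  set.seed(31)
  for (k in 1:15) {
    env <- random_toy_bioavailability()
    for (rid in c("SYN_glycogen", "EX_P")) {
      got <- auxiliary_flux_range(TOY1, env, rid)
      want <- brute_fva_at_optimum(TOY1, bioavailability_overrides(TOY1, env), rid)
      expect_equal(as.numeric(got), want, tolerance = 1e-6)
    }
  }
})

test_that("component ratios convert production to carbon equivalents", {
  # glycogen: 7 carbons, no biomass share -> ratio 7 * x / x_bio
  expect_equal(component_ratio(TOY1, 1, 1, "glycogen"), 7)
  expect_equal(component_ratio(TOY1, 2, 1, "glycogen"), 3.5)
  # a lipid-like pool: 33 carbons, biomass share 0.128; zero export still
  # contributes its biomass-bound carbon 33 * 0.128
  spec <- quota_chain_spec(storage = data.frame(
    name = c("glycogen", "lipid"), carbon_atoms = c(7, 33),
    carbon_cost = c(7, 33), biomass_coef = c(0, 0.128)), id = "TOY-lipid")
  ml <- make_quota_chain_model(spec)
  expect_equal(component_ratio(ml, 1, 0, "lipid"), 33 * 0.128)
  expect_equal(component_ratio(ml, 1, 0, "glycogen"), 0)  # x=0, a=0
  expect_true(is.na(component_ratio(TOY1, 0, 1, "glycogen")))  # undefined, not Inf
  expect_error(component_ratio(TOY1, 1, 1, "nope"), "carbon coefficient")
})

test_that("nutrient slacks measure divertible surplus at the optimum", {
  d <- nutrient_slack(TOY1, toy_env(2, 0.2, 12))
  expect_equal(as.numeric(d), c(1, 0, 7), tolerance = 1e-6)
  d2 <- nutrient_slack(TOY1, toy_env(0.5, 1, 100))
  expect_equal(unname(d2[["EX_N"]]), 0, tolerance = 1e-8)  # N is limiting
  # bioavailability exactly at the minimal requirement: all slacks vanish
  d3 <- nutrient_slack(TOY1, toy_env(1, 0.2, 5))
  expect_lt(max(d3), 1e-7)
  # the canonical-optimum variant agrees here (parsimonious = min uptake)
  d4 <- nutrient_slack(TOY1, toy_env(2, 0.2, 12), method = "canonical")
  expect_equal(as.numeric(d4), as.numeric(d), tolerance = 1e-5)
})

test_that("zero slack means the nutrient is genuinely limiting", {
  env <- toy_env(2, 0.2, 12)
  d <- nutrient_slack(TOY1, env)
  g0 <- fba_max_biomass(TOY1, bioavailability_overrides(TOY1, env),
                        canonical = FALSE)$growth
  for (rid in names(d)) {
    less <- env; less[rid] <- less[rid] * 0.9
    g1 <- fba_max_biomass(TOY1, bioavailability_overrides(TOY1, less),
                          canonical = FALSE)$growth
    if (d[[rid]] < 1e-8) expect_lt(g1, g0 - 1e-9) else expect_equal(g1, g0, tolerance = 1e-9)
  }
})

test_that("resource constraints invert and normalise the slack distribution", {
  sl <- data.frame(N = c(1, 0), P = c(0.3, 0.7))
  rc <- resource_constraint(sl)
  expect_equal(rc$N, c(0, 100))    # smallest slack -> 100% (limiting)
  expect_equal(rc$P, c(100, 0))
  # constant slack carries no information
  sl2 <- data.frame(N = c(5, 5, 5), P = c(1, 2, 3))
  rc2 <- resource_constraint(sl2)
  expect_true(all(is.na(rc2$N)))
  expect_identical(attr(rc2, "uninformative"), "N")
  expect_true(all(rc2$P >= 0 & rc2$P <= 100))
  expect_equal(rc2$P[which.min(sl2$P)], 100)
  expect_error(resource_constraint(sl[1, , drop = FALSE]), ">= 2")
})

test_that("the glycogen storage index splits regimes at the ensemble mean", {
  g <- glycogen_storage_index(c(0, 0.5, 1), c(1, 1, 1))
  expect_equal(g$r_stor, c(0, 0.5, 1))
  expect_equal(g$index, c(0, 0.5, 1))
  expect_equal(attr(g, "mean_index"), 0.5)
  expect_identical(g$regime, c("consumption", "storage", "storage"))
  # minimal entry: index 0, consumption; maximal entry: index 1, storage
  expect_equal(g$index[1], 0)
  expect_equal(g$index[3], 1)
  # implied consumption: v_bar at the mean index minus own production
  expect_equal(g$implied_consumption, c(0.5, 0, 0))
  # TOY1 at (2, 0.2, 12) with glycogen production at its maximum: 7 of the
  # 12 fixed carbons go to glycogen
  rng <- auxiliary_flux_range(TOY1, toy_env(2, 0.2, 12), "SYN_glycogen")
  r_stor <- rng[["max"]] * 7 / 12
  expect_equal(r_stor, 7 / 12, tolerance = 1e-6)
  expect_error(glycogen_storage_index(1, 0), "no carbon fixed")
})

test_that("the storage index is invariant under common rescaling", {
  set.seed(3)
  glyc <- runif(20, 0, 2); cfix <- runif(20, 1, 5)
  a <- glycogen_storage_index(glyc, cfix)
  b <- glycogen_storage_index(glyc * 13, cfix * 13)
  expect_equal(a$r_stor, b$r_stor)
  expect_equal(a$index, b$index)
  expect_identical(a$regime, b$regime)
})
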