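# Synthetic generators: closed-form agreement of quota chains, guaranteed
# feasibility of random networks, and the designed structure of the
# environment grid.

test_that("quota-chain LP growth equals the analytic Liebig minimum", {
  set.seed(17)
  specs <- list(
    quota_chain_spec(),  # TOY1
    quota_chain_spec(nutrients = c(A = 1), carbon_per_biomass = 2,
                     storage = data.frame(name = character(), carbon_atoms = numeric(),
                                          carbon_cost = numeric(), biomass_coef = numeric()),
                     id = "single"),
    quota_chain_spec(nutrients = c(N = 0.8, P = 0.15, Si = 0.3),
                     carbon_per_biomass = 4,
                     storage = data.frame(name = c("glycogen", "lipid"),
                                          carbon_atoms = c(7, 33),
                                          carbon_cost = c(7, 33),
                                          biomass_coef = c(0, 0.1)),
                     id = "diatomish"))
  for (spec in specs) {
    m <- make_quota_chain_model(spec)
    for (k in 1:60) {
      b <- stats::setNames(stats::runif(length(spec$nutrients) + 1, 0, 20),
                           c(paste0("EX_", names(spec$nutrients)), "CFIX"))
      lp <- fba_max_biomass(m, bioavailability_overrides(m, b),
                            canonical = FALSE)$growth
      expect_equal(lp, quota_chain_growth(m, b), tolerance = 1e-8)
    }
  }
})

test_that("single-nutrient chain grows at its availability", {
  m <- make_quota_chain_model(quota_chain_spec(
    nutrients = c(A = 1), carbon_per_biomass = 1,
    storage = data.frame(name = character(), carbon_atoms = numeric(),
                         carbon_cost = numeric(), biomass_coef = numeric())))
  g <- fba_max_biomass(m, bioavailability_overrides(m, c(EX_A = 3, CFIX = 50)),
                       canonical = FALSE)$growth
  expect_equal(g, 3, tolerance = 1e-9)
})

test_that("scaling biomass coefficients by k scales growth by 1/k", {
  base <- quota_chain_spec()
  for (k in c(2, 5)) {
    scaled <- quota_chain_spec(nutrients = base$nutrients * k,
                               carbon_per_biomass = base$carbon_per_biomass * k,
                               storage = base$storage)
    m1 <- make_quota_chain_model(base)
    m2 <- make_quota_chain_model(scaled)
    env <- toy_env(2, 0.2, 12)
    g1 <- fba_max_biomass(m1, bioavailability_overrides(m1, env), canonical = FALSE)$growth
    g2 <- fba_max_biomass(m2, bioavailability_overrides(m2, env), canonical = FALSE)$growth
    expect_equal(g2, g1 / k, tolerance = 1e-8)
  }
  expect_error(quota_chain_spec(nutrients = c(N = 0)), "> 0")
})

test_that("random feasible models always grow at unit bioavailability", {
  for (s in 1:10) {
    m <- make_random_feasible_model(sample(4:10, 1), sample(10:18, 1), seed = s)
    b <- stats::setNames(rep(1, length(m$exchange_reactions)), m$exchange_reactions)
    g <- fba_max_biomass(m, bioavailability_overrides(m, b), canonical = FALSE)
    expect_identical(g$status, "optimal")
    expect_gt(g$growth, 0)
  }
  # same seed -> identical model
  expect_identical(make_random_feasible_model(8, 14, seed = 5),
                   make_random_feasible_model(8, 14, seed = 5))
})

test_that("the synthetic grid has the designed limitation structure", {
  spec <- synthetic_grid_spec(seed = 4L)
  g <- make_environment_grid(spec)
  st <- spec$stoichiometry
  lab <- !is.na(g$designed_limitation)
  expect_gt(sum(lab), 10)
  for (i in which(lab)) {
    nut <- g$designed_limitation[i]
    others <- setdiff(c("N", "P", "carbon_fixed"), nut)
    r_lim <- g[[nut]][i] / st[[nut]]
    r_other <- min(vapply(others, function(o) g[[o]][i] / st[[o]], numeric(1)))
    expect_lt(r_lim, r_other)
  }
  # light decays with depth at fixed (lat, lon, month)
  surf <- g[g$depth == min(g$depth), ]
  deep <- g[g$depth == max(g$depth), ]
  key <- function(d) paste(d$lat, d$lon, d$month)
  expect_true(all(deep$carbon_fixed[match(key(surf), key(deep))] < surf$carbon_fixed))
})

test_that("a fixed seed reproduces the grid CSV byte for byte", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_environment_csv(make_environment_grid(synthetic_grid_spec(seed = 9L)), f1)
  write_environment_csv(make_environment_grid(synthetic_grid_spec(seed = 9L)), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
  rt <- read_environment_csv(f1)
  expect_equal(as.data.frame(rt),
               as.data.frame(make_environment_grid(synthetic_grid_spec(seed = 9L))),
               ignore_attr = TRUE)
})

test_that("contradictory overlapping limitation boxes are rejected", {
  expect_error(synthetic_grid_spec(limitation_boxes = list(
    list(nutrient = "P", lat = c(0, 30), lon = c(0, 50)),
    list(nutrient = "N", lat = c(10, 20), lon = c(10, 20)))),
    "contradictory")
})
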