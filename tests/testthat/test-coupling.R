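# Grid driver: composition of the per-point and ensemble passes, point
# independence, thermal masking, configuration errors.

two_point_grid <- function() {
  data.frame(env_id = 1:2, lat = c(0, 10), lon = c(0, 0), depth = 5,
             month = 1L, temperature = c(25, 24), abundance = c(1, 2),
             carbon_fixed = c(12, 100), N = c(2, 0.5), P = c(0.2, 1),
             designed_limitation = NA_character_)
}

TOY_MAP <- c(N = "EX_N", P = "EX_P", carbon_fixed = "CFIX")

test_that("a two-point grid composes growth, slacks and resource constraints", {
  res <- run_grid(TOY1, two_point_grid(), TOY_MAP, doc_candidates = c(glycogen = 7))
  expect_equal(res$growth, c(1, 0.5), tolerance = 1e-8)
  # envA: N slack 1 -> RC 0%; envB: N limiting -> RC 100%
  expect_equal(res$rc_N, c(0, 100), tolerance = 1e-6)
  expect_equal(res$slack_N, c(1, 0), tolerance = 1e-6)
  # envB's phosphate: uptake 0.1 of 1 available
  expect_equal(res$uptake_P[2], 0.1, tolerance = 1e-6)
  # glycogen: envA can bank 7 of 12 fixed carbons; envB has carbon galore
  expect_equal(res$prod_glycogen[1], 1, tolerance = 1e-6)
  expect_equal(res$r_stor[1], 7 / 12, tolerance = 1e-6)
  expect_equal(res$doc_carbon[1], 7, tolerance = 1e-6)
  expect_equal(res$doc_intensity, res$doc_carbon * c(1, 2), tolerance = 1e-8)
})

test_that("identical grid points give identical rows and flagged RC", {
  g <- two_point_grid()[c(1, 1), ]; g$env_id <- 1:2
  expect_warning(res <- run_grid(TOY1, g, TOY_MAP), NA)
  expect_equal(res$growth[1], res$growth[2])
  expect_true(all(is.na(res$rc_N)))  # degenerate distribution is flagged
})

test_that("permuting grid rows permutes result rows identically", {
  spec <- synthetic_grid_spec(nlat = 4, nlon = 4, ndepth = 1, nmonth = 1, seed = 2L)
  g <- as.data.frame(make_environment_grid(spec))
  perm <- sample(nrow(g))
  r1 <- run_grid(TOY1, g, TOY_MAP)
  r2 <- run_grid(TOY1, g[perm, ], TOY_MAP)
  r2_sorted <- r2[order(r2$env_id), ]
  rownames(r2_sorted) <- NULL
  expect_equal(as.data.frame(r1), as.data.frame(r2_sorted))
})

test_that("growth via the reused niche equals direct per-point FBA", {
  spec <- synthetic_grid_spec(nlat = 4, nlon = 4, ndepth = 1, nmonth = 1, seed = 3L)
  g <- make_environment_grid(spec)
  r_niche <- run_grid(TOY1, g, TOY_MAP, use_niche = TRUE)
  r_fba <- run_grid(TOY1, g, TOY_MAP, use_niche = FALSE)
  expect_equal(r_niche$growth, r_fba$growth, tolerance = 1e-8)
  expect_equal(r_niche$slack_N, r_fba$slack_N, tolerance = 1e-8)
  # a prebuilt niche gives the same result as projecting inside run_grid
  ni <- project_niche(TOY1, c(unname(TOY_MAP), "BIO"))
  r_pre <- run_grid(TOY1, g, TOY_MAP, niche = ni)
  expect_equal(as.data.frame(r_niche), as.data.frame(r_pre))
})

test_that("points outside the niche are reported as zero growth with a flag", {
  m <- TOY1; m$lb["BIO"] <- 0.9  # obligatory growth floor
  g <- two_point_grid()
  g$N[2] <- 0.1  # supports at most 0.1 growth: outside the niche
  res <- run_grid(m, g, TOY_MAP)
  expect_false(res$outside_niche[1])
  expect_true(res$outside_niche[2])
  expect_equal(res$growth[2], 0)
})

test_that("the thermal mask is post hoc and boundary-inclusive", {
  g <- two_point_grid(); g$temperature <- c(5, 10)
  res <- run_grid(TOY1, g, TOY_MAP, thermal_min = 10)
  expect_identical(res$masked, c(TRUE, FALSE))   # 10 degC itself is viable
  expect_equal(res$growth, c(1, 0.5), tolerance = 1e-8)  # values retained
  res2 <- thermal_mask(res, -Inf)
  expect_false(any(res2$masked))
})

test_that("configuration errors precede any solve; iron is ignored with a warning", {
  g <- two_point_grid(); g$Si <- 1
  expect_error(run_grid(TOY1, g, TOY_MAP), "unmapped nutrient columns")
  g2 <- two_point_grid(); g2$Fe <- 0.01
  expect_warning(res <- run_grid(TOY1, g2, TOY_MAP), "ignoring nutrient columns")
  expect_equal(res$growth, c(1, 0.5), tolerance = 1e-8)
})

test_that("per-month ensemble scope normalises within months", {
  g <- rbind(two_point_grid(), two_point_grid())
  g$env_id <- 1:4; g$month <- c(1L, 1L, 2L, 2L)
  res <- run_grid(TOY1, g, TOY_MAP, ensemble_scope = "per-month")
  expect_equal(res$rc_N, c(0, 100, 0, 100), tolerance = 1e-6)
})
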