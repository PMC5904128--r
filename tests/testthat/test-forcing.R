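test_that("population grows by the growth factor and tracks productivity", {
  g <- small_grid()
  fp <- forcing_params()
  pop <- generate_population(g, 165, growth_factor = 7, seed = 3, fp)
  tot <- colSums(pop * g$area_km2 * fp$land_frac)
  expect_equal(tot[165] / tot[1], 7, tolerance = 0.01)
  expect_true(all(diff(tot) >= 0))
  expect_true(all(pop >= 0))
  # static pattern correlated with potential NPP; nobody where NPP is lowest
  npp <- site_fields(g, 3, fp)$npp_potential
  expect_gt(cor(pop[, 1], npp, method = "spearman"), 0.2)
  lowest <- npp <= quantile(npp, 0.1)
  expect_lt(mean(pop[lowest, 1]), 0.1 * mean(pop[, 1]))
})

test_that("population with growth factor 1 is constant and seeds reproduce", {
  g <- small_grid()
  pop <- generate_population(g, 40, growth_factor = 1, seed = 5)
  expect_true(all(pop == pop[, 1]))
  expect_identical(generate_population(g, 40, 7, seed = 11),
                   generate_population(g, 40, 7, seed = 11))
  expect_error(generate_population(g, -5, 7, seed = 1), "positive span")
  expect_error(generate_population(g, 40, 0, seed = 1), "growth_factor")
})

test_that("crop area interpolates its endpoints and never shrinks per cell", {
  g <- small_grid()
  fp <- forcing_params()
  crop <- generate_crop_fraction(g, 165, 5e6, 15e6, seed = 7, fp)
  land <- g$area_km2 * fp$land_frac
  area <- colSums(crop * land)
  expect_equal(area[1], 5e6, tolerance = 0.01)
  expect_equal(area[165], 15e6, tolerance = 0.01)
  expect_true(all(crop >= 0 & crop <= 1))
  expect_true(all(apply(crop, 1, function(x) all(diff(x) >= -1e-12))))
  # constant when endpoints agree
  cc <- generate_crop_fraction(g, 30, 5e6, 5e6, seed = 7, fp)
  expect_true(all(cc == cc[, 1]))
  expect_error(generate_crop_fraction(g, 30, 5e6, 1e9, seed = 7, fp),
               "exceeds")
})

test_that("lightning climatology spans both clamp regimes", {
  g <- make_grid(10, 20)
  fp <- forcing_params()
  fl <- generate_lightning(g, seed = 42, fp)
  fire <- fire_params()
  expect_true(min(fl) >= 0)
  expect_true(any(fl < fire$F_low))
  expect_true(any(fl > fire$F_high))
  # tropical maximum, poleward decay (band means)
  band <- tapply(rowMeans(fl), abs(g$lat), mean)
  expect_gt(band[[1]], band[[length(band)]])
  expect_identical(generate_lightning(g, seed = 42, fp),
                   generate_lightning(g, seed = 42, fp))
})

test_that("frozen climate recycles its block exactly", {
  g <- small_grid()
  cl <- generate_climate(g, 50, transient = FALSE, seed = 9)
  expect_identical(cl$wetness[, , 1:25], cl$wetness[, , 26:50])
  expect_identical(cl$wind[, , 1:25], cl$wind[, , 26:50])
  tr <- generate_climate(g, 50, transient = TRUE, seed = 9)
  expect_false(identical(tr$wetness[, , 1:25], tr$wetness[, , 26:50]))
  expect_identical(generate_climate(g, 10, TRUE, seed = 4),
                   generate_climate(g, 10, TRUE, seed = 4))
})

test_that("CO2 trajectory is a monotone interpolation of its endpoints", {
  co2 <- generate_co2(165, 285, 397)
  expect_equal(co2[1], 285)
  expect_equal(co2[165], 397)
  expect_true(all(diff(co2) >= 0))
  expect_true(all(generate_co2(10, 300, 300) == 300))
  expect_error(generate_co2(10, -5, 300), "must be > 0")
})

test_that("all generated fields respect their range invariants across seeds", {
  g <- small_grid()
  fp <- forcing_params()
  for (seed in 1:20) {
    f <- make_forcing(g, 12, fp, seed)
    expect_true(all(f$population >= 0))
    expect_true(all(f$crop_frac >= 0 & f$crop_frac <= 1))
    expect_true(all(f$lightning >= 0))
    expect_true(all(f$wetness >= 0 & f$wetness <= 1))
    expect_true(all(f$wind >= 0))
    expect_true(all(f$co2 > 0))
    expect_gt(cor(f$population[, 1], f$npp_potential, method = "spearman"),
              0.2)
  }
})

test_that("scenario freezing yields fields bit-identical to the baseline", {
  g <- small_grid()
  f <- make_forcing(g, 50, forcing_params(), 13)
  frozen <- scenario_forcing(f, scenario_spec(character(), years = 50))
  for (y in 2:50) {
    expect_identical(frozen$population[, y], f$population[, 1])
    expect_identical(frozen$crop_frac[, y], f$crop_frac[, 1])
    expect_identical(frozen$co2[y], f$co2[1])
  }
  expect_identical(frozen$wetness[, , 26:50], f$wetness[, , 1:25])
  # population freeze pins the field from the freeze year on
  pf <- scenario_forcing(f, scenario_spec(
    c("climate", "co2", "population", "landuse"),
    population_freeze_year = 30, years = 50))
  expect_identical(pf$population[, 31:50],
                   matrix(f$population[, 30], nrow(f$population), 20))
  expect_identical(pf$population[, 1:30], f$population[, 1:30])
  expect_error(scenario_spec("population", population_freeze_year = 60,
                             years = 50), "within the simulation span")
  expect_error(scenario_spec("volcanoes"), "unknown forcing")
})
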