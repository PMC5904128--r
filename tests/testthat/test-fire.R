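test_that("biomass probability ramps linearly between its thresholds", {
  expect_equal(biomass_probability(0.1), 0)   # below 0.2 fire not sustained
  expect_equal(biomass_probability(1.5), 1)   # above 1.0 fuel does not limit
  expect_equal(biomass_probability(0.6), 0.5) # ramp midpoint
  expect_equal(biomass_probability(c(0, 0.2, 1, 2)), c(0, 0, 1, 1))
  # continuity at the thresholds
  expect_lt(biomass_probability(0.2 + 1e-9), 1e-6)
  expect_gt(biomass_probability(1 - 1e-9), 1 - 1e-6)
  expect_error(biomass_probability(-0.1), ">= 0")
})

test_that("moisture probability decreases from dry to saturated", {
  expect_equal(moisture_probability(0), 1)
  expect_equal(moisture_probability(1), 0)
  expect_equal(moisture_probability(0.5), 0.75) # 1 - 0.5^2
  w <- seq(0, 1, 0.01)
  expect_true(all(diff(moisture_probability(w)) < 0))
  expect_error(moisture_probability(1.2), "wetness")
})

test_that("lightning scalar clamps linearly between its thresholds", {
  p <- fire_params()
  expect_equal(lightning_scalar(p$F_low), 0)
  expect_equal(lightning_scalar(p$F_high), 1)
  expect_equal(lightning_scalar((p$F_low + p$F_high) / 2), 0.5)
  expect_equal(lightning_scalar(0), 0)
  expect_equal(lightning_scalar(100), 1)
})

test_that("ignition sigmoid matches its closed form", {
  expect_equal(ignition_sigmoid(0.8), 0.5)
  expect_equal(ignition_sigmoid(0), 1 / (1 + exp(8)), tolerance = 1e-6)
  expect_equal(ignition_sigmoid(1), 1 / (1 + exp(-2)), tolerance = 1e-6)
  expect_equal(ignition_sigmoid(0), 0.000335350, tolerance = 1e-5)
  expect_equal(ignition_sigmoid(1), 0.880797078, tolerance = 1e-6)
})

test_that("natural ignition hits its endpoints exactly and its midpoint value", {
  expect_identical(natural_ignition_probability(0), 0)
  expect_identical(natural_ignition_probability(1), 1)
  expect_equal(natural_ignition_probability(0.5), 0.10686, tolerance = 1e-4)
  u <- seq(0, 1, 0.02)
  pin <- natural_ignition_probability(u)
  expect_true(all(pin >= 0 & pin <= 1))
  expect_true(all(diff(pin) > 0))
})

test_that("human ignition follows the power law and saturates", {
  expect_equal(human_ignition_probability(0), 0)
  expect_equal(human_ignition_probability(300), 1)
  expect_equal(human_ignition_probability(3), 0.01^0.43, tolerance = 1e-9)
  expect_equal(human_ignition_probability(3), 0.1380, tolerance = 1e-3)
  expect_equal(human_ignition_probability(1e6), 1)
  p <- seq(0, 500, 5)
  expect_true(all(diff(human_ignition_probability(p)) >= 0))
})

test_that("total ignition combines sources and fire probability multiplies", {
  expect_equal(total_ignition_probability(0, 0.4), 0.4)
  expect_equal(total_ignition_probability(1, 0.7), 1)
  expect_equal(total_ignition_probability(0.3, 0.5), 0.65)
  expect_equal(fire_probability(0.5, 0.5, 0.5), 0.125)
  expect_equal(fire_probability(0, 0.9, 0.9), 0)
  expect_equal(fire_probability(1, 1, 1), 1)
})

test_that("extinguishing probability runs from 0.5 to 1 with population", {
  expect_equal(extinguish_probability(0), 0.5)
  expect_equal(extinguish_probability(1e9), 1)
  expect_equal(extinguish_probability(40), 0.5 + (1 - exp(-1)) / 2)
  expect_equal(extinguish_probability(40), 0.81606, tolerance = 1e-5)
  p <- seq(0, 1000, 10)
  q <- extinguish_probability(p)
  expect_true(all(q >= 0.5 & q <= 1))
  expect_true(all(diff(q) > 0))
})

test_that("expected duration and amplification follow the geometric law", {
  expect_equal(expected_duration(0.5), 1) # one day with nobody around
  expect_equal(expected_duration(1), 0)
  q40 <- extinguish_probability(40)
  expect_equal(expected_duration(q40), 0.22540, tolerance = 1e-5)
  expect_equal(duration_amplification(0.5), 3)
  expect_equal(duration_amplification(1), 0)
  expect_error(expected_duration(0), "q must")
  expect_error(duration_amplification(0), "q must")
  # monotone against population density
  p <- seq(0, 200, 2)
  q <- extinguish_probability(p)
  expect_true(all(diff(expected_duration(q)) <= 0))
  expect_true(all(diff(duration_amplification(q)) <= 0))
})

test_that("closed forms match a Monte-Carlo geometric-duration oracle", {
  set.seed(101)
  n <- 1e6
  for (q in c(0.5, 0.6, 0.8, 0.95)) {
    tau <- stats::rgeom(n, q) # P(tau) = q (1-q)^tau, tau = 0, 1, 2, ...
    se1 <- stats::sd(tau) / sqrt(n)
    expect_lt(abs(mean(tau) - expected_duration(q)), 3 * se1)
    t2 <- as.numeric(tau)^2
    se2 <- stats::sd(t2) / sqrt(n)
    expect_lt(abs(mean(t2) - duration_amplification(q)), 3 * se2)
  }
})

test_that("spread rate respects its bounds and modifiers", {
  p <- fire_params()
  expect_equal(spread_rate("natural", wind = 20, wetness = 1), 0)
  expect_equal(spread_rate("natural", wind = 0, wetness = 0),
               p$u_max[["natural"]] * p$spread_wind_floor)
  wind <- runif(50, 0, 60); wet <- runif(50)
  u <- spread_rate("natural", wind, wet)
  expect_true(all(u >= 0 & u <= p$u_max[["natural"]]))
  expect_error(spread_rate("kelp", 5, 0.5), "unknown vegetation class")
})

test_that("daily burned area is an ellipse shaped by wind", {
  p <- fire_params()
  expect_equal(daily_burned_area(0, 10), 0)
  # calm air: circular burn of diameter l
  u <- 0.1
  l <- p$head_back_factor * u * 24
  expect_equal(daily_burned_area(u, 0), pi * l^2 / 4)
  # l = 2 km at length-to-breadth 2 -> pi * 1 * 0.5
  u2 <- 2 / (p$head_back_factor * 24)
  wind2 <- -log(1 - 1 / (p$lb_max - 1)) / p$lb_wind_coef # LB(wind2) = 2
  expect_equal(daily_burned_area(u2, wind2), pi * 1 * 0.5, tolerance = 1e-9)
  expect_equal(daily_burned_area(u2, wind2), 1.5708, tolerance = 1e-4)
})

test_that("cell burned area substitutes, masks crops, and caps", {
  p <- fire_params()
  # P_f * a_1day * Theta * A_g / a_rep with q giving Theta = 3
  expect_equal(cell_burned_area(P_f = 0.1, a_1day = 2, q = 0.5, A_g = 1e4,
                                crop_frac = 0), 12)
  expect_equal(cell_burned_area(0.5, 5, 0.5, 1e4, crop_frac = 1), 0)
  expect_equal(cell_burned_area(0.1, 4, 0.5, 1e4, 0),
               2 * cell_burned_area(0.1, 2, 0.5, 1e4, 0))
  # cap at the natural area
  expect_equal(cell_burned_area(1, 1e9, 0.5, 1e4, 0.4), 6e3)
  expect_true(all(cell_burned_area(runif(20), runif(20, 0, 5),
                                   runif(20, 0.5, 1), 1e4,
                                   runif(20)) <= 1e4))
})

test_that("burned-area scalar has an interior optimum without lightning", {
  p_d <- seq(0, 100, 0.1)
  curve0 <- burned_area_scalar_curve(p_d, P_i_n = 0)
  expect_equal(curve0$A[1], 0) # no people, no lightning: no ignition
  am <- attr(curve0, "argmax")
  expect_gt(am, 0)
  expect_lt(am, 100)
  # saturated lightning: suppression is the only population effect
  curve1 <- burned_area_scalar_curve(p_d, P_i_n = 1)
  expect_true(all(diff(curve1$A) < 0))
})

test_that("every link of the probability chain stays in [0,1]", {
  set.seed(7)
  for (i in 1:200) {
    d <- cell_fire_diagnostics(B_ag = runif(1, 0, 3), wetness = runif(1),
                               F_c2g = runif(1, 0, 20), p_d = runif(1, 0, 500),
                               wind = runif(1, 0, 80), A_g = runif(1, 1, 1e5),
                               crop_frac = runif(1))
    probs <- unlist(d[c("P_b", "P_m", "upsilon_F", "P_i_n", "P_i_h",
                        "P_i", "P_f")])
    expect_true(all(probs >= 0 & probs <= 1))
    expect_true(d$q >= 0.5 && d$q <= 1)
    expect_equal(d$tau_bar, (1 - d$q) / d$q)
    expect_equal(d$theta, (1 - d$q) * (2 - d$q) / d$q^2)
    expect_true(d$A_b >= 0)
  }
})

test_that("crop-covered cells never burn and burning falls with crop cover", {
  set.seed(8)
  for (i in 1:50) {
    d <- cell_fire_diagnostics(B_ag = runif(1, 0.5, 3), wetness = runif(1),
                               F_c2g = runif(1, 0, 20), p_d = runif(1, 0, 100),
                               wind = runif(1, 0, 50), A_g = 1e4,
                               crop_frac = 1)
    expect_equal(d$A_b, 0)
  }
  cf <- seq(0, 1, 0.05)
  ab <- cell_burned_area(0.2, 1.5, 0.55, 1e4, cf)
  expect_true(all(diff(ab) <= 0))
})
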