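test_that("breath series validates units and phase ordering", {
  expect_error(breath_series(1:5, rep(300, 5), unit = "ml_min"), "mass")
  b <- breath_series(1:5, rep(300, 5), unit = "ml_min", mass = 75)
  expect_equal(b$vo2, rep(4, 5))
  expect_error(
    breath_series(1:4, rep(10, 4), phase = c("exercise", "rest", "rest", "recovery")),
    "ordered"
  )
  expect_error(
    breath_series(1:4, rep(10, 4), phase = c("rest", "exercise", "rest", "rest")),
    "ordered"
  )
})

test_that("minute averaging is time-weighted over non-overlapping bins", {
  b <- breath_series(seq(0, 180, 1), rep(3000, 181), unit = "ml_min", mass = 1)
  m <- minute_average(b)
  expect_true(all(abs(m$vo2 - 3000) < 1e-9))
  # 30 s at 2000 + 30 s at 4000 averages to 3000
  b2 <- breath_series(seq(0, 60, 0.5),
                      c(rep(2000, 60), rep(4000, 61)), unit = "ml_min", mass = 1)
  m2 <- minute_average(b2)
  expect_equal(m2$vo2[1L], 3000, tolerance = 0.01)
  # 90 s: one full bin plus a flagged partial
  b3 <- breath_series(seq(0, 90, 1), rep(1000, 91), unit = "ml_min", mass = 1)
  m3 <- minute_average(b3)
  expect_identical(m3$partial, c(FALSE, TRUE))
  expect_error(minute_average(breath_series(1:10, rep(1, 10))), "60 s")
})

test_that("steady state is the mean of the last three minute averages", {
  mins <- c(35, 39, 40.5, 40.8, 41.1)
  t <- seq(0, 300 - 1, 1)
  vo2 <- rep(mins, each = 60)
  b <- breath_series(t, vo2, phase = "exercise")
  expect_equal(steady_state_vo2(b), mean(c(40.5, 40.8, 41.1)), tolerance = 0.01)
  b_const <- breath_series(seq(0, 299), rep(40, 300), phase = "exercise")
  expect_equal(steady_state_vo2(b_const), 40, tolerance = 1e-6)
  b_short <- breath_series(seq(0, 180), rep(40, 181), phase = "exercise")
  expect_error(steady_state_vo2(b_short), "4 min")
})

test_that("linear running cost reproduces the measured flat constant", {
  # net uptake chosen to give the 4.66 J/kg/m grass constant at 2.86 m/s
  expect_equal(linear_cost_cr(38.25 + 3.5, 3.5, v = 2.86), 4.66,
               tolerance = 0.005)
  # group-mean arithmetic: 40.8 steady state, 266/75.9 rest, 2.86 m/s
  expect_equal(linear_cost_cr(40.8, 266 / 75.9, v = 2.86), 4.54,
               tolerance = 0.005)
  # limit: net uptake to zero drives the cost to zero
  expect_lt(linear_cost_cr(3.5 + 1e-6, 3.5, v = 2.86), 1e-5)
  expect_error(linear_cost_cr(40, 3.5, v = 0), "positive")
  expect_error(linear_cost_cr(3.0, 3.5, v = 2.86), "exceed")
})

test_that("aerobic energy integrates net uptake over exercise", {
  t <- seq(0, 480, 1)
  b0 <- breath_series(t, rep(3.5, length(t)), phase = "exercise")
  expect_equal(aerobic_energy(b0, rest = 3.5), 0)
  b1 <- breath_series(t, rep(44.5, length(t)), phase = "exercise")
  expect_equal(aerobic_energy(b1, rest = 3.5), 41 * 8 * 20.9, tolerance = 1e-6)
  # linear ramp covers half the constant-demand area
  b2 <- breath_series(t, 3.5 + 41 * t / 480, phase = "exercise")
  expect_equal(aerobic_energy(b2, rest = 3.5), 41 * 8 * 20.9 / 2,
               tolerance = 1e-6)
})

test_that("alactic debt subtracts the 4th-6th-minute slow baseline", {
  t <- seq(0, 400, 1)
  rest <- 3.5
  # instantly back at rest: no fast debt
  b0 <- breath_series(t, rep(rest, length(t)), phase = "recovery")
  expect_equal(alactic_debt(b0, rest = rest), 0)
  # constant elevation is attributed entirely to the slow baseline
  bc <- breath_series(t, rep(rest + 10, length(t)), phase = "recovery")
  expect_equal(alactic_debt(bc, rest = rest), 0, tolerance = 1e-6)
  # mono-exponential decay: closed-form oracle
  bexp <- breath_series(t, rest + 30 * exp(-t / 40), phase = "recovery")
  total_ml <- 30 * 40 / 60 * (1 - exp(-360 / 40))
  base <- 30 * 40 * (exp(-180 / 40) - exp(-360 / 40)) / 180
  oracle <- (total_ml - base * 6) * 20.9
  expect_equal(alactic_debt(bexp, rest = rest), oracle, tolerance = 0.005)
  expect_gt(oracle, 400)  # the bulk of the 30 mL/kg/min transient
  # the exponential-fit alternative recovers A * tau for a clean curve
  expect_equal(alactic_debt(bexp, rest = rest, method = "exponential"),
               30 * 40 / 60 * 20.9, tolerance = 0.01)
  b_short <- breath_series(seq(0, 300), rep(rest, 301), phase = "recovery")
  expect_error(alactic_debt(b_short, rest = rest), "6 min")
})

test_that("lactic energy converts net lactate accumulation", {
  expect_equal(lactic_energy(5, 5), 0)
  expect_equal(lactic_energy(7.2, 1.0), 6.2 * 3 * 20.9)  # 388.74 J/kg
  expect_equal(lactic_energy(2, 1), 62.7)
  expect_equal(lactic_energy(1, 2), 0)  # floored, never negative
  expect_error(lactic_energy(-1, 0), "non-negative")
})

test_that("energy partition combines compartments into cost and power", {
  ep <- energy_partition(aer = 6.41 * 1168 - 700, anal = 350, anl = 350,
                         distance = 1168, duration = 480)
  expect_equal(ep$total, ep$aer + ep$anal + ep$anl)
  expect_equal(ep$c, ep$total / 1168)
  expect_equal(ep$pvo2, ep$c * 1168 / 480)
  # equivalently total / duration, to machine precision
  expect_equal(ep$pvo2, ep$total / 480)
  # doubling distance at fixed energy halves the cost
  ep2 <- energy_partition(ep$aer, ep$anal, ep$anl, 2 * 1168, 480)
  expect_equal(ep2$c, ep$c / 2)
  expect_error(energy_partition(1, 1, 1, 0, 480), "positive")
  expect_error(energy_partition(-1, 1, 1, 10, 480), "non-negative")
})

test_that("partition estimators recover the simulator's energy truth", {
  sim <- sim_clean()
  truth <- attr(sim$breaths, "truth")
  part <- calorimetry_partition(sim$breaths, sim$lactate$la_pre,
                                sim$lactate$la_post,
                                distance = sim$summary$distance_m)
  expect_equal(part$aer, truth$aer, tolerance = 0.01)
  expect_equal(part$anal, truth$alactic, tolerance = 0.01)
  expect_equal(part$anl, truth$lactic, tolerance = 1e-9)
  # intermittent circuit cost exceeds the flat linear-running cost
  expect_gt(part$c, 4.66)
})

test_that("recovered direct power converges to demand as kinetics sharpen", {
  t <- seq(0, 480, 0.1)
  demand <- 12  # W/kg constant
  truth <- make_series(t, v = rep(demand / 4.66, length(t)),
                       power = rep(demand, length(t)))
  for (tau in c(20, 5, 1)) {
    params <- physio_params(tau_on = tau, tau_off = tau, breath_noise = 0)
    br <- simulate_breaths(truth, params, breath_dt = 1, noise = 0)
    tr <- attr(br, "truth")
    part <- calorimetry_partition(br, 1, 1 + tr$delta_la, distance = 1000,
                                  duration = 480)
    err <- abs(part$total / 480 - demand) / demand
    if (tau == 1) expect_lt(err, 0.01)
  }
})
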