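small_setup <- function(rpm = 300, gas_flow = 0.51, d = 0.05, np = 5,
                        count = 1) {
  reactor_setup(vessel_diameter = 0.122, total_volume = 3,
                working_volume = 2,
                impellers = impeller_spec(d, np, count),
                sparger = "ring", stirrer_speed = rpm, gas_flow = gas_flow)
}

test_that("tip speed follows pi * d * n and inverts the benchtop row", {
  s <- small_setup(rpm = 60, d = 0.1)
  expect_equal(tip_speed(s), pi / 10)
  expect_equal(tip_speed(small_setup(rpm = 0)), 0)
  # 0.97 m/s at 355 rpm implies a 52.2 mm impeller
  d <- 0.97 * 60 / (pi * 355)
  expect_equal(tip_speed(small_setup(rpm = 355, d = d)), 0.97)
  expect_equal(d, 0.0522, tolerance = 1e-3)
})

test_that("geometry ratio is linear in diameter and decreases with scale", {
  s1 <- small_setup()
  s2 <- s1; s2$vessel_diameter <- 2 * s1$vessel_diameter
  expect_equal(geometry_ratio(s2), 2 * geometry_ratio(s1))
  scales <- lapply(c("2L", "20L", "200L"), function(x) scale_preset(x)$setup)
  ratios <- vapply(scales, geometry_ratio, numeric(1))
  expect_true(all(diff(ratios) < 0))
  # benchtop vessels score in the tens, pilot scale near unity (mm/L)
  expect_equal(ratios, c(40.8, 7.96, 1.57), tolerance = 0.01)
})

test_that("ungassed power is Np * rho * n^3 * d^5 summed over impellers", {
  s <- small_setup(rpm = 300, d = 0.05, np = 5)
  expect_equal(ungassed_power(s), 5 * 1000 * 5^3 * 0.05^5)  # 0.1953 W
  expect_equal(ungassed_power(small_setup(rpm = 0)), 0)
  s2 <- small_setup(rpm = 300, d = 0.05, np = 5, count = 2)
  expect_equal(ungassed_power(s2), 2 * ungassed_power(s))
  expect_error(ungassed_power(s, broth_density = -5), "density")
  expect_warning(ungassed_power(small_setup(rpm = 30, d = 0.01)), "Reynolds")
})

test_that("gassed power applies the Michel-Miller correction and caps at P", {
  s <- small_setup(rpm = 300, d = 0.05)
  p0 <- ungassed_power(s)
  # independent hand evaluation of c * (P^2 n d^3 / Q^0.56)^0.45
  q_m3s <- 0.51 / 1000 / 60
  expect_equal(gassed_power(s, p0),
               0.72 * (p0^2 * 5 * 0.05^3 / q_m3s^0.56)^0.45,
               tolerance = 1e-12)
  s0 <- s; s0$gas_flow <- 0
  expect_identical(gassed_power(s0, p0), p0)
  # monotone non-increasing in gas flow, never above ungassed
  flows <- c(0, 0.1, 0.51, 2, 10)
  pg <- vapply(flows, function(q) {
    si <- s; si$gas_flow <- q; gassed_power(si, p0)
  }, numeric(1))
  expect_true(all(diff(pg) <= 1e-12))
  expect_true(all(pg <= p0 + 1e-12))
})

test_that("power per volume and superficial gas velocity are unit-consistent", {
  expect_equal(power_per_volume(0.5, 2), 0.25)
  expect_equal(power_per_volume(0, 2), 0)
  expect_equal(power_per_volume(26, 200), 0.13)
  expect_error(power_per_volume(1, 0), "working_volume")

  pilot <- reactor_setup(0.58, 300, 200, impeller_spec(0.2, 5),
                         stirrer_speed = 117, gas_flow = 37.5)
  expect_equal(superficial_gas_velocity(pilot), 2.366e-3, tolerance = 1e-3)
  v_base <- superficial_gas_velocity(pilot)
  pilot$gas_flow <- 0
  expect_equal(superficial_gas_velocity(pilot), 0)
  pilot$gas_flow <- 75
  expect_equal(superficial_gas_velocity(pilot), 2 * v_base)
})

test_that("simulated DO step has the exponential shape and is reproducible", {
  half <- log(2) / 40
  tr <- simulate_do_step(40, duration = 10 * half, sample_interval = half)
  expect_equal(tr$do_percent[1], 0)
  expect_equal(tr$do_percent[2], 50)          # one half-saturation time
  expect_equal(tr$do_percent[11], 100 * (1 - 2^-10))
  long <- simulate_do_step(40, duration = 1, sample_interval = 0.01)
  expect_equal(tail(long$do_percent, 1), 100, tolerance = 1e-10)
  a <- simulate_do_step(40, noise_sd = 1, seed = 11)
  b <- simulate_do_step(40, noise_sd = 1, seed = 11)
  expect_identical(a, b)
  expect_error(simulate_do_step(-1), "kla")
})

test_that("kla fit inverts the noiseless generator across the working range", {
  for (k in c(10, 32.6, 38.8, 40, 40.5, 41.1, 100)) {
    est <- fit_kla(simulate_do_step(k))
    expect_equal(est$kla, k, tolerance = 1e-4)
    expect_gt(est$r_squared, 0.999999)
  }
})

test_that("kla fit rejects degenerate traces", {
  tr <- simulate_do_step(40)
  expect_error(fit_kla(tr, window = c(99.9, 100)), "fewer than 5|outside")
  flat <- do_trace(seq(0, 1, 0.1), rep(150, 11), saturation_value = 100)
  expect_error(fit_kla(flat), "outside|saturation")
  above <- do_trace(seq(0, 1, 0.25), c(10, 30, 50, 70, 89),
                    saturation_value = 80)
  expect_error(fit_kla(above), "saturation")
})

test_that("kla estimator precision under probe noise is within 3 %", {
  ests <- vapply(1:100, function(s) {
    fit_kla(simulate_do_step(40, noise_sd = 1, seed = s))$kla
  }, numeric(1))
  expect_lt(sd(ests) / mean(ests), 0.03)
  # the log-linearisation carries a small downward bias under noise
  expect_equal(mean(ests), 40, tolerance = 0.03)
})

test_that("power-law kla correlation recovers generating parameters", {
  pts <- expand.grid(pg_vl = c(0.1, 0.25, 0.63), vs = c(1e-3, 2e-3, 4e-3))
  pts$kla <- 120 * pts$pg_vl^0.5 * pts$vs^0.3
  corr <- fit_kla_correlation(pts)
  expect_equal(corr$coefficient, 120, tolerance = 1e-6)
  expect_equal(corr$exponent_power, 0.5, tolerance = 1e-9)
  expect_equal(corr$exponent_gas, 0.3, tolerance = 1e-9)
  expect_equal(predict_kla(corr, 0.25, 2e-3), 120 * 0.25^0.5 * 2e-3^0.3)
  # a single repeated condition cannot identify the exponents
  degen <- data.frame(pg_vl = rep(0.25, 4), vs = rep(2e-3, 4), kla = 40)
  expect_error(fit_kla_correlation(degen), "degenerate")
  expect_error(fit_kla_correlation(pts[1:2, ]), "3 points")
})

test_that("noisy correlation fits recover exponents within Monte-Carlo bounds", {
  pts <- expand.grid(pg_vl = c(0.1, 0.25, 0.63, 1.2),
                     vs = c(1e-3, 2e-3, 4e-3))
  true <- c(a = 0.5, b = 0.3)
  set.seed(42)
  fits <- t(replicate(200, {
    noisy <- pts
    noisy$kla <- 120 * pts$pg_vl^0.5 * pts$vs^0.3 *
      exp(rnorm(nrow(pts), sd = 0.02))
    co <- fit_kla_correlation(noisy)
    c(co$exponent_power, co$exponent_gas)
  }))
  expect_lt(abs(mean(fits[, 1]) - true["a"]), 3 * sd(fits[, 1]))
  expect_lt(abs(mean(fits[, 2]) - true["b"]), 3 * sd(fits[, 2]))
})

test_that("operating-point solver hits the target kla and is monotone", {
  setup <- scale_preset("2L")$setup
  # correlation anchored on three synthetic operating points of that vessel
  rpms <- c(250, 400, 600)
  pts <- do.call(rbind, lapply(rpms, function(r) {
    s <- setup; s$stirrer_speed <- r
    p0 <- ungassed_power(s)
    data.frame(pg_vl = power_per_volume(gassed_power(s, p0), s$working_volume),
               vs = superficial_gas_velocity(s), kla = NA)
  }))
  pts$vs <- pts$vs * c(1, 2, 4)  # vary gas flow too for identifiability
  pts$kla <- 600 * pts$pg_vl^0.45 * pts$vs^0.35
  corr <- fit_kla_correlation(pts)

  # predicted kla rises strictly with stirrer speed at fixed gas flow
  preds <- vapply(seq(100, 1200, by = 100), function(r) {
    s <- setup; s$stirrer_speed <- r
    suppressWarnings(setup_kla(s, corr))
  }, numeric(1))
  expect_true(all(diff(preds) > 0))

  target <- suppressWarnings(setup_kla(setup, corr))
  solved <- suppressWarnings(
    solve_operating_point(target, setup, corr))
  expect_equal(solved$stirrer_speed, setup$stirrer_speed, tolerance = 1e-3)

  solved40 <- suppressWarnings(solve_operating_point(40, setup, corr))
  expect_equal(attr(solved40, "predicted_kla"), 40, tolerance = 0.01)
  expect_error(suppressWarnings(solve_operating_point(1e6, setup, corr)),
               "achievable")
})
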