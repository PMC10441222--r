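test_that("dilution rate sums feed and acid flows over the volume", {
  expect_equal(dilution_rate(0.06, 0, 2), 0.03)
  expect_equal(dilution_rate(0, 0, 2), 0)
  expect_equal(dilution_rate(5.8, 0.2, 200), 0.03)
  expect_error(dilution_rate(0.06, 0, 0), "volume")
})

test_that("specific growth rate recovers mu = D at steady state and mu in batch", {
  # steady chemostat: no biomass change, 1.44 L bled over 24 h at 4.16 g/L
  prev <- make_record(0, 2, 4.16, cum_bleed_l = 0)
  curr <- make_record(24, 2, 4.16, cum_bleed_l = 1.44)
  expect_equal(specific_growth_rate(prev, curr), 0.03, tolerance = 1e-12)

  # no bleed, no growth
  expect_equal(specific_growth_rate(make_record(0, 2, 3),
                                    make_record(10, 2, 3)), 0)

  # exact exponential batch at mu = 0.05 1/h, 2 h sampling: the interval
  # estimator carries only the discretization error of the arithmetic means
  x0 <- 0.5
  prev <- make_record(0, 2, x0)
  curr <- make_record(2, 2, x0 * exp(0.1))
  est <- specific_growth_rate(prev, curr)
  expect_equal(est, (exp(0.1) - 1) / (1 + exp(0.1)))  # closed-form oracle
  expect_lt(abs(est - 0.05) / 0.05, 0.02)

  expect_error(specific_growth_rate(curr, prev), "later")
})

test_that("space-time yields reproduce the published worked examples", {
  expect_equal(round(space_time_yield(4.16, 0.03), 3), 0.125)
  expect_equal(space_time_yield(0, 0.03), 0)
  expect_equal(round(space_time_yield(3.77, 0.03), 3), 0.113)
  expect_equal(round(batch_space_time_yield(35, 310), 3), 0.113)
  expect_equal(round(batch_space_time_yield(22.6, 170), 3), 0.133)
  expect_equal(round(batch_space_time_yield(0.65, 90), 3), 0.007)
  expect_error(batch_space_time_yield(1, 0), "duration")
})

test_that("substrate consumption rate closes the interval mass balance", {
  feed <- feed_composition(msg = 0, glucose = 0)
  # no flows, glucose drops 2 -> 1 g total in 10 h with 5 g mean biomass
  prev <- make_record(0, 1, 5, glucose_gl = 2)
  curr <- make_record(10, 1, 5, glucose_gl = 1)
  expect_equal(specific_consumption_rate(prev, curr, "glucose", feed), 0.02)

  # S_in = S_out and no reactor change gives zero
  fc <- feed_composition(msg = 0, glucose = 1.5)
  prev <- make_record(0, 2, 5, glucose_gl = 1.5)
  curr <- make_record(10, 2, 5, glucose_gl = 1.5,
                      cum_feed_l = 1, cum_bleed_l = 1)
  expect_equal(specific_consumption_rate(prev, curr, "glucose", fc), 0)

  expect_error(specific_consumption_rate(prev, curr, "glucose", feed = NULL),
               "feed")
})

test_that("interval q_S matches the chemostat closed form at steady state", {
  sim <- reference_sim()
  rep <- reference_report()
  feed <- sim$schedule$feed
  D <- sim$schedule$chemostat_D
  # substrate concentration of the total inflow: the substrate-free acid
  # stream (2 % of feed) dilutes the nominal feed concentration
  fd <- 1 / (1 + sim$schedule$acid_fraction)
  q_glc_closed <- D * (feed$glucose * fd - sim$truth$glucose_ss) /
    sim$truth$x_ss
  q_msg_closed <- D * (feed$msg * fd - sim$truth$msg_ss) / sim$truth$x_ss
  expect_equal(summary_mean(rep, "q_glc"), q_glc_closed, tolerance = 0.01)
  expect_equal(summary_mean(rep, "q_msg"), q_msg_closed, tolerance = 0.01)
})

test_that("product formation rate is production-positive and closes the balance", {
  feed <- feed_composition(msg = 0, glucose = 0)
  prev <- make_record(0, 1, 5, trehalose_gl = 0)
  curr <- make_record(10, 1, 5, trehalose_gl = 0.5)
  expect_equal(specific_production_rate(prev, curr, feed = feed), 0.01)
  # constant product, no flows
  prev <- make_record(0, 1, 5, trehalose_gl = 0.3)
  curr <- make_record(10, 1, 5, trehalose_gl = 0.3)
  expect_equal(specific_production_rate(prev, curr, feed = feed), 0)
  # chemostat limit q_P = D * P / x on the reference simulation
  sim <- reference_sim()
  rep <- reference_report()
  q_p_closed <- sim$schedule$chemostat_D * sim$truth$trehalose_ss /
    sim$truth$x_ss
  expect_equal(summary_mean(rep, "q_tre"), q_p_closed, tolerance = 0.01)
})

test_that("yield calculus follows the C-mol arithmetic", {
  expect_equal(biomass_yield(0.03, 0.1), 0.3)
  expect_equal(biomass_yield(0, 0.1), 0)
  expect_equal(biomass_yield(0.06, 0.2), biomass_yield(0.03, 0.1))
  expect_error(biomass_yield(0.03, 0), "q_s")

  expect_equal(trehalose_yield(0.01, 0.1), 0.1052644, tolerance = 1e-6)
  expect_equal(trehalose_yield(0, 0.1), 0)
  # equal C-mol rates give yield 1
  q_tre_g <- cmol_to_mass(0.001, compound_table("trehalose"))
  q_glc_g <- cmol_to_mass(0.001, compound_table("glucose"))
  expect_equal(trehalose_yield(q_tre_g, q_glc_g), 1)

  expect_equal(co2_yield(1, 0.06), 0.5004444, tolerance = 1e-6)
  expect_equal(co2_yield(0, 0.06), 0)

  expect_equal(c_balance(0.5, 0.45, 0.05), 1.0)
  expect_equal(c_balance(0, 0, 0), 0)
  expect_error(c_balance(-0.1, 0.5, 0.1), "non-negative")
})

test_that("gas-phase balances use the molar volume difference form", {
  rec <- list(gas_flow_lh = 30.6, y_co2_in = 0, y_co2_out = 0.005,
              y_o2_in = 0.2095, y_o2_out = 0.2045)
  expect_equal(cer(rec, 2), 3.413045, tolerance = 1e-6)
  expect_equal(our(rec, 2), 3.413045, tolerance = 1e-6)
  expect_equal(our(rec, 1), 2 * our(rec, 2))
  rec0 <- list(gas_flow_lh = 30.6, y_co2_in = 0.004, y_co2_out = 0.004,
               y_o2_in = 0.2, y_o2_out = 0.2)
  expect_equal(cer(rec0, 2), 0)
  expect_equal(our(rec0, 2), 0)
  # linear in the concentration difference
  rec2 <- rec; rec2$y_co2_out <- 0.01
  expect_equal(cer(rec2, 2), 2 * cer(rec, 2))
  expect_error(cer(rec, 0), "volume")

  expect_equal(rq(3, 3.3), 0.909, tolerance = 1e-3)
  expect_equal(rq(0, 3.3), 0)
  expect_error(rq(1, 0), "our")

  expect_equal(q_co2(3.4, 4.16), 0.817, tolerance = 1e-3)
  expect_equal(q_co2(0, 4.16), 0)
  # q * x returns the volumetric rate exactly
  expect_identical(q_co2(3.4, 4.16) * 4.16, 3.4)
  expect_identical(q_o2(3.3, 4.16) * 4.16, 3.3)
})

test_that("steady-state window applies the four-dwell-time rule", {
  s <- sample_table(make_record(c(100, 200, 300), 2, c(4, 4, 4),
                                cum_bleed_l = c(0, 1, 2)))
  out <- steady_state_window(s, chemostat_start = 50, D = 0.03)
  expect_equal(out$time_h, c(200, 300))  # cutoff at 50 + 133.3 h
  out2 <- steady_state_window(s, 97, 1)  # cutoff 101
  expect_equal(out2$time_h, c(200, 300))
  expect_error(steady_state_window(s, 300, 0.03), "cutoff")
  expect_error(steady_state_window(s, 0, 0), "D must")
})

test_that("steady-state summary reports mean and STD percent per parameter", {
  expect_equal(std_percent(c(2, 4)), 47.14045, tolerance = 1e-5)
  expect_equal(std_percent(c(3, 3, 3)), 0)
  expect_equal(std_percent(c(2, 4) * 17), std_percent(c(2, 4)))
  expect_error(std_percent(c(1, -1)), "mean")
  expect_error(std_percent(2), "2 values")

  rep <- reference_report()
  s <- rep$summary
  expect_true(all(c("mu", "q_glc", "q_msg", "q_tre", "cer", "our", "rq",
                    "y_xs", "c_balance") %in% s$parameter))
  expect_equal(attr(s, "n_samples"), nrow(rep$rates) + 1L)
  # a noiseless steady state has essentially zero spread
  expect_lt(max(s$std_pct[s$parameter %in% c("mu", "q_glc", "q_msg")]), 1)
})

test_that("rates are invariant under insertion of an intermediate sample", {
  sim <- reference_sim()
  samples <- sim$samples
  ss <- samples[samples$time_h >= sim$phase_times[["chemostat_start"]] +
                  4 / sim$schedule$chemostat_D, ]
  # coarse: every second steady-state sample; fine: all of them
  coarse <- sample_table(ss[seq(1, nrow(ss), by = 2), ])
  fine <- sample_table(ss)
  r_coarse <- interval_rates(coarse, feed = sim$schedule$feed)
  r_fine <- interval_rates(fine, feed = sim$schedule$feed)
  for (p in c("mu", "q_glc", "q_msg", "q_tre", "D")) {
    expect_equal(mean(r_coarse[[p]]), mean(r_fine[[p]]), tolerance = 0.01)
  }
})
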