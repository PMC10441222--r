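#' Kinetic parameters of the synthetic cultivation
#'
#' Dual-substrate Monod kinetics with a constant-rate extracellular
#' trehalose drain. The simulator ties CO2 production to the carbon balance
#' (CO2 carbon = consumed substrate carbon - biomass carbon - trehalose
#' carbon) and O2 consumption to CO2 via a fixed respiratory quotient, so
#' the generated data conserve carbon by construction.
#'
#' Defaults emulate a culture that reaches roughly 4.2 g/L dry cell weight
#' on the 9.5 g/L MSG + 4.5 g/L glucose feed (overall biomass yield about
#' 0.30 g/g): the per-substrate yields are split so glucose and MSG are
#' drawn down in proportion to their feed ratio.
#'
#' @param mu_max Maximum specific growth rate in 1/h.
#' @param ks_glc,ks_msg Monod half-saturation constants in g/L.
#' @param y_xs_glc,y_xs_msg Biomass yields on each substrate in g/g (both
#'   substrates are co-consumed; the overall yield is
#'   `1 / (1/y_xs_glc + 1/y_xs_msg)`).
#' @param q_tre_const Constant specific trehalose formation rate in g/g/h.
#' @param rq_true True respiratory quotient (mol CO2 per mol O2).
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   measurement noise; 0 disables noise.
#' @param seed Integer seed for the measurement noise.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(mu_max = 0.08, ks_glc = 0.05, ks_msg = 0.05,
                           y_xs_glc = 0.933, y_xs_msg = 0.442,
                           q_tre_const = 0.002, rq_true = 1.0,
                           noise_cv = 0, seed = 1L) {
  vals <- c(mu_max, ks_glc, ks_msg, y_xs_glc, y_xs_msg, q_tre_const, rq_true)
  if (any(vals <= 0)) stop("kinetic parameters must be positive")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(
    list(mu_max = mu_max, ks_glc = ks_glc, ks_msg = ks_msg,
         y_xs_glc = y_xs_glc, y_xs_msg = y_xs_msg,
         q_tre_const = q_tre_const, rq_true = rq_true,
         noise_cv = noise_cv, seed = as.integer(seed)),
    class = "kinetic_params"
  )
}

#' Process schedule of the three-phase cultivation
#'
#' Batch on the diluted medium, exponential fed-batch ramp at a set specific
#' growth rate until the target volume is reached, then chemostat at a fixed
#' dilution rate with the broth level held by an immersion-tube bleed.
#' Defaults mirror the benchtop process: 1.5 L batch (2 g/L MSG, 1 g/L
#' glucose), feed ramp starting at 14.8 g/h with mu_set = 0.035 1/h up to
#' 2 L, then D = 0.03 1/h on 9.5 g/L MSG + 4.5 g/L glucose feed, 24 h
#' sampling.
#'
#' @param batch_volume Batch starting volume in L.
#' @param batch_glc,batch_msg Batch medium concentrations in g/L.
#' @param x0 Inoculation biomass concentration in g/L. The default is set so
#'   the biomass the batch hands over matches the published feed-ramp start:
#'   ramp start, batch carbon load and mu_set jointly determine the biomass
#'   a consistent exponential fed-batch must begin with (see the vignette).
#' @param feed_start_rate Initial feed mass flow in g/h (feed density taken
#'   as 1000 g/L).
#' @param feed_mu_set Set specific growth rate of the exponential ramp in
#'   1/h.
#' @param target_volume Volume at which the continuous phase starts, in L.
#' @param chemostat_D Chemostat dilution rate in 1/h.
#' @param chemostat_duration Length of the continuous phase in h.
#' @param feed A [feed_composition()].
#' @param acid_fraction pH-control acid flow as a fraction of the feed flow.
#' @param sample_interval Sampling interval in h.
#' @param weekend_gap If `TRUE`, drop samples falling on days 6 and 7 of
#'   each week to exercise irregular sampling intervals.
#' @param offgas_interval Off-gas logging interval in h.
#' @return An object of class `process_schedule`.
#' @export
process_schedule <- function(batch_volume = 1.5, batch_glc = 1,
                             batch_msg = 2, x0 = 0.3,
                             feed_start_rate = 14.8, feed_mu_set = 0.035,
                             target_volume = 2, chemostat_D = 0.03,
                             chemostat_duration = 300,
                             feed = feed_composition(),
                             acid_fraction = 0.02,
                             sample_interval = 24, weekend_gap = FALSE,
                             offgas_interval = 1) {
  if (target_volume <= batch_volume) {
    stop("target_volume must exceed batch_volume")
  }
  if (chemostat_D <= 0) stop("chemostat_D must be > 0")
  stopifnot(inherits(feed, "feed_composition"))
  structure(
    list(batch_volume = batch_volume, batch_glc = batch_glc,
         batch_msg = batch_msg, x0 = x0,
         feed_start_rate = feed_start_rate, feed_mu_set = feed_mu_set,
         target_volume = target_volume, chemostat_D = chemostat_D,
         chemostat_duration = chemostat_duration, feed = feed,
         acid_fraction = acid_fraction, sample_interval = sample_interval,
         weekend_gap = weekend_gap, offgas_interval = offgas_interval),
    class = "process_schedule"
  )
}

#' Scale presets for the three reactor scales
#'
#' Operating points of the benchtop (2 L), lab (20 L) and pilot (200 L)
#' setups: working/total volume, sparger, stirrer speed, gas flow, and the
#' matching feed ramp start. Impeller diameters are back-calculated from the
#' tip speeds at the listed stirrer speeds; power numbers assume Rushton-type
#' turbines (Np = 5 per impeller, two mounted).
#'
#' @param scale One of `"2L"`, `"20L"`, `"200L"`.
#' @return A list with elements `setup` (a [reactor_setup()]), `schedule`
#'   (a [process_schedule()]), and `kla` (the scale's target kLa in 1/h).
#' @export
scale_preset <- function(scale = c("2L", "20L", "200L")) {
  scale <- match.arg(scale)
  imp <- function(d) impeller_spec(d, power_number = 5, count = 2)
  switch(scale,
    "2L" = list(
      setup = reactor_setup(0.122, 3, 2, imp(0.0522), sparger = "micro",
                            stirrer_speed = 355, gas_flow = 0.51),
      schedule = process_schedule(batch_volume = 1.5, target_volume = 2,
                                  feed_start_rate = 14.8),
      kla = 38.8),
    "20L" = list(
      setup = reactor_setup(0.239, 30, 20, imp(0.0952), sparger = "ring",
                            stirrer_speed = 285, gas_flow = 5.1,
                            overpressure = 0.2),
      schedule = process_schedule(batch_volume = 15, target_volume = 20,
                                  feed_start_rate = 148),
      kla = 40.5),
    "200L" = list(
      setup = reactor_setup(0.471, 300, 200, imp(0.2008), sparger = "ring",
                            stirrer_speed = 117, gas_flow = 37.5,
                            overpressure = 0.3),
      schedule = process_schedule(batch_volume = 150, target_volume = 200,
                                  feed_start_rate = 1400),
      kla = 41.1)
  )
}

# measurement layer: sampling table, off-gas table and gassing-out trace
# drawn from the true trajectory, with multiplicative Gaussian noise on the
# measured concentrations and on the off-gas concentration differences
.measurements <- function(states, schedule, setup, kla, t_end,
                          noise_cv, seed, viability_pct) {
  s_times <- seq(0, t_end, by = schedule$sample_interval)
  if (schedule$weekend_gap) {
    day <- floor(s_times / 24) %% 7
    s_times <- s_times[!day %in% c(5, 6)]
  }
  at <- function(col, tt) stats::approx(states$time_h, states[[col]],
                                        xout = tt, rule = 2)$y
  set.seed(seed)
  jitter <- function(v) {
    if (noise_cv == 0) v
    else pmax(v * (1 + stats::rnorm(length(v), sd = noise_cv)), 0)
  }
  samples <- data.frame(
    time_h = s_times,
    volume_l = at("V", s_times),
    dcw_gl = jitter(at("x_gl", s_times)),
    od600 = jitter(at("x_gl", s_times) * 0.586),
    glucose_gl = jitter(at("glucose_gl", s_times)),
    msg_gl = jitter(at("msg_gl", s_times)),
    trehalose_gl = jitter(at("trehalose_gl", s_times)),
    cum_feed_l = at("cumF", s_times),
    cum_acid_l = at("cumA", s_times),
    cum_bleed_l = at("cumB", s_times)
  )
  if (!is.null(viability_pct)) {
    samples$viability_pct <- pmin(jitter(rep(viability_pct,
                                             length(s_times))), 100)
  }
  samples <- sample_table(samples)

  og_times <- seq(0, t_end, by = schedule$offgas_interval)
  qg_lh <- setup$gas_flow * 60
  d_co2 <- jitter(at("cer_mmol_l_h", og_times) / 1000 * at("V", og_times) *
                    MOLAR_VOLUME / qg_lh)
  d_o2 <- jitter(at("our_mmol_l_h", og_times) / 1000 * at("V", og_times) *
                   MOLAR_VOLUME / qg_lh)
  y_co2_in <- 0.0004
  offgas <- offgas_table(data.frame(
    time_h = og_times,
    y_o2_in = setup$inlet_o2_fraction,
    y_o2_out = pmax(setup$inlet_o2_fraction - d_o2, 0),
    y_co2_in = y_co2_in,
    y_co2_out = pmin(y_co2_in + d_co2, 1),
    gas_flow_lh = qg_lh
  ))

  trace <- simulate_do_step(kla, noise_sd = if (noise_cv > 0) 1 else 0,
                            seed = seed + 1L)
  list(samples = samples, offgas = offgas, do_trace = trace)
}

#' Redraw the measurement layer of a simulation
#'
#' Keeps the true (deterministic) process trajectory of an existing
#' simulation and redraws only the measurement noise — useful for
#' seed-sweep studies of estimator precision without re-integrating the
#' ODE system.
#'
#' @param sim A [simulate_cultivation()] result.
#' @param noise_cv Measurement noise CV; defaults to the simulation's value.
#' @param seed Integer seed for the new noise realization.
#' @return A `sim_output` with new `samples`, `offgas` and `do_trace`.
#' @export
resample_measurements <- function(sim, noise_cv = sim$kinetics$noise_cv,
                                  seed) {
  stopifnot(inherits(sim, "sim_output"))
  meas <- .measurements(sim$states, sim$schedule, sim$setup, sim$kla,
                        unname(sim$phase_times[["end"]]), noise_cv,
                        as.integer(seed),
                        if ("viability_pct" %in% names(sim$samples)) 91 else NULL)
  sim$samples <- meas$samples
  sim$offgas <- meas$offgas
  sim$do_trace <- meas$do_trace
  sim$kinetics$noise_cv <- noise_cv
  sim$kinetics$seed <- as.integer(seed)
  sim
}

# carbon content per gram [C-mol/g]
.cc <- function() {
  list(glc = 6 / 180.16, msg = 5 / 169.11, tre = 12 / 342.30,
       x = biomass_composition()$carbon_fraction / 12.011)
}

# instantaneous kinetic rates from concentrations
.kin_rates <- function(x, g, m, kin) {
  mu <- kin$mu_max * (g / (kin$ks_glc + g)) * (m / (kin$ks_msg + m))
  mu <- max(mu, 0)
  list(mu = mu, q_glc = mu / kin$y_xs_glc, q_msg = mu / kin$y_xs_msg,
       q_tre = kin$q_tre_const)
}

# ODE right-hand side on total amounts; parms carries the phase controls
.sim_derivs <- function(t, y, parms) {
  kin <- parms$kin; cc <- parms$cc
  X <- y[1]; G <- max(y[2], 0); M <- max(y[3], 0); P <- y[4]; V <- y[5]
  gl <- G / V; ml <- M / V
  kr <- .kin_rates(X / V, gl, ml, kin)
  feed <- parms$feed_fun(t, V)           # L/h
  acid <- parms$acid_fraction * feed     # L/h
  bleed <- if (parms$chemostat) feed + acid else 0
  r_cons_c <- X * (kr$q_glc * cc$glc + kr$q_msg * cc$msg)  # C-mol/h
  r_x_c <- kr$mu * X * cc$x
  r_tre_c <- kr$q_tre * X * cc$tre
  r_co2 <- max(r_cons_c - r_x_c - r_tre_c, 0)              # mol CO2/h
  r_o2 <- r_co2 / kin$rq_true
  fc <- parms$feed_comp
  dX <- kr$mu * X - bleed * X / V
  dG <- -kr$q_glc * X + feed * fc$glucose - bleed * gl
  dM <- -kr$q_msg * X + feed * fc$msg - bleed * ml
  dP <- kr$q_tre * X + feed * fc$trehalose - bleed * P / V
  dV <- feed + acid - bleed
  d_bleed_c <- bleed * (X / V * cc$x + gl * cc$glc + ml * cc$msg +
                          P / V * cc$tre)
  list(c(dX, dG, dM, dP, dV, feed, acid, bleed, r_co2, r_o2, d_bleed_c))
}

#' Simulate the three-phase cultivation
#'
#' Integrates the batch, exponential fed-batch and chemostat phases of the
#' cultivation with [deSolve::lsoda()] on total-amount state variables
#' (biomass, glucose, MSG, trehalose, volume, cumulative feed/acid/bleed,
#' cumulative CO2/O2, bled carbon). The batch ends when either substrate is
#' nearly exhausted; the fed-batch ends when the target volume is reached;
#' the chemostat holds the volume by a bleed equal to the total inflow. Gas
#' production is tied to the carbon balance, so the simulation conserves
#' carbon up to integrator tolerance; off-gas mole fractions follow from the
#' gas flow and the molar volume 22.414 L/mol. Multiplicative Gaussian
#' measurement noise (CV `kinetics$noise_cv`, seeded) is applied to the
#' concentration measurements and to the off-gas concentration differences.
#'
#' Dissolved oxygen is reported diagnostically from the quasi-steady balance
#' `DO = 100 * (1 - OUR / (kla * c_star))` and does not feed back on growth:
#' the simulated process is assumed oxygen-sufficient, which is what a
#' correctly executed constant-kLa scale-up is designed to guarantee.
#'
#' @param schedule A [process_schedule()].
#' @param kinetics A [kinetic_params()].
#' @param setup A [reactor_setup()]; supplies the gas flow and inlet O2
#'   fraction for off-gas generation.
#' @param kla Operating kLa in 1/h; used for the gassing-out trace and the
#'   diagnostic DO profile.
#' @param c_star_mmol_l Oxygen solubility at process conditions in mmol/L
#'   (configurable constant; not a literature value for the medium).
#' @param viability_pct Constant viability level tagged onto the sample
#'   table (noise applies); `NULL` omits the column.
#' @return An object of class `sim_output`: list with `samples`
#'   (a [sample_table()]), `offgas` (an [offgas_table()]), `do_trace`
#'   (a [do_trace()]), `truth` (realized steady state and generating
#'   parameters), `states` (fine-grid trajectory tibble), `phase_times`
#'   (named vector: batch_end, chemostat_start, end), and `washout` flag.
#' @examples
#' sim <- simulate_cultivation()
#' sim$truth$x_ss
#' @export
simulate_cultivation <- function(schedule = process_schedule(),
                                 kinetics = kinetic_params(),
                                 setup = scale_preset("2L")$setup,
                                 kla = 40, c_star_mmol_l = 0.25,
                                 viability_pct = 91) {
  cc <- .cc()
  fc <- schedule$feed
  y0 <- c(X = schedule$x0 * schedule$batch_volume,
          G = schedule$batch_glc * schedule$batch_volume,
          M = schedule$batch_msg * schedule$batch_volume,
          P = 0, V = schedule$batch_volume,
          cumF = 0, cumA = 0, cumB = 0, cumCO2 = 0, cumO2 = 0, cumBC = 0)
  base_parms <- list(kin = kinetics, cc = cc, feed_comp = fc,
                     acid_fraction = schedule$acid_fraction)
  grid <- 0.25

  # -- batch: no flows, stop when either substrate is nearly exhausted
  p1 <- c(base_parms, list(feed_fun = function(t, V) 0, chemostat = FALSE))
  p1$acid_fraction <- 0
  root_batch <- function(t, y, parms) {
    min(y[2] / y[5] - 0.05, y[3] / y[5] - 0.05)
  }
  out1 <- deSolve::lsoda(y0, seq(0, 400, by = grid), .sim_derivs, p1,
                         rootfunc = root_batch, rtol = 1e-8, atol = 1e-8)
  t_batch_end <- unname(out1[nrow(out1), 1L])

  # -- fed-batch: exponential ramp at mu_set, stop at target volume
  f0 <- schedule$feed_start_rate / 1000    # g/h -> L/h at 1000 g/L
  mu_set <- schedule$feed_mu_set
  p2 <- c(base_parms,
          list(feed_fun = function(t, V) f0 * exp(mu_set * (t - t_batch_end)),
               chemostat = FALSE))
  root_fb <- function(t, y, parms) y[5] - schedule$target_volume
  out2 <- deSolve::lsoda(out1[nrow(out1), -1L],
                         seq(t_batch_end, t_batch_end + 400, by = grid),
                         .sim_derivs, p2, rootfunc = root_fb,
                         rtol = 1e-8, atol = 1e-8)
  t_chemo_start <- unname(out2[nrow(out2), 1L])

  # -- chemostat: inflow fixed by D, bleed holds the volume
  D <- schedule$chemostat_D
  f_chemo <- D * schedule$target_volume / (1 + schedule$acid_fraction)
  p3 <- c(base_parms,
          list(feed_fun = function(t, V) f_chemo, chemostat = TRUE))
  t_end <- t_chemo_start + schedule$chemostat_duration
  out3 <- deSolve::lsoda(out2[nrow(out2), -1L],
                         seq(t_chemo_start, t_end, by = grid),
                         .sim_derivs, p3, rtol = 1e-8, atol = 1e-8)

  traj <- rbind(out1, out2[-1L, , drop = FALSE], out3[-1L, , drop = FALSE])
  states <- tibble::as_tibble(as.data.frame(traj))
  names(states)[1L] <- "time_h"

  # derived instantaneous quantities along the trajectory
  gl <- states$G / states$V; ml <- states$M / states$V
  xl <- states$X / states$V
  mu_t <- kinetics$mu_max * (gl / (kinetics$ks_glc + gl)) *
    (ml / (kinetics$ks_msg + ml))
  r_co2 <- pmax(states$X * (mu_t / kinetics$y_xs_glc * cc$glc +
                              mu_t / kinetics$y_xs_msg * cc$msg) -
                  mu_t * states$X * cc$x -
                  kinetics$q_tre_const * states$X * cc$tre, 0)
  r_o2 <- r_co2 / kinetics$rq_true
  states$x_gl <- xl; states$glucose_gl <- gl; states$msg_gl <- ml
  states$trehalose_gl <- states$P / states$V
  states$mu <- mu_t
  states$cer_mmol_l_h <- r_co2 / states$V * 1000
  states$our_mmol_l_h <- r_o2 / states$V * 1000
  states$do_pct <- pmax(100 * (1 - states$our_mmol_l_h / (kla * c_star_mmol_l)), 0)

  meas <- .measurements(states, schedule, setup, kla, t_end,
                        kinetics$noise_cv, kinetics$seed, viability_pct)
  samples <- meas$samples
  offgas <- meas$offgas
  trace <- meas$do_trace

  # -- realized steady-state truth from the final state
  fin <- states[nrow(states), ]
  mu_ss <- fin$mu
  truth <- list(
    kinetics = kinetics, D = D,
    x_ss = fin$x_gl, glucose_ss = fin$glucose_gl, msg_ss = fin$msg_gl,
    trehalose_ss = fin$trehalose_gl,
    mu = mu_ss,
    q_glc = mu_ss / kinetics$y_xs_glc,
    q_msg = mu_ss / kinetics$y_xs_msg,
    q_tre = kinetics$q_tre_const,
    cer = fin$cer_mmol_l_h, our = fin$our_mmol_l_h,
    rq = kinetics$rq_true
  )
  # a culture that cannot grow at D is being diluted out: realized mu stays
  # pinned below the dilution rate instead of converging to it
  washout <- fin$mu < 0.95 * D
  if (washout) warning("chemostat washed out: D exceeds the achievable growth rate")

  structure(
    list(samples = samples, offgas = offgas, do_trace = trace,
         truth = truth, states = states,
         phase_times = c(batch_end = t_batch_end,
                         chemostat_start = t_chemo_start, end = t_end),
         schedule = schedule, kinetics = kinetics, setup = setup,
         kla = kla, washout = washout),
    class = "sim_output"
  )
}

#' @export
print.sim_output <- function(x, ...) {
  pt <- x$phase_times
  cat(sprintf(
    "<sim_output> batch 0-%.1f h, fed-batch to %.1f h, chemostat to %.1f h (D = %g 1/h)\n  steady state: x = %.3f g/L, mu = %.4f 1/h%s\n",
    pt["batch_end"], pt["chemostat_start"], pt["end"],
    x$schedule$chemostat_D, x$truth$x_ss, x$truth$mu,
    if (x$washout) " [WASHOUT]" else ""))
  invisible(x)
}

#' Write simulator fixtures to disk
#'
#' Emits the CSV file set the analysis pipeline consumes — `samples.csv`,
#' `offgas.csv`, `do_trace.csv` — plus `truth.json` holding the generating
#' parameters and realized steady state.
#'
#' @param sim A [simulate_cultivation()] result.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
emit_fixtures <- function(sim, out_dir) {
  stopifnot(inherits(sim, "sim_output"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- c(samples = file.path(out_dir, "samples.csv"),
             offgas = file.path(out_dir, "offgas.csv"),
             do_trace = file.path(out_dir, "do_trace.csv"),
             truth = file.path(out_dir, "truth.json"))
  utils::write.csv(as.data.frame(sim$samples), paths["samples"],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(sim$offgas), paths["offgas"],
                   row.names = FALSE)
  utils::write.csv(data.frame(time_h = sim$do_trace$time_h,
                              do_percent = sim$do_trace$do_percent),
                   paths["do_trace"], row.names = FALSE)
  truth <- sim$truth
  truth$kinetics <- unclass(truth$kinetics)
  truth$phase_times <- as.list(sim$phase_times)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
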