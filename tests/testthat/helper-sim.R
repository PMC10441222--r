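# One noiseless reference simulation, built once and shared across test
# files; the study conditions are the package defaults (benchtop process,
# D = 0.03 1/h, 9.5 g/L MSG + 4.5 g/L glucose feed).
.sim_cache <- new.env(parent = emptyenv())

reference_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- simulate_cultivation()
  }
  .sim_cache$sim
}

reference_report <- function() {
  if (is.null(.sim_cache$report)) {
    sim <- reference_sim()
    .sim_cache$report <- run_pipeline(
      sim$samples, sim$offgas, sim$schedule$feed,
      chemostat_start = sim$phase_times[["chemostat_start"]],
      D = sim$schedule$chemostat_D)
  }
  .sim_cache$report
}

summary_mean <- function(report, param) {
  s <- report$summary
  s$mean[s$parameter == param]
}

# two consecutive steady-state sampling rows with the given fields
make_record <- function(time_h, volume_l, dcw_gl, glucose_gl = 0,
                        msg_gl = 0, trehalose_gl = 0, cum_feed_l = 0,
                        cum_acid_l = 0, cum_bleed_l = 0) {
  data.frame(time_h = time_h, volume_l = volume_l, dcw_gl = dcw_gl,
             od600 = dcw_gl * 0.586, glucose_gl = glucose_gl,
             msg_gl = msg_gl, trehalose_gl = trehalose_gl,
             cum_feed_l = cum_feed_l, cum_acid_l = cum_acid_l,
             cum_bleed_l = cum_bleed_l)
}
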