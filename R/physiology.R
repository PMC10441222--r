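#' Feed composition
#'
#' Carbon-source concentrations of the feed medium. The defaults are the
#' 5-fold concentrated defined medium used from fed-batch onwards: 9.5 g/L
#' monosodium glutamate and 4.5 g/L D-glucose.
#'
#' @param msg MSG concentration in g/L.
#' @param glucose Glucose concentration in g/L.
#' @param trehalose Trehalose concentration in g/L (normally 0).
#' @return An object of class `feed_composition`.
#' @export
feed_composition <- function(msg = 9.5, glucose = 4.5, trehalose = 0) {
  if (msg < 0 || glucose < 0 || trehalose < 0) {
    stop("feed concentrations must be non-negative")
  }
  structure(list(msg = msg, glucose = glucose, trehalose = trehalose),
            class = "feed_composition")
}

#' @export
print.feed_composition <- function(x, ...) {
  cat(sprintf("<feed_composition> %g g/L MSG, %g g/L glucose, %g g/L trehalose\n",
              x$msg, x$glucose, x$trehalose))
  invisible(x)
}

# required columns of a sample table
.sample_cols <- c("time_h", "volume_l", "dcw_gl", "od600", "glucose_gl",
                  "msg_gl", "trehalose_gl", "cum_feed_l", "cum_acid_l",
                  "cum_bleed_l")

#' Validate a cultivation sampling table
#'
#' A sample table holds one row per sampling time point: broth volume, dry
#' cell weight, optical density, substrate and product concentrations, and
#' the cumulative feed, acid and bleed volumes read off the balances. A
#' `glutamate_gl` column (photometric glutamic acid) is converted to
#' `msg_gl` via [msg_from_glutamate()] on entry. A `viability_pct` column is
#' optional and carried through untouched.
#'
#' @param df A data frame with columns `time_h`, `volume_l`, `dcw_gl`,
#'   `od600`, `glucose_gl`, `msg_gl` (or `glutamate_gl`), `trehalose_gl`,
#'   `cum_feed_l`, `cum_acid_l`, `cum_bleed_l`.
#' @return A validated tibble of class `sample_table`.
#' @export
sample_table <- function(df) {
  df <- tibble::as_tibble(df)
  if ("glutamate_gl" %in% names(df) && !"msg_gl" %in% names(df)) {
    df$msg_gl <- msg_from_glutamate(df$glutamate_gl)
    df$glutamate_gl <- NULL
  }
  miss <- setdiff(.sample_cols, names(df))
  if (length(miss)) stop("missing sample columns: ", paste(miss, collapse = ", "))
  if (any(df$time_h < 0)) stop("time_h must be >= 0")
  if (nrow(df) > 1L && any(diff(df$time_h) <= 0)) {
    stop("time_h must be strictly increasing")
  }
  conc <- c("dcw_gl", "glucose_gl", "msg_gl", "trehalose_gl")
  for (cl in conc) {
    if (any(df[[cl]] < 0)) stop(cl, " must be non-negative")
  }
  for (cl in c("cum_feed_l", "cum_acid_l", "cum_bleed_l")) {
    if (nrow(df) > 1L && any(diff(df[[cl]]) < -1e-9)) {
      stop(cl, " must be non-decreasing")
    }
  }
  class(df) <- c("sample_table", class(tibble::tibble()))
  df
}

.offgas_cols <- c("time_h", "y_o2_in", "y_o2_out", "y_co2_in", "y_co2_out",
                  "gas_flow_lh")

#' Validate an off-gas table
#'
#' One row per off-gas reading: O2 and CO2 mole fractions at inlet and
#' outlet, and the inlet gas flow at norm conditions.
#'
#' @param df A data frame with columns `time_h`, `y_o2_in`, `y_o2_out`,
#'   `y_co2_in`, `y_co2_out`, `gas_flow_lh`.
#' @return A validated tibble of class `offgas_table`.
#' @export
offgas_table <- function(df) {
  df <- tibble::as_tibble(df)
  miss <- setdiff(.offgas_cols, names(df))
  if (length(miss)) stop("missing off-gas columns: ", paste(miss, collapse = ", "))
  fr <- c("y_o2_in", "y_o2_out", "y_co2_in", "y_co2_out")
  for (cl in fr) {
    if (any(df[[cl]] < 0 | df[[cl]] > 1)) stop(cl, " must lie in [0, 1]")
  }
  if (any(df$gas_flow_lh < 0)) stop("gas_flow_lh must be >= 0")
  if (nrow(df) > 1L && any(diff(df$time_h) <= 0)) {
    stop("time_h must be strictly increasing")
  }
  class(df) <- c("offgas_table", class(tibble::tibble()))
  df
}

#' Dilution rate
#'
#' @param feed_flow Feed flow in L/h.
#' @param acid_flow pH-control acid flow in L/h (counts toward dilution but
#'   carries no substrate).
#' @param volume Working volume in L; positive.
#' @return Dilution rate `(F_feed + F_acid) / V` in 1/h.
#' @examples
#' dilution_rate(0.06, 0, 2)  # 0.03 1/h
#' @export
dilution_rate <- function(feed_flow, acid_flow, volume) {
  if (any(volume <= 0)) stop("volume must be > 0")
  if (any(feed_flow < 0) || any(acid_flow < 0)) stop("flows must be >= 0")
  (feed_flow + acid_flow) / volume
}

#' Specific growth rate over a sampling interval
#'
#' Interval-wise growth rate accounting for the biomass continuously lost
#' through the bleed:
#' `mu = (dX + dV_bleed * x_bar) / (X_bar * dt)`
#' where `X = x * V` is total biomass in the broth, `x_bar` and `X_bar` are
#' the arithmetic means of concentration and total over the interval, and
#' `dV_bleed` is the bleed volume removed. At chemostat steady state the
#' broth term vanishes and the bleed term recovers `mu = D`.
#'
#' @param prev,curr One-row data frames (or lists) with fields `time_h`,
#'   `volume_l`, `dcw_gl`, `cum_bleed_l` for consecutive sampling points.
#' @return Specific growth rate in 1/h.
#' @export
specific_growth_rate <- function(prev, curr) {
  dt <- curr$time_h - prev$time_h
  if (dt <= 0) stop("curr must be later than prev")
  if (prev$dcw_gl <= 0 || curr$dcw_gl <= 0) stop("dcw must be > 0 at both points")
  x_tot_prev <- prev$dcw_gl * prev$volume_l
  x_tot_curr <- curr$dcw_gl * curr$volume_l
  x_bar <- (prev$dcw_gl + curr$dcw_gl) / 2
  x_tot_bar <- (x_tot_prev + x_tot_curr) / 2
  if (x_tot_bar == 0) stop("mean total biomass is zero")
  dv_bleed <- curr$cum_bleed_l - prev$cum_bleed_l
  ((x_tot_curr - x_tot_prev) + dv_bleed * x_bar) / (x_tot_bar * dt)
}

#' Biomass space-time yield of a continuous process
#'
#' @param dcw Dry cell weight concentration in g/L.
#' @param D Dilution rate in 1/h.
#' @return Volumetric biomass productivity `x * D` in g/L/h.
#' @examples
#' space_time_yield(4.16, 0.03)  # 0.125 g/L/h
#' @export
space_time_yield <- function(dcw, D) {
  if (any(dcw < 0) || any(D < 0)) stop("inputs must be non-negative")
  dcw * D
}

#' Average biomass space-time yield of a batch or fed-batch process
#'
#' @param final_titer Final biomass titer in g/L.
#' @param duration Fermentation time in h; positive.
#' @return `final_titer / duration` in g/L/h.
#' @examples
#' batch_space_time_yield(35, 310)  # 0.113 g/L/h
#' @export
batch_space_time_yield <- function(final_titer, duration) {
  if (any(duration <= 0)) stop("duration must be > 0")
  final_titer / duration
}

# interval flow volumes between two sampling rows
.interval_flows <- function(prev, curr) {
  list(feed = curr$cum_feed_l - prev$cum_feed_l,
       acid = curr$cum_acid_l - prev$cum_acid_l,
       bleed = curr$cum_bleed_l - prev$cum_bleed_l)
}

#' Specific substrate consumption rate over a sampling interval
#'
#' Mass balance on one substrate between two sampling points, with a
#' consumption-positive sign convention:
#' `q_S = (dS_reactor + S_in - S_out) / (dt * X_bar)` where
#' `dS_reactor = S(prev) - S(curr)` in grams of broth content, `S_in` is the
#' substrate supplied with the feed and `S_out` the substrate discharged via
#' the bleed (mean of the bounding broth concentrations times bleed volume).
#' Acid additions are substrate-free.
#'
#' @param prev,curr One-row data frames for consecutive sampling points.
#' @param substrate `"glucose"` or `"msg"`; selects the concentration column
#'   and the feed concentration.
#' @param feed A [feed_composition()].
#' @return Specific consumption rate in g/g/h.
#' @export
specific_consumption_rate <- function(prev, curr,
                                      substrate = c("glucose", "msg"),
                                      feed = feed_composition()) {
  substrate <- match.arg(substrate)
  if (!inherits(feed, "feed_composition")) stop("feed composition is required")
  dt <- curr$time_h - prev$time_h
  if (dt <= 0) stop("curr must be later than prev")
  col <- paste0(substrate, "_gl")
  fl <- .interval_flows(prev, curr)
  s_reactor <- prev[[col]] * prev$volume_l - curr[[col]] * curr$volume_l
  s_in <- feed[[substrate]] * fl$feed
  s_out <- (prev[[col]] + curr[[col]]) / 2 * fl$bleed
  x_tot_bar <- (prev$dcw_gl * prev$volume_l + curr$dcw_gl * curr$volume_l) / 2
  if (x_tot_bar <= 0) stop("mean total biomass must be > 0")
  (s_reactor + s_in - s_out) / (dt * x_tot_bar)
}

#' Specific product formation rate over a sampling interval
#'
#' Mass balance for an extracellular product (trehalose), production-positive:
#' `q_P = (dP_reactor + P_out - P_in) / (dt * X_bar)` with
#' `dP_reactor = P(curr) - P(prev)`.
#'
#' @inheritParams specific_consumption_rate
#' @param product Concentration column stem; default `"trehalose"`.
#' @return Specific production rate in g/g/h.
#' @export
specific_production_rate <- function(prev, curr, product = "trehalose",
                                     feed = feed_composition()) {
  dt <- curr$time_h - prev$time_h
  if (dt <= 0) stop("curr must be later than prev")
  col <- paste0(product, "_gl")
  fl <- .interval_flows(prev, curr)
  p_reactor <- curr[[col]] * curr$volume_l - prev[[col]] * prev$volume_l
  feed_conc <- if (product %in% names(feed)) feed[[product]] else 0
  p_in <- feed_conc * fl$feed
  p_out <- (prev[[col]] + curr[[col]]) / 2 * fl$bleed
  x_tot_bar <- (prev$dcw_gl * prev$volume_l + curr$dcw_gl * curr$volume_l) / 2
  if (x_tot_bar <= 0) stop("mean total biomass must be > 0")
  (p_reactor + p_out - p_in) / (dt * x_tot_bar)
}

#' Biomass yield on total substrate
#'
#' @param mu Specific growth rate in 1/h.
#' @param q_s_total Total specific substrate consumption rate in g/g/h;
#'   positive.
#' @return Yield `mu / q_S` in g biomass per g substrate.
#' @export
biomass_yield <- function(mu, q_s_total) {
  if (any(q_s_total <= 0)) stop("q_s_total must be > 0")
  mu / q_s_total
}

# C-mol-specific substrate rate from gram-based glucose and MSG rates
.q_s_cmol <- function(q_glc, q_msg) {
  mass_to_cmol(q_glc, compound_table("glucose")) +
    mass_to_cmol(q_msg, compound_table("msg"))
}

#' Trehalose yield on substrate in C-mol per C-mol
#'
#' Both rates are converted to carbon moles (trehalose: 12 C, 342.30 g/mol;
#' substrate as glucose + MSG) before dividing.
#'
#' @param q_tre Specific trehalose production rate in g/g/h.
#' @param q_glc,q_msg Specific substrate consumption rates in g/g/h; their
#'   combined C-mol rate must be positive.
#' @return Yield in C-mol trehalose per C-mol substrate.
#' @export
trehalose_yield <- function(q_tre, q_glc, q_msg = 0) {
  qs <- .q_s_cmol(q_glc, q_msg)
  if (any(qs <= 0)) stop("substrate rate must be > 0")
  mass_to_cmol(q_tre, compound_table("trehalose")) / qs
}

#' Carbon evolution rate from off-gas data
#'
#' `CER = (Qg / V) * (1 / Vm) * (y_CO2,out - y_CO2,in) * 1000` in mmol/L/h,
#' with Vm = 22.414 L/mol.
#'
#' @param record One-row data frame (or list) with `gas_flow_lh`, `y_co2_in`,
#'   `y_co2_out`.
#' @param volume Working volume in L; positive.
#' @return CER in mmol CO2 per L broth per h.
#' @export
cer <- function(record, volume) {
  if (any(volume <= 0)) stop("volume must be > 0")
  (record$gas_flow_lh / volume) / MOLAR_VOLUME *
    (record$y_co2_out - record$y_co2_in) * 1000
}

#' Oxygen uptake rate from off-gas data
#'
#' `OUR = (Qg / V) * (1 / Vm) * (y_O2,in - y_O2,out) * 1000` in mmol/L/h,
#' reported positive for consumption.
#'
#' @param record One-row data frame (or list) with `gas_flow_lh`, `y_o2_in`,
#'   `y_o2_out`.
#' @param volume Working volume in L; positive.
#' @return OUR in mmol O2 per L broth per h.
#' @export
our <- function(record, volume) {
  if (any(volume <= 0)) stop("volume must be > 0")
  (record$gas_flow_lh / volume) / MOLAR_VOLUME *
    (record$y_o2_in - record$y_o2_out) * 1000
}

#' Respiratory quotient
#'
#' @param cer Carbon evolution rate in mmol/L/h.
#' @param our Oxygen uptake rate in mmol/L/h; positive.
#' @return `CER / OUR` (dimensionless).
#' @export
rq <- function(cer, our) {
  if (any(our <= 0)) stop("our must be > 0 for RQ")
  cer / our
}

#' Specific carbon dioxide production rate
#'
#' @param cer Carbon evolution rate in mmol/L/h.
#' @param dcw Dry cell weight concentration in g/L; positive.
#' @return `CER / x` in mmol per g biomass per h.
#' @export
q_co2 <- function(cer, dcw) {
  if (any(dcw <= 0)) stop("dcw must be > 0")
  cer / dcw
}

#' Specific oxygen consumption rate
#'
#' @param our Oxygen uptake rate in mmol/L/h.
#' @param dcw Dry cell weight concentration in g/L; positive.
#' @return `OUR / x` in mmol per g biomass per h.
#' @export
q_o2 <- function(our, dcw) {
  if (any(dcw <= 0)) stop("dcw must be > 0")
  our / dcw
}

#' CO2 yield on substrate in C-mol per C-mol
#'
#' One mmol CO2 carries one mC-mol, so the specific CO2 rate converts
#' directly; the substrate rate is converted via the compound table.
#'
#' @param q_co2 Specific CO2 production rate in mmol/g/h.
#' @param q_glc,q_msg Specific substrate consumption rates in g/g/h.
#' @return Yield in C-mol CO2 per C-mol substrate.
#' @export
co2_yield <- function(q_co2, q_glc, q_msg = 0) {
  qs <- .q_s_cmol(q_glc, q_msg)
  if (any(qs <= 0)) stop("substrate rate must be > 0")
  (q_co2 / 1000) / qs
}

#' Carbon balance closure
#'
#' Sum of the biomass, CO2 and trehalose yields, each in C-mol per C-mol of
#' substrate. A value close to 1.0 means all substrate carbon is recovered
#' in biomass, exhaust gas or extracellular product.
#'
#' @param y_xs Biomass yield in C-mol/C-mol.
#' @param y_co2s CO2 yield in C-mol/C-mol.
#' @param y_tres Trehalose yield in C-mol/C-mol.
#' @return The carbon balance (dimensionless).
#' @export
c_balance <- function(y_xs, y_co2s, y_tres) {
  if (any(c(y_xs, y_co2s, y_tres) < 0)) stop("yields must be non-negative")
  y_xs + y_co2s + y_tres
}

#' Select steady-state sampling points
#'
#' A chemostat is taken to have reached steady state after four theoretical
#' dwell times, i.e. samples from `chemostat_start + 4 / D` onwards qualify.
#'
#' @param samples A [sample_table()].
#' @param chemostat_start Process time at which the continuous phase
#'   started, in h.
#' @param D Dilution rate in 1/h; positive.
#' @return The qualifying subset of `samples`.
#' @export
steady_state_window <- function(samples, chemostat_start, D) {
  if (D <= 0) stop("D must be > 0")
  cutoff <- chemostat_start + 4 / D
  out <- samples[samples$time_h >= cutoff, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop(sprintf("no sampling points at or after the steady-state cutoff (%.1f h)",
                 cutoff))
  }
  out
}

#' Interval-wise physiological rates
#'
#' Evaluates the full rate calculus between every pair of consecutive
#' sampling points: dilution rate from the balance readings, specific growth
#' rate (bleed-corrected), biomass space-time yield, specific glucose, MSG
#' and trehalose rates, and — when an off-gas table is supplied — CER, OUR,
#' RQ and the specific gas rates, with the off-gas signals linearly
#' interpolated to the interval midpoints. Irregular sampling intervals
#' (weekend gaps) are handled natively by the interval formulas.
#'
#' @param samples A [sample_table()] with at least 2 rows.
#' @param offgas An optional [offgas_table()].
#' @param feed A [feed_composition()].
#' @return A tibble of class `interval_rates`, one row per interval, with
#'   columns `t_mid`, `dt`, `D`, `mu`, `dx` (space-time yield), `q_glc`,
#'   `q_msg`, `q_tre`, and (if off-gas is given) `cer`, `our`, `rq`, `q_co2`,
#'   `q_o2`.
#' @export
interval_rates <- function(samples, offgas = NULL, feed = feed_composition()) {
  stopifnot(inherits(samples, "sample_table"))
  if (nrow(samples) < 2L) stop("at least 2 sampling points are required")
  n <- nrow(samples) - 1L
  res <- vector("list", n)
  for (i in seq_len(n)) {
    prev <- samples[i, ]; curr <- samples[i + 1L, ]
    dt <- curr$time_h - prev$time_h
    v_bar <- (prev$volume_l + curr$volume_l) / 2
    x_bar <- (prev$dcw_gl + curr$dcw_gl) / 2
    fl <- .interval_flows(prev, curr)
    D <- dilution_rate(fl$feed / dt, fl$acid / dt, v_bar)
    res[[i]] <- tibble::tibble(
      t_mid = (prev$time_h + curr$time_h) / 2,
      dt = dt,
      D = D,
      mu = specific_growth_rate(prev, curr),
      dx = space_time_yield(x_bar, D),
      q_glc = specific_consumption_rate(prev, curr, "glucose", feed),
      q_msg = specific_consumption_rate(prev, curr, "msg", feed),
      q_tre = specific_production_rate(prev, curr, "trehalose", feed),
      x_bar = x_bar,
      v_bar = v_bar
    )
  }
  out <- do.call(rbind, res)
  if (!is.null(offgas)) {
    stopifnot(inherits(offgas, "offgas_table"))
    interp <- function(col) {
      stats::approx(offgas$time_h, offgas[[col]], xout = out$t_mid,
                    rule = 2)$y
    }
    og <- list(gas_flow_lh = interp("gas_flow_lh"),
               y_co2_in = interp("y_co2_in"), y_co2_out = interp("y_co2_out"),
               y_o2_in = interp("y_o2_in"), y_o2_out = interp("y_o2_out"))
    out$cer <- cer(og, out$v_bar)
    out$our <- our(og, out$v_bar)
    out$rq <- ifelse(out$our > 0, out$cer / out$our, NA_real_)
    out$q_co2 <- q_co2(out$cer, out$x_bar)
    out$q_o2 <- q_o2(out$our, out$x_bar)
  }
  class(out) <- c("interval_rates", class(tibble::tibble()))
  out
}

#' Coefficient of variation in percent
#'
#' @param values Numeric vector with at least 2 values and non-zero mean.
#' @return `100 * sd(values) / mean(values)` (sample standard deviation).
#' @examples
#' std_percent(c(2, 4))  # 47.14
#' @export
std_percent <- function(values) {
  if (length(values) < 2L) stop("at least 2 values are required")
  m <- mean(values)
  if (m == 0) stop("mean is zero; STD% undefined")
  100 * stats::sd(values) / m
}

#' Summarize steady-state physiology
#'
#' Derives the per-interval yields (biomass yield in g/g and C-mol/C-mol,
#' trehalose and CO2 yields in C-mol/C-mol, carbon balance) from an
#' [interval_rates()] table restricted to steady state, then reports the
#' mean and STD% (100 * sd / mean) of every rate and yield over the
#' steady-state intervals. Parameters whose mean is zero get `NA` STD%.
#'
#' @param rates An [interval_rates()] table with >= 2 rows (steady-state
#'   intervals only).
#' @param biomass_comp A [biomass_composition()] for the C-mol biomass
#'   yield.
#' @return An object of class `steady_state_summary`: a tibble with columns
#'   `parameter`, `mean`, `std_pct`, and attribute `n_samples`.
#' @export
summarize_steady_state <- function(rates, biomass_comp = biomass_composition()) {
  stopifnot(inherits(rates, "interval_rates"))
  if (nrow(rates) < 2L) stop("at least 2 steady-state intervals are required")
  r <- tibble::as_tibble(rates)
  r$q_s_total <- r$q_glc + r$q_msg
  r$y_xs <- biomass_yield(r$mu, r$q_s_total)
  qs_cmol <- .q_s_cmol(r$q_glc, r$q_msg)
  r$y_xs_cmol <- biomass_to_cmol(r$mu, biomass_comp) / qs_cmol
  r$y_tre_cmol <- trehalose_yield(r$q_tre, r$q_glc, r$q_msg)
  if ("q_co2" %in% names(r)) {
    r$y_co2_cmol <- co2_yield(r$q_co2, r$q_glc, r$q_msg)
    r$c_balance <- c_balance(r$y_xs_cmol, r$y_co2_cmol, r$y_tre_cmol)
  }
  params <- setdiff(names(r), c("t_mid", "dt", "x_bar", "v_bar"))
  stat <- lapply(params, function(p) {
    v <- r[[p]]
    m <- mean(v)
    s <- if (m == 0 || anyNA(v)) NA_real_ else 100 * stats::sd(v) / m
    tibble::tibble(parameter = p, mean = m, std_pct = s)
  })
  out <- do.call(rbind, stat)
  structure(out, n_samples = nrow(r) + 1L,
            class = c("steady_state_summary", class(tibble::tibble())))
}

#' @export
print.steady_state_summary <- function(x, ...) {
  cat(sprintf("<steady_state_summary> over %d steady-state samples\n",
              attr(x, "n_samples")))
  df <- as.data.frame(x)
  df$mean <- signif(df$mean, 4)
  df$std_pct <- round(df$std_pct, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
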