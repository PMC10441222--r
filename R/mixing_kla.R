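#' Impeller specification
#'
#' @param diameter Impeller diameter in m; positive.
#' @param power_number Turbulent, ungassed power number (dimensionless);
#'   positive. Impeller characteristics are vendor-specific and must be
#'   supplied by the user.
#' @param count Number of identical impellers on the shaft; >= 1.
#' @return An object of class `impeller_spec`.
#' @export
impeller_spec <- function(diameter, power_number, count = 1L) {
  if (!is.numeric(diameter) || diameter <= 0) stop("diameter must be > 0")
  if (!is.numeric(power_number) || power_number <= 0) {
    stop("power_number must be > 0")
  }
  if (count < 1) stop("count must be >= 1")
  structure(
    list(diameter = diameter, power_number = power_number,
         count = as.integer(count)),
    class = "impeller_spec"
  )
}

#' Stirred-tank reactor setup
#'
#' Bundles the geometry and operating point of one bioreactor scale: vessel,
#' impellers, sparger type, stirrer speed, gas flow (at norm conditions),
#' head-space overpressure, temperature, and the oxygen mole fraction of the
#' inlet gas.
#'
#' @param vessel_diameter Inner vessel diameter in m.
#' @param total_volume Total reactor volume in L.
#' @param working_volume Liquid working volume in L; must not exceed
#'   `total_volume`.
#' @param impellers A single [impeller_spec()] or a list of them.
#' @param sparger `"ring"` or `"micro"`.
#' @param stirrer_speed Stirrer speed in rpm; non-negative.
#' @param gas_flow Gas flow in normalized L/min; non-negative.
#' @param overpressure Head-space overpressure in bar.
#' @param temperature Broth temperature in degrees C.
#' @param inlet_o2_fraction O2 mole fraction of the inlet gas, in \[0, 1\].
#' @return An object of class `reactor_setup`.
#' @examples
#' benchtop <- reactor_setup(
#'   vessel_diameter = 0.122, total_volume = 3, working_volume = 2,
#'   impellers = impeller_spec(0.0522, 5, count = 2),
#'   sparger = "micro", stirrer_speed = 355, gas_flow = 0.51
#' )
#' tip_speed(benchtop)
#' @export
reactor_setup <- function(vessel_diameter, total_volume, working_volume,
                          impellers, sparger = c("ring", "micro"),
                          stirrer_speed = 0, gas_flow = 0,
                          overpressure = 0, temperature = 75,
                          inlet_o2_fraction = 0.2095) {
  sparger <- match.arg(sparger)
  if (inherits(impellers, "impeller_spec")) impellers <- list(impellers)
  stopifnot(all(vapply(impellers, inherits, logical(1), "impeller_spec")))
  if (working_volume > total_volume) {
    stop("working_volume must not exceed total_volume")
  }
  if (stirrer_speed < 0) stop("stirrer_speed must be >= 0")
  if (gas_flow < 0) stop("gas_flow must be >= 0")
  if (inlet_o2_fraction < 0 || inlet_o2_fraction > 1) {
    stop("inlet_o2_fraction must be in [0, 1]")
  }
  structure(
    list(vessel_diameter = vessel_diameter, total_volume = total_volume,
         working_volume = working_volume, impellers = impellers,
         sparger = sparger, stirrer_speed = stirrer_speed,
         gas_flow = gas_flow, overpressure = overpressure,
         temperature = temperature, inlet_o2_fraction = inlet_o2_fraction),
    class = "reactor_setup"
  )
}

#' @export
print.reactor_setup <- function(x, ...) {
  cat(sprintf(
    "<reactor_setup> %g L working / %g L total, %s sparger\n  %g rpm, %g L/min, %g bar overpressure, %g degC\n",
    x$working_volume, x$total_volume, x$sparger,
    x$stirrer_speed, x$gas_flow, x$overpressure, x$temperature))
  invisible(x)
}

#' Impeller tip speed
#'
#' @param setup A [reactor_setup()] with at least one impeller.
#' @return Tip speed in m/s: `pi * diameter * rpm / 60` of the first
#'   (largest-duty) impeller.
#' @export
tip_speed <- function(setup) {
  stopifnot(inherits(setup, "reactor_setup"))
  if (length(setup$impellers) == 0L) stop("no impeller diameter defined")
  pi * setup$impellers[[1L]]$diameter * setup$stirrer_speed / 60
}

#' Reactor geometry ratio
#'
#' Vessel diameter divided by total reactor volume, a compact descriptor of
#' how slender a vessel is relative to its size; it drops steeply from
#' benchtop to pilot scale.
#'
#' @param setup A [reactor_setup()].
#' @param units `"mm_per_L"` (default, the convention in which benchtop
#'   vessels score in the tens) or `"m_per_L"`.
#' @return The ratio D_R / V_R in the chosen unit convention.
#' @export
geometry_ratio <- function(setup, units = c("mm_per_L", "m_per_L")) {
  stopifnot(inherits(setup, "reactor_setup"))
  units <- match.arg(units)
  if (setup$total_volume <= 0) stop("total_volume must be > 0")
  r <- setup$vessel_diameter / setup$total_volume
  if (units == "mm_per_L") r * 1000 else r
}

#' Ungassed agitation power
#'
#' Turbulent-regime power draw `sum(count * Np * rho * n^3 * d^5)` over the
#' mounted impellers, with the stirrer speed converted to revolutions per
#' second. A warning is issued when the impeller Reynolds number falls below
#' 1e4, where the constant-power-number assumption degrades.
#'
#' @param setup A [reactor_setup()].
#' @param broth_density Broth density in kg/m^3; default 1000.
#' @param viscosity Dynamic viscosity in Pa s; default 4e-4 (water at 75
#'   degrees C), used only for the Reynolds check.
#' @return Power in W.
#' @export
ungassed_power <- function(setup, broth_density = 1000, viscosity = 4e-4) {
  stopifnot(inherits(setup, "reactor_setup"))
  if (broth_density <= 0) stop("broth_density must be > 0")
  n <- setup$stirrer_speed / 60  # 1/s
  p <- 0
  for (imp in setup$impellers) {
    if (n > 0) {
      re <- broth_density * n * imp$diameter^2 / viscosity
      if (re < 1e4) {
        warning(sprintf(
          "impeller Reynolds number %.0f < 1e4; turbulent power number may not apply", re))
      }
    }
    p <- p + imp$count * imp$power_number * broth_density * n^3 * imp$diameter^5
  }
  p
}

#' Gassed (aerated) agitation power
#'
#' Sparged gas cavities behind the blades reduce the power draw. The default
#' correction is the Michel-Miller correlation
#' `Pg = c * (P^2 * n * d^3 / Q^0.56)^0.45` (SI units, c = 0.72), capped at
#' the ungassed power so that `Pg -> P` as the gas flow vanishes.
#'
#' @param setup A [reactor_setup()]; `gas_flow` is read from it.
#' @param ungassed Ungassed power in W (see [ungassed_power()]).
#' @param c_mm Correlation prefactor; default 0.72.
#' @return Gassed power in W; equals `ungassed` at zero gas flow and never
#'   exceeds it.
#' @export
gassed_power <- function(setup, ungassed, c_mm = 0.72) {
  stopifnot(inherits(setup, "reactor_setup"))
  if (setup$gas_flow < 0) stop("gas_flow must be >= 0")
  if (setup$gas_flow == 0 || ungassed == 0) return(ungassed)
  n <- setup$stirrer_speed / 60                    # 1/s
  d <- setup$impellers[[1L]]$diameter              # m
  q <- setup$gas_flow / 1000 / 60                  # L/min -> m^3/s
  pg <- c_mm * (ungassed^2 * n * d^3 / q^0.56)^0.45
  min(pg, ungassed)
}

#' Aerated power input per working volume
#'
#' @param gassed Gassed power in W.
#' @param working_volume Working volume in L.
#' @return Specific power input in kW/m^3 (numerically identical to W/L).
#' @export
power_per_volume <- function(gassed, working_volume) {
  if (working_volume <= 0) stop("working_volume must be > 0")
  gassed / working_volume
}

#' Superficial gas velocity
#'
#' @param setup A [reactor_setup()].
#' @return Volumetric gas flow divided by the vessel cross-section, in m/s.
#' @export
superficial_gas_velocity <- function(setup) {
  stopifnot(inherits(setup, "reactor_setup"))
  if (setup$vessel_diameter <= 0) stop("vessel_diameter must be > 0")
  area <- pi * setup$vessel_diameter^2 / 4           # m^2
  (setup$gas_flow / 1000 / 60) / area                # m^3/s / m^2
}

#' Dissolved-oxygen step-response trace
#'
#' @param time Time in h, strictly increasing, at least 5 points.
#' @param do_percent Dissolved oxygen in % air saturation.
#' @param saturation_value Calibrated 100 % level (the plateau the probe was
#'   spanned to); default 100.
#' @return An object of class `do_trace`, a tibble with columns `time_h` and
#'   `do_percent` plus a `saturation_value` attribute.
#' @export
do_trace <- function(time, do_percent, saturation_value = 100) {
  if (length(time) < 5L) stop("a DO trace needs at least 5 points")
  if (length(time) != length(do_percent)) {
    stop("time and do_percent must have equal length")
  }
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  structure(
    tibble::tibble(time_h = as.numeric(time),
                   do_percent = as.numeric(do_percent)),
    saturation_value = saturation_value,
    class = c("do_trace", class(tibble::tibble()))
  )
}

#' Simulate a dynamic gassing-out experiment
#'
#' Generates the dissolved-oxygen response after switching the sparged gas
#' from nitrogen (~0 % DO) to air: `C(t) = 100 * (1 - exp(-kla * t))`,
#' optionally filtered by a first-order probe lag, with additive Gaussian
#' measurement noise.
#'
#' @param kla Volumetric oxygen transfer coefficient in 1/h; positive.
#' @param duration Trace length in h; default covers ~6 characteristic times.
#' @param sample_interval Probe sampling interval in h; default 1 s.
#' @param probe_lag First-order probe time constant in h; 0 disables the lag.
#' @param noise_sd Gaussian noise standard deviation in %DO; 0 disables.
#' @param seed Integer seed; required whenever `noise_sd > 0`.
#' @return A [do_trace()].
#' @examples
#' tr <- simulate_do_step(40)
#' fit_kla(tr)
#' @export
simulate_do_step <- function(kla, duration = 6 / kla,
                             sample_interval = 1 / 3600,
                             probe_lag = 0, noise_sd = 0, seed = NULL) {
  if (kla <= 0) stop("kla must be > 0")
  t <- seq(0, duration, by = sample_interval)
  if (probe_lag > 0) {
    a <- kla * probe_lag
    if (abs(a - 1) < 1e-8) {
      # confluent limit of the two-exponential solution
      m <- 100 * (1 - (1 + kla * t) * exp(-kla * t))
    } else {
      m <- 100 * (1 - (exp(-kla * t) - a * exp(-t / probe_lag)) / (1 - a))
    }
  } else {
    m <- 100 * (1 - exp(-kla * t))
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required for noisy traces")
    set.seed(seed)
    m <- m + stats::rnorm(length(m), sd = noise_sd)
  }
  do_trace(t, m, saturation_value = 100)
}

#' Estimate kLa from a gassing-out DO trace
#'
#' Dynamic method: within a window of the DO range (default 10-90 % of the
#' calibrated saturation) the oxygen deficit is log-linearised,
#' `ln(1 - C/C*) = -kla * t`, and kLa estimated as minus the regression
#' slope. The window keeps the fit away from the ill-conditioned region near
#' saturation. An optional nonlinear least-squares refinement of the
#' exponential model is available for heavily noisy traces.
#'
#' @param trace A [do_trace()].
#' @param window Fit window as %DO `c(low, high)`; default `c(10, 90)`.
#' @param refine If `TRUE`, refine the log-linear estimate by nonlinear least
#'   squares on `C(t) = C* (1 - exp(-kla t))`.
#' @return An object of class `kla_estimate` with fields `kla` (1/h),
#'   `r_squared`, `fit_window`, `n_points_used`.
#' @export
fit_kla <- function(trace, window = c(10, 90), refine = FALSE) {
  stopifnot(inherits(trace, "do_trace"))
  cstar <- attr(trace, "saturation_value")
  keep <- trace$do_percent >= window[1] & trace$do_percent <= window[2]
  if (!any(keep)) stop("all points fall outside the fit window")
  if (sum(keep) < 5L) stop("fewer than 5 points inside the fit window")
  tt <- trace$time_h[keep]
  cc <- trace$do_percent[keep]
  if (any(cc >= cstar)) {
    stop("saturation value is not above all DO points in the window")
  }
  y <- log(1 - cc / cstar)
  fit <- stats::lm(y ~ tt)
  kla <- -unname(stats::coef(fit)[2L])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  if (kla <= 0) stop("non-positive kla estimate; trace is not a rising step response")
  if (refine) {
    nls_fit <- try(stats::nls(
      do_percent ~ cstar * (1 - exp(-k * time_h)),
      data = trace[keep, ], start = list(k = kla)), silent = TRUE)
    if (!inherits(nls_fit, "try-error")) {
      kla <- unname(stats::coef(nls_fit)[["k"]])
    }
  }
  structure(
    list(kla = kla, r_squared = r2, fit_window = window,
         n_points_used = sum(keep)),
    class = "kla_estimate"
  )
}

#' @export
print.kla_estimate <- function(x, ...) {
  cat(sprintf("<kla_estimate> kLa = %.2f 1/h (R^2 = %.4f, %d points in %g-%g %%DO)\n",
              x$kla, x$r_squared, x$n_points_used,
              x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' Fit a power-law kLa correlation
#'
#' Standard stirred-tank form `kla = alpha * (Pg/VL)^a * vs^b`, fitted by
#' ordinary least squares on logs. The correlation interpolates measured
#' operating points so that a target kLa can be translated into stirrer
#' speed and gas flow at another scale.
#'
#' @param points A data frame with columns `pg_vl` (kW/m^3), `vs` (m/s) and
#'   `kla` (1/h); at least 3 rows with distinct conditions.
#' @return An object of class `kla_correlation` with fields `coefficient`,
#'   `exponent_power`, `exponent_gas`.
#' @export
fit_kla_correlation <- function(points) {
  points <- as.data.frame(points)
  stopifnot(all(c("pg_vl", "vs", "kla") %in% names(points)))
  if (nrow(points) < 3L) stop("at least 3 points are required")
  x1 <- log(points$pg_vl); x2 <- log(points$vs)
  fit <- stats::lm(log(points$kla) ~ x1 + x2)
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("degenerate design: conditions do not span power and gas velocity")
  structure(
    list(coefficient = exp(unname(cf[1L])),
         exponent_power = unname(cf[2L]),
         exponent_gas = unname(cf[3L])),
    class = "kla_correlation"
  )
}

#' @export
print.kla_correlation <- function(x, ...) {
  cat(sprintf("<kla_correlation> kLa = %.3g * (Pg/VL)^%.3f * vs^%.3f\n",
              x$coefficient, x$exponent_power, x$exponent_gas))
  invisible(x)
}

#' Predict kLa from a fitted correlation
#'
#' @param corr A [fit_kla_correlation()] result.
#' @param pg_vl Aerated power input in kW/m^3 (vectorised).
#' @param vs Superficial gas velocity in m/s (vectorised).
#' @return Predicted kLa in 1/h.
#' @export
predict_kla <- function(corr, pg_vl, vs) {
  stopifnot(inherits(corr, "kla_correlation"))
  corr$coefficient * pg_vl^corr$exponent_power * vs^corr$exponent_gas
}

#' Predicted kLa of a reactor setup under a correlation
#'
#' Convenience wrapper: computes the aerated power input and superficial gas
#' velocity of `setup` and evaluates the correlation there.
#'
#' @inheritParams ungassed_power
#' @param corr A [fit_kla_correlation()] result.
#' @return Predicted kLa in 1/h.
#' @export
setup_kla <- function(setup, corr, broth_density = 1000) {
  p0 <- ungassed_power(setup, broth_density)
  pg <- gassed_power(setup, p0)
  pv <- power_per_volume(pg, setup$working_volume)
  predict_kla(corr, pv, superficial_gas_velocity(setup))
}

#' Solve for the stirrer speed reaching a target kLa
#'
#' Holds the gas flow fixed and root-solves the fitted correlation for the
#' stirrer speed whose predicted kLa matches the target — the constant-kLa
#' scale-up step that translates an operating point across reactor scales.
#'
#' @param target_kla Target kLa in 1/h; positive.
#' @param setup A [reactor_setup()] describing the destination reactor.
#' @param corr A [fit_kla_correlation()] for that reactor.
#' @param fixed_gas_flow Gas flow in normalized L/min to hold; defaults to
#'   the setup's current gas flow.
#' @param rpm_range Admissible stirrer-speed interval in rpm.
#' @param tol Relative tolerance on the achieved kLa; default 1 %.
#' @param broth_density Broth density in kg/m^3.
#' @return The input setup with `stirrer_speed` replaced, carrying the
#'   achieved kLa in attribute `predicted_kla`.
#' @export
solve_operating_point <- function(target_kla, setup, corr,
                                  fixed_gas_flow = setup$gas_flow,
                                  rpm_range = c(50, 1500), tol = 0.01,
                                  broth_density = 1000) {
  stopifnot(inherits(setup, "reactor_setup"), inherits(corr, "kla_correlation"))
  if (target_kla <= 0) stop("target_kla must be > 0")
  setup$gas_flow <- fixed_gas_flow
  pred_at <- function(rpm) {
    s <- setup; s$stirrer_speed <- rpm
    suppressWarnings(setup_kla(s, corr, broth_density))
  }
  lo <- pred_at(rpm_range[1]); hi <- pred_at(rpm_range[2])
  if (target_kla < min(lo, hi) || target_kla > max(lo, hi)) {
    stop(sprintf(
      "target kLa %.3g 1/h outside achievable interval [%.3g, %.3g] 1/h for rpm in [%g, %g]",
      target_kla, min(lo, hi), max(lo, hi), rpm_range[1], rpm_range[2]))
  }
  root <- stats::uniroot(function(r) log(pred_at(r) / target_kla),
                         interval = rpm_range, tol = 1e-4)
  setup$stirrer_speed <- root$root
  achieved <- pred_at(root$root)
  if (abs(achieved - target_kla) / target_kla > tol) {
    stop("root solving did not converge within tolerance")
  }
  attr(setup, "predicted_kla") <- achieved
  setup
}
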