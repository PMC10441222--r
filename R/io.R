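# shared CSV reader: mandatory header, comma-separated, period decimal;
# errors name the offending row and column
.read_table <- function(path, required, label) {
  if (!file.exists(path)) stop(label, " file not found: ", path)
  df <- utils::read.csv(path, check.names = TRUE, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(label, " file ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warning(label, " file ", path, " contains a header only")
    return(df)
  }
  for (cl in required) {
    v <- df[[cl]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("%s file %s: non-numeric value '%s' in column %s, row %d",
                     label, path, v[bad[1L]], cl, bad[1L]))
      }
      df[[cl]] <- num
    }
    nas <- which(is.na(df[[cl]]))
    if (length(nas)) {
      stop(sprintf("%s file %s: missing value in column %s, row %d",
                   label, path, cl, nas[1L]))
    }
  }
  if (nrow(df) > 1L && any(diff(df$time_h) <= 0)) {
    stop(sprintf("%s file %s: time_h not strictly increasing at row %d",
                 label, path, which(diff(df$time_h) <= 0)[1L] + 1L))
  }
  df
}

#' Read a cultivation sampling table from CSV
#'
#' Expects the documented comma-separated schema with a header row:
#' `time_h, volume_l, dcw_gl, od600, glucose_gl, msg_gl (or glutamate_gl),
#' trehalose_gl, cum_feed_l, cum_acid_l, cum_bleed_l` and optionally
#' `viability_pct`. Glutamic acid readings are converted to MSG on entry.
#'
#' @param path Path to the CSV file.
#' @return A [sample_table()] (empty tibble if the file is header-only).
#' @export
read_samples <- function(path) {
  req <- setdiff(.sample_cols, "msg_gl")
  df <- utils::read.csv(path, nrows = 1)
  req <- c(req, if ("glutamate_gl" %in% names(df)) "glutamate_gl" else "msg_gl")
  out <- .read_table(path, req, "sample")
  if (nrow(out) == 0L) return(out)
  sample_table(out)
}

#' Read an off-gas table from CSV
#'
#' Schema: `time_h, y_o2_in, y_o2_out, y_co2_in, y_co2_out, gas_flow_lh`.
#'
#' @param path Path to the CSV file.
#' @return An [offgas_table()].
#' @export
read_offgas <- function(path) {
  out <- .read_table(path, .offgas_cols, "off-gas")
  if (nrow(out) == 0L) return(out)
  offgas_table(out)
}

#' Read a gassing-out DO trace from CSV
#'
#' Schema: `time_h, do_percent`; the calibrated saturation level defaults
#' to 100 %.
#'
#' @param path Path to the CSV file.
#' @param saturation_value Calibrated 100 % DO level.
#' @return A [do_trace()].
#' @export
read_dotrace <- function(path, saturation_value = 100) {
  out <- .read_table(path, c("time_h", "do_percent"), "DO trace")
  if (nrow(out) == 0L) return(out)
  do_trace(out$time_h, out$do_percent, saturation_value)
}

#' Read a run configuration from YAML
#'
#' The configuration bundles the reactor setup, feed composition, process
#' schedule and analysis options; every field has the package default, so a
#' minimal file only overrides what differs. See the package vignette for
#' the schema.
#'
#' @param path Path to a YAML file.
#' @return A list of class `run_config` with elements `setup`, `feed`,
#'   `schedule`, `kinetics`, `options`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  feed <- do.call(feed_composition, raw$feed %||% list())
  sched_args <- raw$schedule %||% list()
  sched_args$feed <- feed
  cfg <- list(
    setup = if (!is.null(raw$reactor)) {
      imps <- lapply(raw$reactor$impellers %||%
                       list(list(diameter = 0.0522, power_number = 5, count = 2)),
                     function(i) do.call(impeller_spec, i))
      raw$reactor$impellers <- imps
      do.call(reactor_setup, raw$reactor)
    } else scale_preset(raw$scale %||% "2L")$setup,
    feed = feed,
    schedule = do.call(process_schedule, sched_args),
    kinetics = do.call(kinetic_params, raw$kinetics %||% list()),
    options = utils::modifyList(
      list(kla = 40, fit_window = c(10, 90), dwell_times = 4,
           biomass_carbon_fraction = biomass_composition()$carbon_fraction),
      raw$options %||% list())
  )
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full chemostat analysis pipeline
#'
#' Executes, in order: steady-state windowing (four dwell times after the
#' chemostat start), interval-wise rate calculus, yield and carbon-balance
#' computation, and the steady-state summary. Inputs come either from CSV
#' files (`samples`/`offgas` paths or tables) or from a simulation. Every
#' applied convention (sign conventions, off-gas interpolation, window rule)
#' is recorded in the returned report.
#'
#' @param samples A [sample_table()] or path to a sample CSV.
#' @param offgas An [offgas_table()], path to an off-gas CSV, or `NULL`.
#' @param feed A [feed_composition()].
#' @param chemostat_start Process time the continuous phase started, in h.
#' @param D Nominal dilution rate in 1/h (used for the steady-state cutoff).
#' @param dwell_times Dwell times required before steady state; default 4.
#' @param biomass_comp A [biomass_composition()].
#' @param out_dir If non-`NULL`, the per-interval rates (CSV) and summary
#'   (CSV + JSON) are written there.
#' @return A list of class `pipeline_report`: `rates` (steady-state
#'   [interval_rates()]), `summary` (a [summarize_steady_state()] result),
#'   `steady_state_cutoff_h`, and `conventions` (the audit trail of applied
#'   conventions).
#' @export
run_pipeline <- function(samples, offgas = NULL, feed = feed_composition(),
                         chemostat_start, D, dwell_times = 4,
                         biomass_comp = biomass_composition(),
                         out_dir = NULL) {
  if (is.character(samples)) samples <- read_samples(samples)
  if (is.character(offgas)) offgas <- read_offgas(offgas)
  cutoff <- chemostat_start + dwell_times / D
  ss <- samples[samples$time_h >= cutoff, , drop = FALSE]
  if (nrow(ss) == 0L) {
    stop(sprintf("no sampling points at or after the steady-state cutoff (%.1f h)",
                 cutoff))
  }
  if (nrow(ss) < 3L) {
    stop("fewer than 3 steady-state sampling points; cannot form >= 2 intervals")
  }
  rates <- interval_rates(sample_table(ss), offgas, feed)
  summ <- summarize_steady_state(rates, biomass_comp)
  conventions <- list(
    steady_state_rule = sprintf("samples from chemostat start + %g/D = %.1f h",
                                dwell_times, cutoff),
    q_s_sign = "consumption-positive (dS_reactor = prev - curr)",
    q_p_sign = "production-positive (dP_reactor = curr - prev)",
    bleed_term = "mean of bounding broth concentrations times bleed volume",
    acid = "substrate-free; counts toward dilution rate only",
    offgas = "linearly interpolated to interval midpoints",
    our_sign = "(y_O2,in - y_O2,out), positive for consumption",
    molar_volume_l_mol = MOLAR_VOLUME,
    biomass_carbon_fraction = biomass_comp$carbon_fraction
  )
  report <- structure(
    list(rates = rates, summary = summ, steady_state_cutoff_h = cutoff,
         conventions = conventions),
    class = "pipeline_report"
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(as.data.frame(rates),
                     file.path(out_dir, "interval_rates.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(summ),
                     file.path(out_dir, "steady_state_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(steady_state_cutoff_h = cutoff,
           n_samples = attr(summ, "n_samples"),
           conventions = conventions,
           summary = as.data.frame(summ)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> steady state from %.1f h, %d intervals\n",
              x$steady_state_cutoff_h, nrow(x$rates)))
  print(x$summary)
  invisible(x)
}
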