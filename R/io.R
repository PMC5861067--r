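# Readers and writers shared across the package: trace CSV, simulation
# time-series CSV, and summary JSON. CSVs are plain RFC-4180 style with a
# header row and '.' decimal; JSON keys embed their units.

#' Read an intensity trace from CSV
#'
#' Expects columns `time_s`, `intensity_cp`, `intensity_pp` (optionally
#' `specimen`); time must be uniform to within `tol_s`.
#'
#' @param path CSV file path.
#' @param tol_s Uniform-sampling tolerance, seconds (default 1e-6).
#' @return A `mozpump_trace`.
#' @export
read_trace_csv <- function(path, tol_s = 1e-6) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "intensity_cp", "intensity_pp")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in need) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("non-finite value in '%s' at row %d", col, bad[1]),
           call. = FALSE)
    }
  }
  specimen <- if ("specimen" %in% names(df)) df$specimen[1] else "s1"
  intensity_trace(df$time_s, df$intensity_cp, df$intensity_pp,
                  specimen = specimen, tol_s = tol_s)
}

#' Write an intensity trace to CSV
#'
#' @param trace A `mozpump_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "mozpump_trace"))
  df <- as.data.frame(trace)
  df$specimen <- attr(trace, "specimen")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a simulation time series to CSV
#'
#' Columns (SI units): time, flows, pump pressures, volume rates, pump
#' powers, and valve flags.
#'
#' @param sim A `mozpump_sim` from [simulate_mode()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(sim, path) {
  stopifnot(inherits(sim, "mozpump_sim"))
  df <- data.frame(
    t_s = sim$t_s,
    q1_m3_s = sim$q1_m3_s, q2_m3_s = sim$q2_m3_s, q3_m3_s = sim$q3_m3_s,
    p_cp_pa = sim$p_cp_pa, p_pp_pa = sim$p_pp_pa,
    vdot_cp_m3_s = sim$vdot_cp_m3_s, vdot_pp_m3_s = sim$vdot_pp_m3_s,
    p_pow_cp_w = sim$p_pow_cp_w, p_pow_pp_w = sim$p_pow_pp_w,
    pharyngeal_valve_closed = sim$pharyngeal_valve_closed,
    esophageal_valve_closed = sim$esophageal_valve_closed)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write summary metrics to JSON
#'
#' Serializes a `mozpump_summary` (or any named list of scalars) with
#' stable key order and units embedded in the key names. Reporting units:
#' flows in nL/s, pressures in kPa, power in nW.
#'
#' @param metrics A `mozpump_summary` from [mode_summary()], or a named
#'   list of scalar values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(metrics, path) {
  if (inherits(metrics, "mozpump_summary")) {
    metrics <- list(
      mode = metrics$mode,
      q_avg_nl_per_s = metrics$q_avg_m3_s * 1e12,
      dp_max_kpa = metrics$dp_max_pa / 1e3,
      p_avg_nw = metrics$p_avg_w * 1e9,
      max_backflow_fraction = metrics$max_backflow_fraction,
      backflow_volume_fraction = metrics$backflow_volume_fraction,
      effectiveness_nl_per_s_per_nw =
        metrics$effectiveness_m3_s_w * 1e12 / 1e9)
  }
  if (is.null(names(metrics)) || any(names(metrics) == "")) {
    stop("metrics must be a fully named list", call. = FALSE)
  }
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
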