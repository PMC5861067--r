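# Headline metrics: time-averaged flow, backflow statistics, pump-volume
# table, mode comparison ratios, the pulsed-pipe illustration of rate
# nonlinearity, and the capillary meniscus priming threshold.

#' Time-averaged inlet flow of a simulated mode
#'
#' Trapezoidal time average of the feeding-canal flow `Q1` over the
#' simulated period. By mass conservation the averages of `Q1`, `Q2`, `Q3`
#' agree for any full-period result.
#'
#' @param sim A `mozpump_sim` or `mozpump_ko_sim`.
#' @return Flow in m^3/s.
#' @export
time_average_flow <- function(sim) {
  if (inherits(sim, "mozpump_ko_sim")) {
    return(trapz_mean(sim$t_s, sim$q_in_m3_s))
  }
  stopifnot(inherits(sim, "mozpump_sim"))
  trapz_mean(sim$t_s, sim$q1_m3_s)
}

#' Backflow statistics of a simulated mode
#'
#' The continuous mode periodically pushes fluid back out of the feeding
#' canal (negative `Q1`). Reports the maximum backflow rate as a fraction
#' of the maximum inflow rate, and the backflow volume as a fraction of
#' the net inflow volume over one period. The gross-inflow variant of the
#' volume fraction (backflow volume over the integral of positive inflow
#' only) is reported alongside for transparency.
#'
#' @param sim A `mozpump_sim` from [simulate_mode()].
#' @return A list with `max_backflow_fraction`, `backflow_volume_fraction`
#'   (denominator: net inflow volume), and
#'   `backflow_volume_fraction_gross` (denominator: gross inflow volume).
#' @export
backflow_metrics <- function(sim) {
  stopifnot(inherits(sim, "mozpump_sim"))
  q1 <- sim$q1_m3_s
  t <- sim$t_s
  q_max <- max(q1)
  net <- trapz_mean(t, q1)
  if (q_max <= 0 || net <= 0) {
    stop("backflow metrics undefined: no net inflow", call. = FALSE)
  }
  back <- trapz_mean(t, pmax(0, -q1))
  gross <- trapz_mean(t, pmax(0, q1))
  list(max_backflow_fraction = max(0, -min(q1)) / q_max,
       backflow_volume_fraction = back / net,
       backflow_volume_fraction_gross = back / gross)
}

#' Pump volume table
#'
#' Minimum and maximum prolate-spheroid pump volumes per pump and drinking
#' mode, the stroke volume change, and the burst-to-continuous ratio of
#' the change.
#'
#' @param config A [system_config()] object.
#' @return A data frame with one row per pump x mode: `pump`, `mode`,
#'   `v_min_nl`, `v_max_nl`, `v_change_nl`, `change_rel_continuous`.
#' @export
volume_table <- function(config = default_config()) {
  stopifnot(inherits(config, "mozpump_config"))
  rows <- list()
  for (p in c("cp", "pp")) {
    g <- if (p == "cp") config$cibarial else config$pharyngeal
    b <- g$length_m / 2
    v_min <- pump_volume(g$h_min_m / 2, b)
    changes <- c(continuous = NA_real_, burst = NA_real_)
    for (m in c("continuous", "burst")) {
      h_max <- if (m == "continuous") g$h_max_continuous_m else g$h_max_burst_m
      v_max <- pump_volume(h_max / 2, b)
      changes[m] <- v_max - v_min
      rows[[length(rows) + 1L]] <- data.frame(
        pump = p, mode = m,
        v_min_nl = v_min * 1e12, v_max_nl = v_max * 1e12,
        v_change_nl = (v_max - v_min) * 1e12,
        stringsAsFactors = FALSE)
    }
    ratio <- changes["burst"] / changes["continuous"]
    rows[[length(rows) - 1L]]$change_rel_continuous <- 1
    rows[[length(rows)]]$change_rel_continuous <- unname(ratio)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pulsed-pipe illustration of flow-rate nonlinearity
#'
#' Steady Hagen-Poiseuille flow through a single straight pipe under a
#' piecewise-constant pressure schedule: each level gives `Q = dp / kappa`,
#' and the time-averaged flow is the duty-weighted mean of the levels.
#' Illustrates how a brief large-pressure phase dominates the average flow
#' in a linear-resistance system driven nonlinearly in time.
#'
#' @param diameter_m Pipe diameter, metres.
#' @param length_m Pipe length, metres.
#' @param viscosity_pa_s Dynamic viscosity, Pa s.
#' @param dp_pa Vector of pressure-drop levels, Pa.
#' @param duration_s Vector of level durations, seconds (same length).
#' @return A list with `q_per_level_m3_s` and `q_average_m3_s`.
#' @export
pulsed_pipe_example <- function(diameter_m = 25e-6, length_m = 6.4e-3,
                                viscosity_pa_s = 3.0e-3,
                                dp_pa = 1e3, duration_s = 1) {
  if (length(dp_pa) != length(duration_s)) {
    stop("`dp_pa` and `duration_s` must have equal length", call. = FALSE)
  }
  if (any(duration_s <= 0)) {
    stop("durations must be positive", call. = FALSE)
  }
  k <- tube_impedance(length_m, diameter_m, viscosity_pa_s)
  q <- dp_pa / k
  list(q_per_level_m3_s = q,
       q_average_m3_s = sum(q * duration_s) / sum(duration_s))
}

#' Capillary meniscus priming threshold
#'
#' When air enters the feeding canal, an air-liquid meniscus of radius of
#' curvature `R` resists being drawn up by the Laplace pressure
#' `dp_m = 2 sigma / R`. A drinking mode can pull the meniscus toward the
#' head only if its cibarial pump pressure dips below `-dp_m` (gauge).
#'
#' The default `radius_m = 25e-6` reproduces the reference threshold of
#' about 6.2 kPa for the standard feeding-canal geometry; see the methods
#' vignette for the convention discussion.
#'
#' @param sims A list of `mozpump_sim` objects (typically continuous and
#'   burst), or NULL for the threshold alone.
#' @param surface_tension_n_m Surface tension, N/m.
#' @param radius_m Meniscus radius of curvature, metres.
#' @return A list with `dp_meniscus_pa`, `p_inlet_pa` (gauge), and, if
#'   simulations were supplied, a named logical vector `feasible` keyed by
#'   mode.
#' @export
meniscus_threshold <- function(sims = NULL, surface_tension_n_m = 0.077,
                               radius_m = 25e-6) {
  check_positive(surface_tension_n_m = surface_tension_n_m,
                 radius_m = radius_m)
  dp_m <- 2 * surface_tension_n_m / radius_m
  out <- list(dp_meniscus_pa = dp_m, p_inlet_pa = -dp_m)
  if (!is.null(sims)) {
    if (inherits(sims, "mozpump_sim")) sims <- list(sims)
    feas <- vapply(sims, function(s) {
      stopifnot(inherits(s, "mozpump_sim"))
      p_atm <- s$config$boundaries$p_atm_pa
      min(s$p_cp_pa - p_atm) < -dp_m
    }, logical(1))
    names(feas) <- vapply(sims, function(s) s$mode, character(1))
    out$feasible <- feas
  }
  out
}

#' Summary metrics of a simulated mode
#'
#' @param sim A `mozpump_sim` from [simulate_mode()].
#' @return A list of class `mozpump_summary`: `mode`, `q_avg_m3_s`,
#'   `dp_max_pa`, `p_avg_w`, `max_backflow_fraction`,
#'   `backflow_volume_fraction`, `effectiveness_m3_s_w` (average flow per
#'   unit average power).
#' @export
mode_summary <- function(sim) {
  stopifnot(inherits(sim, "mozpump_sim"))
  q_avg <- time_average_flow(sim)
  p_avg <- mode_average_power(sim)
  bf <- backflow_metrics(sim)
  structure(list(mode = sim$mode,
                 q_avg_m3_s = q_avg,
                 dp_max_pa = max_proboscis_pressure_drop(sim),
                 p_avg_w = p_avg,
                 max_backflow_fraction = bf$max_backflow_fraction,
                 backflow_volume_fraction = bf$backflow_volume_fraction,
                 effectiveness_m3_s_w = q_avg / p_avg),
            class = "mozpump_summary")
}

#' Burst-to-continuous mode comparison
#'
#' Ratios of time-averaged flow, maximum proboscis pressure drop, and
#' cycle-averaged power between two mode summaries, plus the effectiveness
#' ratio (flow per unit power, continuous over burst).
#'
#' @param continuous,burst `mozpump_summary` objects from [mode_summary()],
#'   computed on the same configuration.
#' @return A list with `flow_ratio`, `dp_ratio`, `power_ratio`,
#'   `effectiveness_ratio`.
#' @export
mode_comparison <- function(continuous, burst) {
  stopifnot(inherits(continuous, "mozpump_summary"),
            inherits(burst, "mozpump_summary"))
  for (s in list(continuous, burst)) {
    if (s$q_avg_m3_s == 0 || s$p_avg_w == 0) {
      stop("mode comparison undefined: zero flow or power", call. = FALSE)
    }
  }
  list(flow_ratio = burst$q_avg_m3_s / continuous$q_avg_m3_s,
       dp_ratio = burst$dp_max_pa / continuous$dp_max_pa,
       power_ratio = burst$p_avg_w / continuous$p_avg_w,
       effectiveness_ratio = continuous$effectiveness_m3_s_w /
         burst$effectiveness_m3_s_w)
}

#' @export
print.mozpump_summary <- function(x, ...) {
  cat(sprintf("<mozpump_summary> %s mode\n", x$mode))
  cat(sprintf("  Q_avg = %.3g nL/s, max |dp| = %.3g kPa, P_avg = %.3g nW\n",
              x$q_avg_m3_s * 1e12, x$dp_max_pa / 1e3, x$p_avg_w * 1e9))
  cat(sprintf("  backflow: max %.1f%% of peak inflow, %.1f%% of net volume\n",
              100 * x$max_backflow_fraction,
              100 * x$backflow_volume_fraction))
  invisible(x)
}
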