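# Prescribed pump-wall kinematics. Each pump is a prolate spheroid of fixed
# semi-major axis b = L/2 whose semi-minor axis a(t) follows a raised-cosine
# waveform: a continuous oscillation between H_min/2 and H_max/2 in the
# continuous mode, or a single isolated 1-cos hump per period in the burst
# mode. Volume rates are closed-form derivatives, never finite differences,
# because the instant flow solution is linear in Vdot and differencing noise
# would contaminate the pressure peaks.

#' Cycle timing for the two drinking modes
#'
#' Continuous mode: both pumps oscillate with period `t_c_s`, the cibarial
#' pump starting at `tau_cp_c_s` and the pharyngeal pump at `tau_pp_c_s`
#' within the cycle. Burst mode: one isolated event per period `t_b_s`,
#' each pump executing a single stroke between its start and end times.
#' Defaults are the mean timings measured from the x-ray recordings.
#'
#' @param t_c_s Continuous-mode period, seconds.
#' @param tau_cp_c_s,tau_pp_c_s Continuous-mode phase delays of the cibarial
#'   and pharyngeal pumps, seconds.
#' @param t_b_s Burst-mode period, seconds.
#' @param t_s_cp_s,t_e_cp_s Burst-mode start/end of the cibarial stroke, s.
#' @param t_s_pp_s,t_e_pp_s Burst-mode start/end of the pharyngeal stroke, s.
#' @return An object of class `mozpump_timing`.
#' @export
mode_timing <- function(t_c_s = 0.2335, tau_cp_c_s = 0, tau_pp_c_s = 0.0835,
                        t_b_s = 0.703,
                        t_s_cp_s = 0.4e-3, t_e_cp_s = 0.662,
                        t_s_pp_s = 0.153, t_e_pp_s = 0.646) {
  check_positive(t_c_s = t_c_s, t_b_s = t_b_s)
  for (nm in c("tau_cp_c_s", "tau_pp_c_s")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v >= t_c_s) {
      stop(sprintf("`%s` must lie in [0, t_c_s)", nm), call. = FALSE)
    }
  }
  for (p in c("cp", "pp")) {
    ts <- get(sprintf("t_s_%s_s", p))
    te <- get(sprintf("t_e_%s_s", p))
    if (!(ts >= 0 && ts < te && te <= t_b_s)) {
      stop(sprintf("burst times must satisfy 0 <= t_s_%s < t_e_%s <= t_b",
                   p, p), call. = FALSE)
    }
  }
  structure(list(t_c_s = t_c_s, tau_cp_c_s = tau_cp_c_s,
                 tau_pp_c_s = tau_pp_c_s, t_b_s = t_b_s,
                 t_s_cp_s = t_s_cp_s, t_e_cp_s = t_e_cp_s,
                 t_s_pp_s = t_s_pp_s, t_e_pp_s = t_e_pp_s),
            class = "mozpump_timing")
}

#' Reference cycle timing
#'
#' Continuous mode: period 233.5 ms, cibarial delay 0, pharyngeal delay
#' 83.5 ms. Burst mode: period 703 ms, cibarial stroke 0.4-662 ms,
#' pharyngeal stroke 153-646 ms.
#'
#' @return An object of class `mozpump_timing`.
#' @export
default_timing <- function() mode_timing()

# internal: per-pump timing lookup
pump_delay <- function(timing, pump) {
  switch(pump, cp = timing$tau_cp_c_s, pp = timing$tau_pp_c_s,
         stop("`pump` must be 'cp' or 'pp'", call. = FALSE))
}
burst_window <- function(timing, pump) {
  switch(pump,
         cp = c(timing$t_s_cp_s, timing$t_e_cp_s),
         pp = c(timing$t_s_pp_s, timing$t_e_pp_s),
         stop("`pump` must be 'cp' or 'pp'", call. = FALSE))
}

#' Pump semi-minor axis in the continuous mode
#'
#' `a(t) = H_min/2 + (H_max - H_min)/4 * (1 - cos(w (t - tau)))` with
#' `w = 2 pi / T_C`; periodic with the continuous-mode period.
#'
#' @param t Time(s), seconds; vectorized.
#' @param pump_geom A [pump_geometry()] object.
#' @param timing A [mode_timing()] object.
#' @param pump `"cp"` or `"pp"` (selects the phase delay).
#' @return Semi-minor axis in metres.
#' @export
minor_axis_continuous <- function(t, pump_geom, timing, pump = c("cp", "pp")) {
  pump <- match.arg(pump)
  stopifnot(inherits(pump_geom, "mozpump_pump"),
            inherits(timing, "mozpump_timing"))
  tau <- pump_delay(timing, pump)
  w <- 2 * pi / timing$t_c_s
  pump_geom$h_min_m / 2 +
    (pump_geom$h_max_continuous_m - pump_geom$h_min_m) / 4 *
    (1 - cos(w * (t - tau)))
}

# internal: da/dt, continuous mode
minor_axis_rate_continuous <- function(t, pump_geom, timing, pump) {
  tau <- pump_delay(timing, pump)
  w <- 2 * pi / timing$t_c_s
  (pump_geom$h_max_continuous_m - pump_geom$h_min_m) / 4 * w *
    sin(w * (t - tau))
}

#' Pump semi-minor axis in the burst mode
#'
#' Resting (`H_min/2`) outside the pump's stroke window; inside, a single
#' `1 - cos` hump peaking at `H_max_burst/2` at the window midpoint. The
#' waveform is value- and slope-continuous at the window edges. Times
#' outside `[0, T_B]` wrap by the burst period.
#'
#' @inheritParams minor_axis_continuous
#' @return Semi-minor axis in metres.
#' @export
minor_axis_burst <- function(t, pump_geom, timing, pump = c("cp", "pp")) {
  pump <- match.arg(pump)
  stopifnot(inherits(pump_geom, "mozpump_pump"),
            inherits(timing, "mozpump_timing"))
  win <- burst_window(timing, pump)
  tb <- t %% timing$t_b_s
  a <- rep(pump_geom$h_min_m / 2, length(tb))
  inside <- tb >= win[1] & tb <= win[2]
  if (any(inside)) {
    w <- 2 * pi / (win[2] - win[1])
    a[inside] <- pump_geom$h_min_m / 2 +
      (pump_geom$h_max_burst_m - pump_geom$h_min_m) / 4 *
      (1 - cos(w * (tb[inside] - win[1])))
  }
  a
}

# internal: da/dt, burst mode
minor_axis_rate_burst <- function(t, pump_geom, timing, pump) {
  win <- burst_window(timing, pump)
  tb <- t %% timing$t_b_s
  da <- numeric(length(tb))
  inside <- tb >= win[1] & tb <= win[2]
  if (any(inside)) {
    w <- 2 * pi / (win[2] - win[1])
    da[inside] <- (pump_geom$h_max_burst_m - pump_geom$h_min_m) / 4 * w *
      sin(w * (tb[inside] - win[1]))
  }
  da
}

#' Prolate-spheroid pump volume
#'
#' `V = (4 pi / 3) a^2 b` for semi-minor axis `a` and semi-major axis `b`.
#'
#' @param a_m Semi-minor axis, metres (vectorized).
#' @param b_m Semi-major axis, metres.
#' @return Volume in m^3.
#' @export
pump_volume <- function(a_m, b_m) {
  if (any(a_m < 0) || any(b_m < 0)) {
    stop("axes must be non-negative", call. = FALSE)
  }
  (4 * pi / 3) * a_m^2 * b_m
}

#' Pump volume rate of change
#'
#' Closed-form derivative `dV/dt = (8 pi / 3) a b da/dt` with `da/dt` from
#' the analytic derivative of the mode waveform. Integrates to zero over a
#' full period in either mode.
#'
#' @param t Time(s), seconds; vectorized.
#' @param pump_geom A [pump_geometry()] object.
#' @param mode `"continuous"` or `"burst"`.
#' @param timing A [mode_timing()] object.
#' @param pump `"cp"` or `"pp"`.
#' @return Volume rate in m^3/s.
#' @export
volume_rate <- function(t, pump_geom, mode = c("continuous", "burst"),
                        timing, pump = c("cp", "pp")) {
  mode <- match.arg(mode)
  pump <- match.arg(pump)
  stopifnot(inherits(pump_geom, "mozpump_pump"),
            inherits(timing, "mozpump_timing"))
  b <- pump_geom$length_m / 2
  if (mode == "continuous") {
    a <- minor_axis_continuous(t, pump_geom, timing, pump)
    da <- minor_axis_rate_continuous(t, pump_geom, timing, pump)
  } else {
    a <- minor_axis_burst(t, pump_geom, timing, pump)
    da <- minor_axis_rate_burst(t, pump_geom, timing, pump)
  }
  (8 * pi / 3) * a * b * da
}

#' Sampled pump kinematics over one mode period
#'
#' Uniform grid of `n_steps + 1` points spanning exactly one period
#' (both endpoints included, spacing `T / n_steps`), with per-pump
#' semi-minor axis, volume, and analytic volume rate.
#'
#' @param mode `"continuous"` or `"burst"`.
#' @param config A [system_config()] object.
#' @param timing A [mode_timing()] object.
#' @param n_steps Number of grid intervals per period (>= 100; default 2000).
#' @return A data frame with columns `t_s`, `a_cp_m`, `a_pp_m`, `v_cp_m3`,
#'   `v_pp_m3`, `vdot_cp_m3_s`, `vdot_pp_m3_s`; the mode and period are
#'   attached as attributes.
#' @export
kinematics_timeline <- function(mode = c("continuous", "burst"), config,
                                timing = default_timing(), n_steps = 2000) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "mozpump_config"),
            inherits(timing, "mozpump_timing"))
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 100) {
    stop("`n_steps` must be a single number >= 100", call. = FALSE)
  }
  n_steps <- as.integer(n_steps)
  period <- if (mode == "continuous") timing$t_c_s else timing$t_b_s
  t <- seq(0, period, length.out = n_steps + 1L)
  axis_fun <- if (mode == "continuous") minor_axis_continuous else
    minor_axis_burst
  a_cp <- axis_fun(t, config$cibarial, timing, "cp")
  a_pp <- axis_fun(t, config$pharyngeal, timing, "pp")
  out <- data.frame(
    t_s = t,
    a_cp_m = a_cp,
    a_pp_m = a_pp,
    v_cp_m3 = pump_volume(a_cp, config$cibarial$length_m / 2),
    v_pp_m3 = pump_volume(a_pp, config$pharyngeal$length_m / 2),
    vdot_cp_m3_s = volume_rate(t, config$cibarial, mode, timing, "cp"),
    vdot_pp_m3_s = volume_rate(t, config$pharyngeal, mode, timing, "pp")
  )
  attr(out, "mode") <- mode
  attr(out, "period_s") <- period
  out
}
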