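# Instantaneous flow solution of the five-unknown control-volume system
# (Q1, Q2, Q3, p_CP, p_PP). At each instant the tube network is linear once
# the valve state is fixed; the valve state in turn depends on the signs of
# Q2 and Q3. The solver enumerates the four (sign Q2, sign Q3) branches in
# the fixed order (+,+), (+,-), (-,+), (-,-) and accepts the first branch
# whose solution reproduces the assumed signs (Q exactly zero counts as
# forward). This is deterministic and exhaustive; if no branch is
# self-consistent the solver reports non-convergence rather than guessing.

# internal: the three tube impedances for a given branch pair (logical
# closed flags), as a list of scalars
branch_impedances <- function(config, pharyngeal_closed, esophageal_closed) {
  mu <- config$fluid$viscosity_pa_s
  k1 <- tube_impedance(config$feeding_canal$length_m,
                       config$feeding_canal$diameter_m, mu)
  k2 <- if (pharyngeal_closed) {
    tube_impedance(config$pharynx$length_m - config$valve$constricted_length_m,
                   config$pharynx$diameter_m, mu) +
      tube_impedance(config$valve$constricted_length_m,
                     config$valve$constricted_diameter_m, mu)
  } else {
    tube_impedance(config$pharynx$length_m, config$pharynx$diameter_m, mu)
  }
  k3 <- tube_impedance(config$esophagus$length_m,
                       config$esophagus$diameter_m, mu)
  if (esophageal_closed) k3 <- k3 * config$valve$esophageal_backflow_factor
  list(k1 = k1, k2 = k2, k3 = k3)
}

#' Valve-dependent tube impedances
#'
#' Maps assumed flow directions in the pharynx and esophagus to the
#' impedance set used by the instant solver. The feeding-canal impedance is
#' direction-independent; the pharyngeal valve constricts under backflow
#' (`sign_q2 = -1`); the esophageal valve multiplies the esophageal
#' impedance by the configured backflow factor (`sign_q3 = -1`). A zero
#' sign maps to the forward (open) branch.
#'
#' @param sign_q2,sign_q3 Assumed signs of the pharyngeal and esophageal
#'   flows: -1, 0, or +1.
#' @param config A [system_config()] object.
#' @return A list with `k1_pa_s_m3`, `k2_pa_s_m3`, `k3_pa_s_m3`,
#'   `pharyngeal_valve_closed`, `esophageal_valve_closed`.
#' @export
impedance_state <- function(sign_q2, sign_q3, config) {
  stopifnot(inherits(config, "mozpump_config"))
  p_closed <- sign_q2 < 0
  e_closed <- sign_q3 < 0
  k <- branch_impedances(config, p_closed, e_closed)
  list(k1_pa_s_m3 = k$k1, k2_pa_s_m3 = k$k2, k3_pa_s_m3 = k$k3,
       pharyngeal_valve_closed = p_closed,
       esophageal_valve_closed = e_closed)
}

# branch enumeration order: forward-most first; each row is
# (pharyngeal_closed, esophageal_closed)
.branch_order <- rbind(c(FALSE, FALSE), c(FALSE, TRUE),
                       c(TRUE, FALSE), c(TRUE, TRUE))

# internal vectorized solver core. vdot_cp, vdot_pp are equal-length
# vectors; returns a list of equal-length vectors plus valve flags.
# Pressures are absolute (p_food + drop); p_food, dp_gut from config.
solve_instants <- function(vdot_cp, vdot_pp, dp_gut, config) {
  n <- length(vdot_cp)
  stopifnot(length(vdot_pp) == n)
  if (!all(is.finite(vdot_cp)) || !all(is.finite(vdot_pp)) ||
      !is.finite(dp_gut)) {
    stop("volume rates and gut backpressure must be finite", call. = FALSE)
  }
  p_food <- config$boundaries$p_food_pa
  q1 <- q2 <- q3 <- p_cp <- p_pp <- rep(NA_real_, n)
  p_closed <- e_closed <- rep(NA, n)
  unresolved <- rep(TRUE, n)
  for (b in seq_len(nrow(.branch_order))) {
    if (!any(unresolved)) break
    pc <- .branch_order[b, 1]
    ec <- .branch_order[b, 2]
    k <- branch_impedances(config, pc, ec)
    sk <- k$k1 + k$k2 + k$k3
    i <- which(unresolved)
    cq1 <- -dp_gut / sk + vdot_cp[i] / sk * (k$k2 + k$k3) +
      vdot_pp[i] / sk * k$k3
    cq2 <- -dp_gut / sk - vdot_cp[i] / sk * k$k1 + vdot_pp[i] / sk * k$k3
    cq3 <- -dp_gut / sk - vdot_cp[i] / sk * k$k1 -
      vdot_pp[i] / sk * (k$k1 + k$k2)
    ok2 <- if (pc) cq2 < 0 else cq2 >= 0
    ok3 <- if (ec) cq3 < 0 else cq3 >= 0
    hit <- ok2 & ok3
    if (any(hit)) {
      j <- i[hit]
      q1[j] <- cq1[hit]
      q2[j] <- cq2[hit]
      q3[j] <- cq3[hit]
      p_cp[j] <- p_food - k$k1 * cq1[hit]
      p_pp[j] <- p_cp[j] - k$k2 * cq2[hit]
      p_closed[j] <- pc
      e_closed[j] <- ec
      unresolved[j] <- FALSE
    }
  }
  if (any(unresolved)) {
    idx <- which(unresolved)
    stop(sprintf(
      "no sign-consistent valve branch at %d instant(s); first index %d (vdot_cp = %g, vdot_pp = %g)",
      length(idx), idx[1], vdot_cp[idx[1]], vdot_pp[idx[1]]),
      call. = FALSE)
  }
  list(q1_m3_s = q1, q2_m3_s = q2, q3_m3_s = q3,
       p_cp_pa = p_cp, p_pp_pa = p_pp,
       pharyngeal_valve_closed = p_closed,
       esophageal_valve_closed = e_closed)
}

#' Solve the instantaneous flow system
#'
#' Given the two pump volume rates and the gut backpressure, returns the
#' unique sign-consistent solution for the three tube flows and the two
#' pump pressures.
#'
#' @param vdot_cp_m3_s,vdot_pp_m3_s Cibarial and pharyngeal pump volume
#'   rates, m^3/s.
#' @param dp_gut_pa Gut backpressure `p_gut - p_food`, Pa (default: from
#'   `config`).
#' @param config A [system_config()] object.
#' @return A list with flows `q1_m3_s`, `q2_m3_s`, `q3_m3_s`, absolute
#'   pump pressures `p_cp_pa`, `p_pp_pa`, the `impedances` actually used
#'   (see [impedance_state()]), and `converged = TRUE`.
#' @export
solve_instant <- function(vdot_cp_m3_s, vdot_pp_m3_s,
                          dp_gut_pa = config$boundaries$dp_gut_pa, config) {
  stopifnot(inherits(config, "mozpump_config"))
  sol <- solve_instants(vdot_cp_m3_s, vdot_pp_m3_s, dp_gut_pa, config)
  imp <- impedance_state(
    ifelse(sol$pharyngeal_valve_closed, -1, 1),
    ifelse(sol$esophageal_valve_closed, -1, 1),
    config)
  list(q1_m3_s = sol$q1_m3_s, q2_m3_s = sol$q2_m3_s, q3_m3_s = sol$q3_m3_s,
       p_cp_pa = sol$p_cp_pa, p_pp_pa = sol$p_pp_pa,
       impedances = imp, converged = TRUE)
}

#' Simulate one period of a drinking mode
#'
#' Runs the prescribed kinematics through the instant solver on a uniform
#' grid spanning exactly one mode period. The kinematics are periodic and
#' the quasi-steady system is memoryless, so no spin-up is needed: the
#' solution is periodic by construction. Pump powers are attached (see
#' [pump_power()]).
#'
#' @param mode `"continuous"` or `"burst"`.
#' @param config A [system_config()] object.
#' @param timing A [mode_timing()] object.
#' @param n_steps Grid intervals per period (default 2000).
#' @return An object of class `mozpump_sim`: a list with the time grid and
#'   per-step flows, pressures, pump states, powers, and valve flags, plus
#'   snapshots of the configuration and timing.
#' @export
simulate_mode <- function(mode = c("continuous", "burst"), config,
                          timing = default_timing(), n_steps = 2000) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "mozpump_config"))
  kin <- kinematics_timeline(mode, config, timing, n_steps)
  sol <- solve_instants(kin$vdot_cp_m3_s, kin$vdot_pp_m3_s,
                        config$boundaries$dp_gut_pa, config)
  p_hemo <- config$boundaries$p_hemo_pa
  out <- list(
    mode = mode,
    t_s = kin$t_s,
    period_s = attr(kin, "period_s"),
    a_cp_m = kin$a_cp_m, a_pp_m = kin$a_pp_m,
    v_cp_m3 = kin$v_cp_m3, v_pp_m3 = kin$v_pp_m3,
    vdot_cp_m3_s = kin$vdot_cp_m3_s, vdot_pp_m3_s = kin$vdot_pp_m3_s,
    q1_m3_s = sol$q1_m3_s, q2_m3_s = sol$q2_m3_s, q3_m3_s = sol$q3_m3_s,
    p_cp_pa = sol$p_cp_pa, p_pp_pa = sol$p_pp_pa,
    p_pow_cp_w = pump_power(sol$p_cp_pa, p_hemo, kin$vdot_cp_m3_s),
    p_pow_pp_w = pump_power(sol$p_pp_pa, p_hemo, kin$vdot_pp_m3_s),
    pharyngeal_valve_closed = sol$pharyngeal_valve_closed,
    esophageal_valve_closed = sol$esophageal_valve_closed,
    config = config, timing = timing, n_steps = as.integer(n_steps)
  )
  class(out) <- "mozpump_sim"
  out
}

#' Maximum pressure drop across the proboscis
#'
#' `max_t |p_CP(t) - p_food|`, the headline suction metric of a simulated
#' mode.
#'
#' @param sim A `mozpump_sim` from [simulate_mode()].
#' @return Pressure in Pa.
#' @export
max_proboscis_pressure_drop <- function(sim) {
  stopifnot(inherits(sim, "mozpump_sim"))
  if (length(sim$p_cp_pa) == 0) stop("empty simulation", call. = FALSE)
  max(abs(sim$p_cp_pa - sim$config$boundaries$p_food_pa))
}

#' @export
print.mozpump_sim <- function(x, ...) {
  cat(sprintf("<mozpump_sim> %s mode, %d steps over %.4g s\n",
              x$mode, x$n_steps, x$period_s))
  cat(sprintf("  Q_avg = %.3g nL/s, max |dp| = %.3g kPa, P_avg = %.3g nW\n",
              time_average_flow(x) * 1e12,
              max_proboscis_pressure_drop(x) / 1e3,
              mode_average_power(x) * 1e9))
  invisible(x)
}

# internal: trapezoidal time-average of y over the (uniform, period-closing)
# grid t. With both period endpoints present this is the exact periodic
# trapezoid mean.
trapz_mean <- function(t, y) {
  n <- length(t)
  sum(diff(t) * (y[-1] + y[-n]) / 2) / (t[n] - t[1])
}
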