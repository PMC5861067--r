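# Virtual single-pump knockouts: one pump is replaced by a static circular
# tube of its length and resting height, and the reduced network is
# re-solved. With the pharyngeal pump removed, the pharynx, knockout tube,
# and esophagus carry a single series flow Q4, so the sign of Q4 selects
# the branch of both the pharyngeal and esophageal valves simultaneously.
# With the cibarial pump removed, the feeding canal, knockout tube, and
# pharynx carry Q5 while the esophagus carries Q3.

#' Impedance of a knocked-out pump
#'
#' A removed pump is modelled as a straight circular tube with the pump's
#' length and its resting height as diameter: `kappa(L, H_min)`, constant
#' in time.
#'
#' @param pump_geom A [pump_geometry()] object.
#' @param viscosity_pa_s Dynamic viscosity, Pa s.
#' @return Impedance in Pa s/m^3.
#' @export
knockout_impedance <- function(pump_geom, viscosity_pa_s = 3.0e-3) {
  stopifnot(inherits(pump_geom, "mozpump_pump"))
  tube_impedance(pump_geom$length_m, pump_geom$h_min_m, viscosity_pa_s)
}

# internal vectorized solver, pharyngeal pump removed.
# Returns q1, q4, p_cp (absolute), valve flags.
solve_pp_removed_vec <- function(vdot_cp, dp_gut, config) {
  n <- length(vdot_cp)
  mu <- config$fluid$viscosity_pa_s
  k_pp <- knockout_impedance(config$pharyngeal, mu)
  p_food <- config$boundaries$p_food_pa
  q1 <- q4 <- p_cp <- rep(NA_real_, n)
  p_closed <- e_closed <- rep(NA, n)
  unresolved <- rep(TRUE, n)
  # single series flow: both valves see sign(Q4); enumerate the same four
  # branch pairs for determinism, forward-most first
  for (b in seq_len(nrow(.branch_order))) {
    if (!any(unresolved)) break
    pc <- .branch_order[b, 1]
    ec <- .branch_order[b, 2]
    k <- branch_impedances(config, pc, ec)
    k4 <- k$k2 + k_pp + k$k3
    sk <- k$k1 + k4
    i <- which(unresolved)
    cq4 <- -dp_gut / sk - vdot_cp[i] * k$k1 / sk
    ok2 <- if (pc) cq4 < 0 else cq4 >= 0
    ok3 <- if (ec) cq4 < 0 else cq4 >= 0
    hit <- ok2 & ok3
    if (any(hit)) {
      j <- i[hit]
      q4[j] <- cq4[hit]
      q1[j] <- -dp_gut / sk + vdot_cp[j] * k4 / sk
      p_cp[j] <- p_food + dp_gut * k$k1 / sk - vdot_cp[j] * k$k1 * k4 / sk
      p_closed[j] <- pc
      e_closed[j] <- ec
      unresolved[j] <- FALSE
    }
  }
  if (any(unresolved)) {
    stop("no sign-consistent branch in pharyngeal-knockout solve at index ",
         which(unresolved)[1], call. = FALSE)
  }
  list(q1_m3_s = q1, q4_m3_s = q4, p_cp_pa = p_cp,
       pharyngeal_valve_closed = p_closed,
       esophageal_valve_closed = e_closed)
}

# internal vectorized solver, cibarial pump removed.
# Returns q5, q3, p_pp (absolute), valve flags. The pharyngeal valve sees
# sign(Q5) (flow through feeding canal, knockout, pharynx), the esophageal
# valve sees sign(Q3).
solve_cp_removed_vec <- function(vdot_pp, dp_gut, config) {
  n <- length(vdot_pp)
  mu <- config$fluid$viscosity_pa_s
  k_cp <- knockout_impedance(config$cibarial, mu)
  p_food <- config$boundaries$p_food_pa
  q5 <- q3 <- p_pp <- rep(NA_real_, n)
  p_closed <- e_closed <- rep(NA, n)
  unresolved <- rep(TRUE, n)
  for (b in seq_len(nrow(.branch_order))) {
    if (!any(unresolved)) break
    pc <- .branch_order[b, 1]
    ec <- .branch_order[b, 2]
    k <- branch_impedances(config, pc, ec)
    k5 <- k$k1 + k_cp + k$k2
    sk <- k5 + k$k3
    i <- which(unresolved)
    cq5 <- -dp_gut / sk + vdot_pp[i] * k$k3 / sk
    cq3 <- -dp_gut / sk - vdot_pp[i] * k5 / sk
    ok2 <- if (pc) cq5 < 0 else cq5 >= 0
    ok3 <- if (ec) cq3 < 0 else cq3 >= 0
    hit <- ok2 & ok3
    if (any(hit)) {
      j <- i[hit]
      q5[j] <- cq5[hit]
      q3[j] <- cq3[hit]
      p_pp[j] <- p_food + dp_gut * k5 / sk - vdot_pp[j] * k$k3 * k5 / sk
      p_closed[j] <- pc
      e_closed[j] <- ec
      unresolved[j] <- FALSE
    }
  }
  if (any(unresolved)) {
    stop("no sign-consistent branch in cibarial-knockout solve at index ",
         which(unresolved)[1], call. = FALSE)
  }
  list(q5_m3_s = q5, q3_m3_s = q3, p_pp_pa = p_pp,
       pharyngeal_valve_closed = p_closed,
       esophageal_valve_closed = e_closed)
}

#' Instantaneous solve with the pharyngeal pump removed
#'
#' @param vdot_cp_m3_s Cibarial pump volume rate(s), m^3/s.
#' @param dp_gut_pa Gut backpressure, Pa (default: from `config`).
#' @param config A [system_config()] object.
#' @return A list with `q1_m3_s`, `q4_m3_s` (the series flow through
#'   pharynx, knockout tube, and esophagus), `p_cp_pa`, and valve flags.
#' @export
solve_pp_removed <- function(vdot_cp_m3_s,
                             dp_gut_pa = config$boundaries$dp_gut_pa,
                             config) {
  stopifnot(inherits(config, "mozpump_config"))
  solve_pp_removed_vec(vdot_cp_m3_s, dp_gut_pa, config)
}

#' Instantaneous solve with the cibarial pump removed
#'
#' @param vdot_pp_m3_s Pharyngeal pump volume rate(s), m^3/s.
#' @param dp_gut_pa Gut backpressure, Pa (default: from `config`).
#' @param config A [system_config()] object.
#' @return A list with `q5_m3_s` (the series flow through feeding canal,
#'   knockout tube, and pharynx), `q3_m3_s`, `p_pp_pa`, and valve flags.
#' @export
solve_cp_removed <- function(vdot_pp_m3_s,
                             dp_gut_pa = config$boundaries$dp_gut_pa,
                             config) {
  stopifnot(inherits(config, "mozpump_config"))
  solve_cp_removed_vec(vdot_pp_m3_s, dp_gut_pa, config)
}

#' Simulate one period with a single pump knocked out
#'
#' Runs the same kinematics grid as [simulate_mode()] with one pump
#' replaced by its static knockout tube. The inlet flow (`q1` for the
#' pharyngeal knockout, `q5` for the cibarial knockout) is reported as
#' `q_in_m3_s`; the proboscis pressure-drop metric uses the remaining
#' pump's pressure.
#'
#' @param mode `"continuous"` or `"burst"`.
#' @param remove Which pump to remove: `"pp"` (pharyngeal) or `"cp"`
#'   (cibarial).
#' @param config A [system_config()] object.
#' @param timing A [mode_timing()] object.
#' @param n_steps Grid intervals per period (default 2000).
#' @return An object of class `mozpump_ko_sim`.
#' @export
simulate_knockout <- function(mode = c("continuous", "burst"),
                              remove = c("pp", "cp"), config,
                              timing = default_timing(), n_steps = 2000) {
  mode <- match.arg(mode)
  remove <- match.arg(remove)
  stopifnot(inherits(config, "mozpump_config"))
  kin <- kinematics_timeline(mode, config, timing, n_steps)
  dp_gut <- config$boundaries$dp_gut_pa
  p_hemo <- config$boundaries$p_hemo_pa
  if (remove == "pp") {
    sol <- solve_pp_removed_vec(kin$vdot_cp_m3_s, dp_gut, config)
    q_in <- sol$q1_m3_s
    q_out <- sol$q4_m3_s
    p_pump <- sol$p_cp_pa
    vdot <- kin$vdot_cp_m3_s
  } else {
    sol <- solve_cp_removed_vec(kin$vdot_pp_m3_s, dp_gut, config)
    q_in <- sol$q5_m3_s
    q_out <- sol$q3_m3_s
    p_pump <- sol$p_pp_pa
    vdot <- kin$vdot_pp_m3_s
  }
  pw <- pump_power(p_pump, p_hemo, vdot)
  out <- list(
    mode = mode, removed = remove,
    t_s = kin$t_s, period_s = attr(kin, "period_s"),
    q_in_m3_s = q_in, q_out_m3_s = q_out,
    p_pump_pa = p_pump, vdot_m3_s = vdot,
    p_pow_cp_w = if (remove == "pp") pw else numeric(length(pw)),
    p_pow_pp_w = if (remove == "cp") pw else numeric(length(pw)),
    pharyngeal_valve_closed = sol$pharyngeal_valve_closed,
    esophageal_valve_closed = sol$esophageal_valve_closed,
    config = config, timing = timing, n_steps = as.integer(n_steps)
  )
  class(out) <- "mozpump_ko_sim"
  out
}

#' Compare single-pump and two-pump performance
#'
#' Runs the two-pump simulation and the requested knockout on identical
#' grids and reports signed percentage changes (knockout relative to the
#' two-pump baseline) in time-averaged flow, peak inlet flow, maximum
#' proboscis pressure drop, and cycle-averaged input power.
#'
#' @param mode `"continuous"` or `"burst"`.
#' @param remove Pump to remove; defaults to the mode's minor pump
#'   (`"pp"` in continuous mode, `"cp"` in burst mode).
#' @param config A [system_config()] object.
#' @param timing A [mode_timing()] object.
#' @param n_steps Grid intervals per period (default 2000).
#' @return A list with the baseline and knockout summary values (SI units)
#'   and the percentage changes `flow_change_pct`, `peak_flow_change_pct`,
#'   `dp_change_pct`, `power_change_pct`.
#' @export
knockout_comparison <- function(mode = c("continuous", "burst"),
                                remove = NULL, config = default_config(),
                                timing = default_timing(), n_steps = 2000) {
  mode <- match.arg(mode)
  if (is.null(remove)) remove <- if (mode == "continuous") "pp" else "cp"
  remove <- match.arg(remove, c("pp", "cp"))
  base <- simulate_mode(mode, config, timing, n_steps)
  ko <- simulate_knockout(mode, remove, config, timing, n_steps)
  p_food <- config$boundaries$p_food_pa
  b_flow <- trapz_mean(base$t_s, base$q1_m3_s)
  k_flow <- trapz_mean(ko$t_s, ko$q_in_m3_s)
  b_peak <- max(base$q1_m3_s)
  k_peak <- max(ko$q_in_m3_s)
  b_dp <- max_proboscis_pressure_drop(base)
  k_dp <- max(abs(ko$p_pump_pa - p_food))
  b_pow <- mode_average_power(base)
  k_pow <- mode_average_power(ko)
  pct <- function(k, b) 100 * (k - b) / b
  list(mode = mode, removed = remove,
       baseline = list(q_avg_m3_s = b_flow, q_peak_m3_s = b_peak,
                       dp_max_pa = b_dp, p_avg_w = b_pow),
       knockout = list(q_avg_m3_s = k_flow, q_peak_m3_s = k_peak,
                       dp_max_pa = k_dp, p_avg_w = k_pow),
       flow_change_pct = pct(k_flow, b_flow),
       peak_flow_change_pct = pct(k_peak, b_peak),
       dp_change_pct = pct(k_dp, b_dp),
       power_change_pct = pct(k_pow, b_pow))
}
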