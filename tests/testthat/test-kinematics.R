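test_that("continuous-mode minor axis hits its endpoints and midpoint", {
  g <- ref_config$cibarial
  tau <- ref_timing$tau_cp_c_s
  tc <- ref_timing$t_c_s
  expect_equal(minor_axis_continuous(tau, g, ref_timing, "cp"),
               g$h_min_m / 2)
  expect_equal(minor_axis_continuous(tau + tc / 2, g, ref_timing, "cp"),
               g$h_max_continuous_m / 2)
  # quarter-cycle midpoint: (H_min + H_max)/4 = 22 um for the cibarial pump
  expect_equal(minor_axis_continuous(tau + tc / 4, g, ref_timing, "cp"),
               22e-6)
  # periodicity
  t <- seq(0, tc, length.out = 17)
  expect_equal(minor_axis_continuous(t + 3 * tc, g, ref_timing, "cp"),
               minor_axis_continuous(t, g, ref_timing, "cp"))
  # pharyngeal delay shifts the waveform
  gp <- ref_config$pharyngeal
  expect_equal(minor_axis_continuous(ref_timing$tau_pp_c_s, gp, ref_timing,
                                     "pp"), gp$h_min_m / 2)
})

test_that("burst-mode minor axis is an isolated, C1-continuous hump", {
  gp <- ref_config$pharyngeal
  expect_equal(minor_axis_burst(0, gp, ref_timing, "pp"), gp$h_min_m / 2)
  mid <- (ref_timing$t_s_pp_s + ref_timing$t_e_pp_s) / 2
  expect_equal(minor_axis_burst(mid, gp, ref_timing, "pp"), 128e-6)
  # value and slope continuity at the stroke edges
  for (p in c("cp", "pp")) {
    g <- if (p == "cp") ref_config$cibarial else ref_config$pharyngeal
    for (edge in if (p == "cp") c(ref_timing$t_s_cp_s, ref_timing$t_e_cp_s)
                 else c(ref_timing$t_s_pp_s, ref_timing$t_e_pp_s)) {
      eps <- 1e-9
      a <- minor_axis_burst(c(edge - eps, edge, edge + eps), g, ref_timing, p)
      expect_lt(max(abs(a - g$h_min_m / 2)), 1e-12)
      dv <- volume_rate(c(edge - eps, edge + eps), g, "burst", ref_timing, p)
      expect_lt(max(abs(dv)), 1e-12)
    }
  }
  # wrap by period
  expect_equal(minor_axis_burst(mid + ref_timing$t_b_s, gp, ref_timing, "pp"),
               minor_axis_burst(mid, gp, ref_timing, "pp"))
})

test_that("pump volume follows the prolate-spheroid formula", {
  expect_equal(pump_volume(19e-6, 116e-6) * 1e12, 0.18, tolerance = 0.03)
  expect_equal(pump_volume(31.5e-6, 116e-6) * 1e12, 0.48, tolerance = 0.01)
  expect_equal(pump_volume(0, 1e-4), 0)
  expect_equal(pump_volume(2e-6, 3e-6), 4 * pi / 3 * 4e-12 * 3e-6)
  # burst-mode pharyngeal stroke volume from the geometry
  dv <- pump_volume(128e-6, 163e-6) - pump_volume(22e-6, 163e-6)
  expect_equal(dv * 1e12, 10.86, tolerance = 1e-3)
})

test_that("analytic volume rate matches finite differences and integrates to zero", {
  h <- 1e-7
  for (mode in c("continuous", "burst")) {
    period <- if (mode == "continuous") ref_timing$t_c_s else ref_timing$t_b_s
    t <- seq(0.01, period - 0.01, length.out = 200)
    for (p in c("cp", "pp")) {
      g <- if (p == "cp") ref_config$cibarial else ref_config$pharyngeal
      b <- g$length_m / 2
      axis_fun <- if (mode == "continuous") minor_axis_continuous else
        minor_axis_burst
      v <- function(tt) pump_volume(axis_fun(tt, g, ref_timing, p), b)
      fd <- (v(t + h) - v(t - h)) / (2 * h)
      an <- volume_rate(t, g, mode, ref_timing, p)
      scale <- max(abs(an))
      expect_lt(max(abs(an - fd)) / scale, 1e-4)
      # closure over one period (trapezoid on a fine grid)
      tg <- seq(0, period, length.out = 4001)
      vd <- volume_rate(tg, g, mode, ref_timing, p)
      integral <- sum(diff(tg) * (vd[-1] + vd[-length(vd)]) / 2)
      expect_lt(abs(integral), 1e-6 * max(abs(vd)) * period)
    }
  }
})

test_that("kinematics timeline is self-consistent and attains the extremes", {
  for (mode in c("continuous", "burst")) {
    tl <- kinematics_timeline(mode, ref_config, ref_timing, 2000)
    expect_equal(nrow(tl), 2001)
    expect_equal(diff(tl$t_s)[1], attr(tl, "period_s") / 2000)
    expect_equal(tl$v_cp_m3,
                 pump_volume(tl$a_cp_m, ref_config$cibarial$length_m / 2))
    hmax <- if (mode == "continuous") ref_config$pharyngeal$h_max_continuous_m
            else ref_config$pharyngeal$h_max_burst_m
    expect_equal(min(tl$a_pp_m), ref_config$pharyngeal$h_min_m / 2,
                 tolerance = 1e-6)
    expect_equal(max(tl$a_pp_m), hmax / 2, tolerance = 1e-6)
  }
  expect_error(kinematics_timeline("continuous", ref_config, ref_timing, 50),
               ">= 100")
})
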