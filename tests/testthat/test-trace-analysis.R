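make_trace <- function(cp, pp, fps = 30) {
  n <- length(cp)
  intensity_trace((seq_len(n) - 1) / fps, cp, pp)
}

test_that("3-point smoothing averages interiors and shrinks at the ends", {
  tr <- make_trace(c(0, 3, 0, 0, 0), rep(1, 5))
  sm <- smooth_trace(tr)
  expect_equal(sm$intensity_cp[2], 1)           # (0+3+0)/3
  expect_equal(sm$intensity_cp[1], 1.5)         # shrunken end window
  expect_equal(sm$intensity_pp, rep(1, 5))      # constant unchanged
  # white-noise variance shrinks by ~3 in the interior
  set.seed(11)
  x <- rnorm(30000)
  y <- mozpump:::moving_average(x, 3L)
  expect_equal(stats::sd(y[2:29999]), 1 / sqrt(3), tolerance = 0.02)
  expect_error(smooth_trace(tr, window = 2), "odd")
})

test_that("per-bout normalization maps each bout onto [0, 1]", {
  tr <- make_trace(c(10, 15, 20, 2, 4, 6), c(1, 2, 3, 4, 5, 6))
  nb <- normalize_trace(tr, bouts = list(c(1, 3), c(4, 6)))
  expect_equal(nb$intensity_cp, c(0, 0.5, 1, 0, 0.5, 1))
  expect_equal(range(nb$intensity_pp[1:3]), c(0, 1))
  # invariant to affine rescaling of the raw intensities
  tr2 <- make_trace(3 * c(10, 15, 20, 2, 4, 6) + 7, c(1, 2, 3, 4, 5, 6))
  nb2 <- normalize_trace(tr2, bouts = list(c(1, 3), c(4, 6)))
  expect_equal(nb2$intensity_cp, nb$intensity_cp)
  flat <- make_trace(rep(1, 5), 1:5)
  expect_error(normalize_trace(flat), "flat bout")
})

test_that("cycle detection finds sinusoid periods and ignores flat traces", {
  fps <- 50
  t <- seq(0, 5 - 1 / fps, by = 1 / fps)
  x <- 0.5 + 0.5 * sin(2 * pi * t)  # 5 periods
  tr <- intensity_trace(t, x, x)
  ev <- detect_cycles(tr, "cp")
  expect_equal(nrow(ev), 5)
  # peaks at the crests, starts/ends at troughs (or the trace edge)
  expect_equal(ev$peak_s, 0.25 + 0:4, tolerance = 0.03)
  expect_equal(ev$start_s[-1], 0.75 + 0:3, tolerance = 0.03)
  flat <- make_trace(rep(0.5, 60), rep(0.5, 60))
  expect_equal(nrow(detect_cycles(flat, "cp")), 0)
  # sub-prominence wiggles are pruned
  y <- 0.5 + 0.04 * sin(2 * pi * t)
  expect_equal(nrow(detect_cycles(intensity_trace(t, y, y), "cp")), 0)
})

test_that("noise-free synthetic cycles are recovered within one frame", {
  recipe <- trace_recipe(list(segment_continuous(10)), noise_sd = 0)
  g <- generate_trace(recipe, seed = 1)
  res <- analyze_trace(g$trace)
  frame <- 1 / 30
  for (ch in c("cp", "pp")) {
    truth <- g$truth[g$truth$channel == ch, ]
    ev <- res[[paste0(ch, "_events")]]
    expect_equal(nrow(ev), nrow(truth))
    expect_lt(max(abs(ev$peak_s - truth$peak_s)), frame + 1e-9)
    expect_lt(max(abs(ev$start_s - truth$start_s)), frame + 1e-9)
    expect_lt(max(abs(ev$end_s - truth$end_s)), frame + 1e-9)
  }
})

test_that("timing table identities hold for identical event trains", {
  ev <- data.frame(start_s = c(0, 1, 2), peak_s = c(0.3, 1.3, 2.3),
                   end_s = c(0.6, 1.6, 2.6))
  cy <- timing_cycles(ev, ev)
  expect_true(all(cy$between_starts_ms == 0))
  expect_true(all(cy$between_peaks_ms == 0))
  expect_true(all(cy$between_ends_ms == 0))
  expect_equal(cy$cp_pp_ratio, rep(1, 3))
  expect_equal(cy$frequency_hz[1:2], c(1, 1))
  # negative time-to-next when the next cycle starts before this one ends
  pp <- data.frame(start_s = c(0.5, 1.5, 2.5), peak_s = c(0.7, 1.7, 2.7),
                   end_s = c(1.2, 2.2, 3.2))
  cy2 <- timing_cycles(ev, pp)
  expect_true(all(cy2$time_to_next_ms[1:2] < 0))
  tt <- timing_table(cy2)
  expect_equal(tt$mean_ms[tt$variable == "total_cycle_ms"], 1200)
  expect_equal(tt$mean_rel_pct[tt$variable == "total_cycle_ms"], 100)
})

test_that("amplitude-based classification separates burst strokes", {
  # equal amplitudes: everything continuous
  fps <- 30
  t <- seq(0, 4, by = 1 / fps)
  x <- 1 + 0.5 * (1 - cos(2 * pi * 2 * t))
  tr <- intensity_trace(t, x, x)
  ev <- detect_cycles(normalize_trace(tr), "pp")
  lab <- classify_mode(ev, tr, "pp")
  expect_true(all(lab$mode == "continuous"))
  # synthetic bursts with 17x pharyngeal stroke volume: exactly 2 burst
  # labels, none missed
  g <- generate_trace(default_trace_recipe(pp_burst_volume_factor = 17),
                      seed = 4)
  res <- analyze_trace(g$trace)
  truth_b <- g$truth[g$truth$channel == "pp" & g$truth$mode == "burst", ]
  got_b <- res$pp_events[res$pp_events$mode == "burst", ]
  expect_equal(nrow(got_b), 2)
  expect_lt(max(abs(sort(got_b$peak_s) - sort(truth_b$peak_s))), 2 / 30)
  # a single isolated large event falls back to the absolute threshold
  y <- rep(1, 90)
  y[40:50] <- 1 + 10 * (1 - cos(2 * pi * (0:10) / 10))
  tr1 <- make_trace(y, y)
  ev1 <- detect_cycles(normalize_trace(tr1), "cp")
  lab1 <- classify_mode(ev1, tr1, "cp")
  expect_equal(lab1$mode, "burst")
})

test_that("smoothing and normalization commute with affine intensity rescaling", {
  set.seed(21)
  base <- cumsum(rnorm(120))
  tr <- make_trace(base, rev(base))
  tr_aff <- make_trace(5 * base - 2, 5 * rev(base) - 2)
  a <- normalize_trace(smooth_trace(tr))
  b <- normalize_trace(smooth_trace(tr_aff))
  expect_equal(a$intensity_cp, b$intensity_cp, tolerance = 1e-12)
  expect_equal(a$intensity_pp, b$intensity_pp, tolerance = 1e-12)
})

test_that("frequency recovery holds across the reported 2-12 Hz range", {
  # sampled at 100 Hz so the upper end of the range is resolvable
  for (f in c(2, 4, 8, 12)) {
    tc <- 1 / f
    tim <- mode_timing(t_c_s = tc, tau_pp_c_s = 0.3 * tc)
    r <- trace_recipe(list(segment_continuous(15)), fps = 100, timing = tim)
    g <- generate_trace(r, seed = 30 + f)
    res <- analyze_trace(g$trace)
    fr <- res$timing$mean_ms[res$timing$variable == "frequency_hz"]
    expect_lt(abs(fr / f - 1), 0.05)
  }
})
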