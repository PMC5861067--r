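test_that("generation is deterministic for a fixed seed", {
  r <- default_trace_recipe()
  g1 <- generate_trace(r, seed = 9)
  g2 <- generate_trace(r, seed = 9)
  expect_identical(g1$trace, g2$trace)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_trace(r, seed = 10)
  expect_false(identical(g1$trace$intensity_cp, g3$trace$intensity_cp))
  expect_error(generate_trace(r), "seed")
})

test_that("noise-free traces are exact affine images of the volume schedule", {
  r <- trace_recipe(list(segment_continuous(5)), noise_sd = 0,
                    gain_cp = 20, offset_cp = 3)
  g <- generate_trace(r, seed = 1)
  tr <- g$trace
  # reconstruct the cibarial volume from the waveform directly
  cfg <- default_config()
  tc <- default_timing()$t_c_s
  gcp <- cfg$cibarial
  a <- minor_axis_continuous(tr$time_s, gcp, default_timing(), "cp")
  v_nl <- pump_volume(a, gcp$length_m / 2) * 1e12
  in_stroke <- tr$time_s <= 5 * tc
  expect_equal(tr$intensity_cp[in_stroke], (3 + 20 * v_nl)[in_stroke],
               tolerance = 1e-12)
  # exactly n_cycles maxima per channel at zero noise
  res <- analyze_trace(tr)
  expect_equal(nrow(res$cp_events), 5)
  expect_equal(nrow(res$pp_events), 5)
})

test_that("drift adds a linear baseline without breaking detection", {
  r <- trace_recipe(list(segment_continuous(8)), noise_sd = 0,
                    drift_per_s = 2)
  r0 <- trace_recipe(list(segment_continuous(8)), noise_sd = 0)
  g <- generate_trace(r, seed = 2)
  g0 <- generate_trace(r0, seed = 2)
  expect_equal(g$trace$intensity_cp - g0$trace$intensity_cp,
               2 * g$trace$time_s, tolerance = 1e-12)
  res <- analyze_trace(g$trace)
  expect_equal(nrow(res$cp_events), 8)
})

test_that("measured-means recipes carry the per-mode event timings", {
  rc <- recipe_from_paper_means("continuous", n_cycles = 3)
  g <- generate_trace(rc, seed = 1)
  truth_cp <- g$truth[g$truth$channel == "cp", ]
  truth_pp <- g$truth[g$truth$channel == "pp", ]
  # cycle repetition at 4 Hz; total cycle (cibarial start to pharyngeal
  # end) 317 ms; stroke durations 241 and 226 ms
  expect_equal(diff(truth_cp$start_s), rep(0.250, 2))
  expect_equal(truth_pp$end_s[1] - truth_cp$start_s[1], 0.317)
  expect_equal(truth_cp$end_s - truth_cp$start_s, rep(0.241, 3))
  expect_equal(truth_pp$end_s - truth_pp$start_s, rep(0.226, 3))
  rb <- recipe_from_paper_means("burst")
  gb <- generate_trace(rb, seed = 1)
  tb <- gb$truth
  expect_equal(tb$start_s[tb$channel == "cp"], 0.4e-3)
  expect_equal(tb$start_s[tb$channel == "pp"], 0.153)
  rm <- recipe_from_paper_means("mixed", n_cycles = 10)
  gm <- generate_trace(rm, seed = 1)
  tm <- gm$truth
  # pharyngeal burst stroke volume is 17x the continuous stroke volume
  amp <- tm$amplitude_intensity[tm$channel == "pp"]
  modes <- tm$mode[tm$channel == "pp"]
  expect_equal(amp[modes == "burst"] / amp[modes == "continuous"][1], 17,
               tolerance = 1e-9)
})

test_that("end-to-end recovery: timing means within two frames over 50 seeds", {
  frame <- 1 / 30
  errs_start <- errs_peak <- errs_end <- c()
  burst_found <- integer(0)
  for (seed in 1:50) {
    g <- generate_trace(default_trace_recipe(pp_burst_volume_factor = 17),
                        seed = seed)
    res <- analyze_trace(g$trace)
    truth <- g$truth[g$truth$channel == "cp" & g$truth$mode == "continuous", ]
    det <- res$cp_events[res$cp_events$mode == "continuous", ]
    if (nrow(det) == nrow(truth)) {
      errs_start <- c(errs_start, mean(det$start_s - truth$start_s))
      errs_peak <- c(errs_peak, mean(det$peak_s - truth$peak_s))
      errs_end <- c(errs_end, mean(det$end_s - truth$end_s))
    }
    burst_found <- c(burst_found, sum(res$pp_events$mode == "burst"))
  }
  # every replicate recovers both embedded bursts (no false negatives)
  expect_true(all(burst_found >= 2))
  # nearly all replicates recover the full continuous event count, and
  # the recovered timing means sit within two frames of ground truth
  expect_gt(length(errs_peak), 45)
  expect_lt(abs(mean(errs_start)), 2 * frame)
  expect_lt(abs(mean(errs_peak)), 2 * frame)
  expect_lt(abs(mean(errs_end)), 2 * frame)
})
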