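# Ground-truthed synthetic ROI-intensity traces. Each channel's intensity
# is an affine image of the prolate-spheroid pump volume (x-ray absorption
# is linear in the mass of contrast agent), sampled at the video frame
# rate, with optional additive Gaussian noise and linear baseline drift.
# The schedule is a sequence of segments: continuous segments of n
# back-to-back raised-cosine stroke cycles per pump (with the pharyngeal
# phase delay), and burst segments holding one isolated large-stroke event
# per pump. Every generated event's true start/peak/end time, mode label,
# and amplitude are returned alongside the trace.

#' Continuous-pumping schedule segment
#'
#' @param n_cycles Number of stroke cycles.
#' @return A segment specification for [trace_recipe()].
#' @export
segment_continuous <- function(n_cycles) {
  if (n_cycles < 1) stop("`n_cycles` must be >= 1", call. = FALSE)
  list(type = "continuous", n_cycles = as.integer(n_cycles))
}

#' Burst-event schedule segment
#'
#' One isolated large-stroke event (one stroke per pump) occupying one
#' burst period.
#'
#' @return A segment specification for [trace_recipe()].
#' @export
segment_burst <- function() {
  list(type = "burst")
}

#' Recipe for a synthetic intensity trace
#'
#' @param schedule List of segments from [segment_continuous()] /
#'   [segment_burst()], played back to back.
#' @param fps Frame rate, Hz (default 30).
#' @param config A [system_config()] supplying pump geometry.
#' @param timing A [mode_timing()] supplying cycle timing. The continuous
#'   stroke repetition interval can be overridden with
#'   `cycle_interval_s` (>= stroke duration); by default strokes repeat
#'   every `t_c_s` with no rest gap.
#' @param gain_cp,gain_pp Intensity units per nanolitre of pump volume.
#' @param offset_cp,offset_pp Intensity baseline offsets.
#' @param noise_sd Additive Gaussian noise SD as a fraction of the
#'   continuous-stroke intensity amplitude of each channel (default 0.05).
#' @param drift_per_s Linear baseline drift, intensity units per second.
#' @param cycle_interval_s Optional continuous stroke repetition interval,
#'   seconds.
#' @param stroke_durations_s Optional per-pump continuous stroke durations
#'   `c(cp =, pp =)`, seconds (default: the continuous period for both).
#' @param stroke_offsets_s Optional per-pump continuous stroke start
#'   offsets within a cycle `c(cp =, pp =)`, seconds (default: the
#'   continuous-mode phase delays).
#' @param pp_burst_volume_factor Optional override: scale the pharyngeal
#'   burst stroke so its volume change is this multiple of the pharyngeal
#'   continuous-stroke volume change.
#' @param seed Integer seed; generation refuses to run without one.
#' @return An object of class `mozpump_recipe`.
#' @export
trace_recipe <- function(schedule, fps = 30, config = default_config(),
                         timing = default_timing(),
                         gain_cp = 100, gain_pp = 100,
                         offset_cp = 50, offset_pp = 60,
                         noise_sd = 0.05, drift_per_s = 0,
                         cycle_interval_s = NULL,
                         stroke_durations_s = NULL,
                         stroke_offsets_s = NULL,
                         pp_burst_volume_factor = NULL,
                         seed = NULL) {
  check_positive(fps = fps)
  stopifnot(inherits(config, "mozpump_config"),
            inherits(timing, "mozpump_timing"))
  if (length(schedule) == 0) stop("empty schedule", call. = FALSE)
  for (seg in schedule) {
    if (!is.list(seg) || !seg$type %in% c("continuous", "burst")) {
      stop("invalid schedule segment", call. = FALSE)
    }
  }
  if (is.null(cycle_interval_s)) cycle_interval_s <- timing$t_c_s
  if (is.null(stroke_durations_s)) {
    stroke_durations_s <- c(cp = timing$t_c_s, pp = timing$t_c_s)
  }
  if (is.null(stroke_offsets_s)) {
    stroke_offsets_s <- c(cp = timing$tau_cp_c_s, pp = timing$tau_pp_c_s)
  }
  if (any(stroke_durations_s > cycle_interval_s + 1e-12)) {
    stop("continuous stroke durations exceed the cycle interval",
         call. = FALSE)
  }
  structure(list(schedule = schedule, fps = fps, config = config,
                 timing = timing,
                 gain = c(cp = gain_cp, pp = gain_pp),
                 offset = c(cp = offset_cp, pp = offset_pp),
                 noise_sd = noise_sd, drift_per_s = drift_per_s,
                 cycle_interval_s = cycle_interval_s,
                 stroke_durations_s = stroke_durations_s,
                 stroke_offsets_s = stroke_offsets_s,
                 pp_burst_volume_factor = pp_burst_volume_factor,
                 seed = seed),
            class = "mozpump_recipe")
}

#' Default mixed-mode recipe
#'
#' Twenty continuous cycles at the reference timing with two burst events
#' embedded mid-bout (after cycles 7 and 14), emulating the typical
#' appearance of burst events within bouts of continuous pumping.
#'
#' @param n_cycles Total continuous cycles (default 20).
#' @param bursts_after Cycle counts after which a burst is inserted.
#' @param ... Passed to [trace_recipe()].
#' @return A `mozpump_recipe`.
#' @export
default_trace_recipe <- function(n_cycles = 20, bursts_after = c(7, 14),
                                 ...) {
  bursts_after <- sort(unique(bursts_after))
  if (any(bursts_after < 1 | bursts_after >= n_cycles)) {
    stop("`bursts_after` must lie strictly inside the cycle count",
         call. = FALSE)
  }
  sched <- list()
  prev <- 0
  for (b in bursts_after) {
    sched <- c(sched, list(segment_continuous(b - prev)), list(segment_burst()))
    prev <- b
  }
  sched <- c(sched, list(segment_continuous(n_cycles - prev)))
  trace_recipe(schedule = sched, ...)
}

#' Recipe matching the measured mean timings
#'
#' Builds recipes whose event timings equal the measured per-mode means:
#' continuous cycles repeat at 4.0 Hz (250 ms) with cibarial strokes of
#' 241 ms starting 1 ms into the cycle and pharyngeal strokes of 226 ms
#' starting at 92 ms (total cycle about 317 ms, since consecutive cycles
#' overlap); burst events use the modelled start/end times. For the mixed
#' recipe the pharyngeal burst stroke volume is 17 times the continuous
#' stroke volume, matching the observed expansion ratio.
#'
#' @param mode `"continuous"`, `"burst"`, or `"mixed"`.
#' @param n_cycles Continuous cycles (default 20; ignored for pure burst).
#' @param ... Passed to [trace_recipe()].
#' @return A `mozpump_recipe`.
#' @export
recipe_from_paper_means <- function(mode = c("continuous", "burst", "mixed"),
                                    n_cycles = 20, ...) {
  mode <- match.arg(mode)
  args <- list(
    cycle_interval_s = 0.250,
    stroke_durations_s = c(cp = 0.241, pp = 0.226),
    stroke_offsets_s = c(cp = 0.001, pp = 0.092),
    ...
  )
  if (mode == "continuous") {
    do.call(trace_recipe,
            c(list(schedule = list(segment_continuous(n_cycles))), args))
  } else if (mode == "burst") {
    do.call(trace_recipe,
            c(list(schedule = list(segment_burst())), args))
  } else {
    mid <- max(1, floor(n_cycles / 2))
    do.call(trace_recipe,
            c(list(schedule = list(segment_continuous(mid), segment_burst(),
                                   segment_continuous(n_cycles - mid)),
                   pp_burst_volume_factor = 17), args))
  }
}

# internal: per-channel stroke tables (absolute times) for a recipe.
# Each stroke: t0, duration, a_min, a_max, b, mode.
recipe_strokes <- function(recipe) {
  cfg <- recipe$config
  tim <- recipe$timing
  geoms <- list(cp = cfg$cibarial, pp = cfg$pharyngeal)
  strokes <- list(cp = list(), pp = list())
  t0 <- 0
  for (seg in recipe$schedule) {
    if (seg$type == "continuous") {
      dur_seg <- (seg$n_cycles - 1) * recipe$cycle_interval_s +
        max(recipe$stroke_offsets_s + recipe$stroke_durations_s)
      for (ch in c("cp", "pp")) {
        g <- geoms[[ch]]
        for (k in seq_len(seg$n_cycles)) {
          strokes[[ch]][[length(strokes[[ch]]) + 1L]] <- list(
            t0 = t0 + (k - 1) * recipe$cycle_interval_s +
              recipe$stroke_offsets_s[[ch]],
            duration = recipe$stroke_durations_s[[ch]],
            a_min = g$h_min_m / 2, a_max = g$h_max_continuous_m / 2,
            b = g$length_m / 2, mode = "continuous")
        }
      }
      t0 <- t0 + dur_seg
    } else {
      wins <- list(cp = c(tim$t_s_cp_s, tim$t_e_cp_s),
                   pp = c(tim$t_s_pp_s, tim$t_e_pp_s))
      for (ch in c("cp", "pp")) {
        g <- geoms[[ch]]
        a_max <- g$h_max_burst_m / 2
        if (ch == "pp" && !is.null(recipe$pp_burst_volume_factor)) {
          # choose a_max so the stroke volume change is the requested
          # multiple of the continuous stroke volume change
          a_min <- g$h_min_m / 2
          a_c <- g$h_max_continuous_m / 2
          a_max <- sqrt(a_min^2 + recipe$pp_burst_volume_factor *
                          (a_c^2 - a_min^2))
        }
        strokes[[ch]][[length(strokes[[ch]]) + 1L]] <- list(
          t0 = t0 + wins[[ch]][1],
          duration = wins[[ch]][2] - wins[[ch]][1],
          a_min = g$h_min_m / 2, a_max = a_max,
          b = g$length_m / 2, mode = "burst")
      }
      t0 <- t0 + tim$t_b_s
    }
  }
  list(strokes = strokes, total_duration = t0)
}

#' Generate a synthetic intensity trace with ground truth
#'
#' Samples the recipe's volume schedule at the frame rate, maps volume to
#' intensity with the per-channel gain and offset, and adds drift and
#' seeded Gaussian noise. Deterministic for a fixed seed.
#'
#' @param recipe A [trace_recipe()].
#' @param seed Integer seed; overrides the recipe's seed. Mandatory (in
#'   one place or the other) for reproducibility.
#' @return A list with `trace` (a `mozpump_trace`) and `truth` (a data
#'   frame: `channel`, `mode`, `start_s`, `peak_s`, `end_s`,
#'   `amplitude_intensity`).
#' @export
generate_trace <- function(recipe, seed = recipe$seed) {
  stopifnot(inherits(recipe, "mozpump_recipe"))
  if (is.null(seed)) {
    stop("a seed is required (in the recipe or as an argument)",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  st <- recipe_strokes(recipe)
  n <- ceiling(st$total_duration * recipe$fps) + 1L
  t <- (seq_len(n) - 1L) / recipe$fps
  intensity <- list()
  truth <- list()
  for (ch in c("cp", "pp")) {
    ss <- st$strokes[[ch]]
    g <- if (ch == "cp") recipe$config$cibarial else recipe$config$pharyngeal
    v <- rep(pump_volume(g$h_min_m / 2, g$length_m / 2), n)
    cont_amp_v <- NA_real_
    for (s in ss) {
      i <- which(t >= s$t0 & t <= s$t0 + s$duration)
      if (length(i)) {
        a <- s$a_min + (s$a_max - s$a_min) / 2 *
          (1 - cos(2 * pi * (t[i] - s$t0) / s$duration))
        v[i] <- pump_volume(a, s$b)
      }
      dv <- pump_volume(s$a_max, s$b) - pump_volume(s$a_min, s$b)
      if (s$mode == "continuous" && is.na(cont_amp_v)) cont_amp_v <- dv
      truth[[length(truth) + 1L]] <- data.frame(
        channel = ch, mode = s$mode, start_s = s$t0,
        peak_s = s$t0 + s$duration / 2, end_s = s$t0 + s$duration,
        amplitude_intensity = recipe$gain[[ch]] * dv * 1e12,
        stringsAsFactors = FALSE)
    }
    if (is.na(cont_amp_v)) {
      cont_amp_v <- min(vapply(ss, function(s) {
        pump_volume(s$a_max, s$b) - pump_volume(s$a_min, s$b)
      }, numeric(1)))
    }
    y <- recipe$offset[[ch]] + recipe$gain[[ch]] * v * 1e12 +
      recipe$drift_per_s * t
    sd_abs <- recipe$noise_sd * recipe$gain[[ch]] * cont_amp_v * 1e12
    if (sd_abs > 0) y <- y + stats::rnorm(n, 0, sd_abs)
    intensity[[ch]] <- y
  }
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$channel, truth$start_s), ]
  rownames(truth) <- NULL
  list(trace = intensity_trace(t, intensity$cp, intensity$pp),
       truth = truth)
}
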