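# Kinematics extraction from ROI-intensity time series. X-ray absorption is
# linear in the mass of contrast-laden feeding solution, so the mean ROI
# intensity over each pump tracks its volume. The pipeline smooths each
# channel with a 3-point moving average, min-max normalizes per bout,
# detects stroke cycles from alternating local extrema with a prominence
# filter, classifies events into continuous vs burst strokes by relative
# amplitude, and tabulates the cycle timing variables.

#' Construct an intensity trace
#'
#' Two-channel (cibarial, pharyngeal) ROI-intensity time series on a
#' uniform time grid.
#'
#' @param time_s Sample times, seconds; must be uniform.
#' @param intensity_cp,intensity_pp Channel intensities, arbitrary units.
#' @param specimen Specimen identifier (default `"s1"`).
#' @param tol_s Tolerance for uniform-sampling check, seconds.
#' @return A data frame of class `mozpump_trace` with attributes `fps` and
#'   `specimen`.
#' @export
intensity_trace <- function(time_s, intensity_cp, intensity_pp,
                            specimen = "s1", tol_s = 1e-6) {
  n <- length(time_s)
  if (n < 3) stop("trace needs at least 3 samples", call. = FALSE)
  if (length(intensity_cp) != n || length(intensity_pp) != n) {
    stop("channels and time must have equal length", call. = FALSE)
  }
  if (anyNA(time_s) || anyNA(intensity_cp) || anyNA(intensity_pp)) {
    stop("trace contains missing values", call. = FALSE)
  }
  dt <- diff(time_s)
  if (any(dt <= 0) || max(dt) - min(dt) > tol_s) {
    bad <- which(abs(dt - stats::median(dt)) > tol_s)[1]
    stop(sprintf("non-uniform sampling near row %d", bad + 1L),
         call. = FALSE)
  }
  out <- data.frame(time_s = time_s, intensity_cp = intensity_cp,
                    intensity_pp = intensity_pp)
  attr(out, "fps") <- 1 / stats::median(dt)
  attr(out, "specimen") <- specimen
  class(out) <- c("mozpump_trace", "data.frame")
  out
}

# internal: channel column name
channel_col <- function(channel) {
  switch(channel, cp = "intensity_cp", pp = "intensity_pp",
         stop("`channel` must be 'cp' or 'pp'", call. = FALSE))
}

# internal: centered moving average with shrunken end windows
moving_average <- function(x, window) {
  half <- (window - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth a trace with a centered moving average
#'
#' Default 3-point window; endpoints use shrunken windows so the output
#' has the same length as the input.
#'
#' @param trace A `mozpump_trace`.
#' @param window Odd window length (default 3).
#' @return The smoothed trace (same class and attributes).
#' @export
smooth_trace <- function(trace, window = 3L) {
  stopifnot(inherits(trace, "mozpump_trace"))
  if (window %% 2L != 1L || window < 1L) {
    stop("`window` must be a positive odd integer", call. = FALSE)
  }
  if (nrow(trace) < window) stop("trace shorter than window", call. = FALSE)
  trace$intensity_cp <- moving_average(trace$intensity_cp, window)
  trace$intensity_pp <- moving_average(trace$intensity_pp, window)
  trace
}

# internal: bouts as a two-column matrix of index ranges covering the trace
resolve_bouts <- function(trace, bouts) {
  n <- nrow(trace)
  if (is.null(bouts)) return(matrix(c(1L, n), ncol = 2))
  b <- do.call(rbind, lapply(bouts, function(r) {
    if (length(r) != 2 || r[1] < 1 || r[2] > n || r[1] >= r[2]) {
      stop("each bout must be an index range c(start, end) inside the trace",
           call. = FALSE)
    }
    as.integer(r)
  }))
  b[order(b[, 1]), , drop = FALSE]
}

#' Min-max normalize a trace per bout
#'
#' Each channel is rescaled to `[0, 1]` using the minimum and maximum
#' intensity observed within each bout. Samples outside every bout are
#' left untouched.
#'
#' @param trace A `mozpump_trace`.
#' @param bouts Optional list of index ranges `c(start, end)`; default is
#'   one bout spanning the whole trace.
#' @return The normalized trace.
#' @export
normalize_trace <- function(trace, bouts = NULL) {
  stopifnot(inherits(trace, "mozpump_trace"))
  b <- resolve_bouts(trace, bouts)
  for (col in c("intensity_cp", "intensity_pp")) {
    x <- trace[[col]]
    for (k in seq_len(nrow(b))) {
      i <- b[k, 1]:b[k, 2]
      rng <- range(x[i])
      if (rng[2] <= rng[1]) {
        stop(sprintf("flat bout in %s: cannot normalize", col),
             call. = FALSE)
      }
      x[i] <- (x[i] - rng[1]) / (rng[2] - rng[1])
    }
    trace[[col]] <- x
  }
  trace
}

# internal: alternating local extrema of x (indices + kind), plateaus
# resolved to the first sample after the monotone run
local_extrema <- function(x) {
  n <- length(x)
  empty <- list(idx = integer(0), kind = character(0))
  if (n < 3) return(empty)
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) < 2) return(empty)
  sf <- s[nz]
  chg <- which(sf[-1] != sf[-length(sf)])
  if (length(chg) == 0) return(empty)
  list(idx = nz[chg] + 1L,
       kind = ifelse(sf[chg] > 0, "max", "min"))
}

# internal: zigzag prominence pruning -- repeatedly drop the adjacent
# extremum pair with the smallest vertical span below the threshold
prune_extrema <- function(idx, kind, x, prominence) {
  while (length(idx) >= 2) {
    dv <- abs(diff(x[idx]))
    k <- which.min(dv)
    if (dv[k] >= prominence) break
    keep <- setdiff(seq_along(idx), c(k, k + 1L))
    idx <- idx[keep]
    kind <- kind[keep]
  }
  list(idx = idx, kind = kind)
}

# internal: cycle detection on a plain numeric vector; returns a data frame
# of index triples. Trace endpoints stand in for missing flanking minima.
detect_cycles_vec <- function(x, prominence) {
  ex <- local_extrema(x)
  ex <- prune_extrema(ex$idx, ex$kind, x, prominence)
  imax <- ex$idx[ex$kind == "max"]
  if (length(imax) == 0) {
    return(data.frame(start_idx = integer(0), peak_idx = integer(0),
                      end_idx = integer(0), amplitude = numeric(0)))
  }
  imin <- ex$idx[ex$kind == "min"]
  n <- length(x)
  # a maximum near the trace edge may lack a flanking pruned minimum
  # (e.g. a leading rest plateau); walk downhill from the peak instead of
  # falling back to the trace endpoint
  walk_left <- function(j) {
    while (j > 1L && x[j - 1L] < x[j]) j <- j - 1L
    j
  }
  walk_right <- function(j) {
    while (j < n && x[j + 1L] < x[j]) j <- j + 1L
    j
  }
  # a flanking minimum inside a rest plateau is positionally arbitrary
  # (ties and smoothing bleed); snap it toward the peak while the signal
  # stays within 2% of the event amplitude of the flank level, so the
  # stroke boundary sits at the plateau edge
  snap_to_edge <- function(flank, peak) {
    x0 <- x[flank]
    cap <- 0.02 * abs(x[peak] - x0)
    step <- if (peak > flank) 1L else -1L
    while (flank + step != peak &&
           abs(x[flank + step] - x0) <= cap) {
      flank <- flank + step
    }
    flank
  }
  start_idx <- vapply(imax, function(j) {
    prev <- imin[imin < j]
    snap_to_edge(if (length(prev)) max(prev) else walk_left(j), j)
  }, integer(1))
  end_idx <- vapply(imax, function(j) {
    nxt <- imin[imin > j]
    snap_to_edge(if (length(nxt)) min(nxt) else walk_right(j), j)
  }, integer(1))
  amp <- x[imax] - (x[start_idx] + x[end_idx]) / 2
  keep <- amp >= prominence / 2
  data.frame(start_idx = start_idx[keep], peak_idx = imax[keep],
             end_idx = end_idx[keep], amplitude = amp[keep])
}

#' Detect pump stroke cycles in one channel
#'
#' Extrema are found from sign changes of the first difference; an
#' alternating minimum/maximum sequence is pruned so that every retained
#' swing spans at least `prominence` (in the units of the supplied trace,
#' normally normalized units). Each surviving maximum, flanked by minima
#' (or a trace endpoint), defines one stroke: start at the preceding
#' minimum, peak at the maximum, end at the following minimum.
#'
#' @param trace A `mozpump_trace` (normally smoothed and normalized).
#' @param channel `"cp"` or `"pp"`.
#' @param prominence Minimum retained swing (default 0.1).
#' @return A data frame with columns `start_s`, `peak_s`, `end_s`,
#'   `start_idx`, `peak_idx`, `end_idx`, `amplitude`.
#' @export
detect_cycles <- function(trace, channel = c("cp", "pp"), prominence = 0.1) {
  channel <- match.arg(channel)
  stopifnot(inherits(trace, "mozpump_trace"))
  ev <- detect_cycles_vec(trace[[channel_col(channel)]], prominence)
  ev$start_s <- trace$time_s[ev$start_idx]
  ev$peak_s <- trace$time_s[ev$peak_idx]
  ev$end_s <- trace$time_s[ev$end_idx]
  ev[, c("start_s", "peak_s", "end_s",
         "start_idx", "peak_idx", "end_idx", "amplitude")]
}

#' Classify stroke events into continuous vs burst mode
#'
#' An event is labeled `"burst"` when its un-normalized amplitude exceeds
#' `ratio_threshold` times the median amplitude of the continuous events
#' in the same recording (the median over all events is used as the
#' initial reference and refined once). When fewer than three events are
#' available there is no continuous context; the absolute fallback then
#' labels an event burst when its raw amplitude exceeds
#' `absolute_threshold` (default: half the raw channel range).
#'
#' @param events Event table from [detect_cycles()].
#' @param trace The raw (or smoothed, un-normalized) `mozpump_trace`, used
#'   to measure raw amplitudes at the detected indices.
#' @param channel `"cp"` or `"pp"`.
#' @param ratio_threshold Burst-to-continuous amplitude multiple
#'   (default 3).
#' @param absolute_threshold Raw-amplitude fallback threshold; default
#'   half the channel range.
#' @return The event table with columns `raw_amplitude` and `mode` added.
#' @export
classify_mode <- function(events, trace, channel = c("cp", "pp"),
                          ratio_threshold = 3, absolute_threshold = NULL) {
  channel <- match.arg(channel)
  stopifnot(inherits(trace, "mozpump_trace"))
  if (nrow(events) == 0) {
    events$raw_amplitude <- numeric(0)
    events$mode <- character(0)
    return(events)
  }
  x <- trace[[channel_col(channel)]]
  amp <- x[events$peak_idx] -
    (x[events$start_idx] + x[events$end_idx]) / 2
  events$raw_amplitude <- amp
  if (nrow(events) >= 3) {
    ref <- stats::median(amp)
    lab <- ifelse(amp > ratio_threshold * ref, "burst", "continuous")
    if (any(lab == "continuous")) {
      ref <- stats::median(amp[lab == "continuous"])
      lab <- ifelse(amp > ratio_threshold * ref, "burst", "continuous")
    }
  } else {
    if (is.null(absolute_threshold)) {
      absolute_threshold <- diff(range(x)) / 2
    }
    lab <- ifelse(amp >= absolute_threshold, "burst", "continuous")
  }
  events$mode <- lab
  events
}

#' Per-cycle pump timing variables
#'
#' Pairs each cibarial event with the first pharyngeal event starting
#' within its cycle (before the next cibarial start); unpaired cibarial
#' events are skipped with a message. Times within a cycle are measured
#' from the cibarial stroke start; the total cycle runs from the cibarial
#' start to the pharyngeal end.
#'
#' @param cp_events,pp_events Event tables from [detect_cycles()] (one
#'   channel each), in seconds.
#' @return A data frame with one row per paired cycle; all durations in
#'   milliseconds. `frequency_hz` is the reciprocal of the interval to the
#'   next cycle start (NA for the last cycle).
#' @export
timing_cycles <- function(cp_events, pp_events) {
  if (nrow(cp_events) == 0 || nrow(pp_events) == 0) {
    stop("need at least one event in each channel", call. = FALSE)
  }
  cp <- cp_events[order(cp_events$start_s), ]
  pp <- pp_events[order(pp_events$start_s), ]
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(cp))) {
    t0 <- cp$start_s[i]
    t_next <- if (i < nrow(cp)) cp$start_s[i + 1] else Inf
    j <- which(pp$start_s >= t0 & pp$start_s < t_next)
    if (length(j) == 0) {
      skipped <- skipped + 1L
      next
    }
    j <- j[1]
    ms <- function(x) 1000 * x
    total <- ms(pp$end_s[j] - t0)
    rows[[length(rows) + 1L]] <- data.frame(
      cycle_start_s = t0,
      cp_start_ms = 0,
      pp_start_ms = ms(pp$start_s[j] - t0),
      cp_peak_ms = ms(cp$peak_s[i] - t0),
      pp_peak_ms = ms(pp$peak_s[j] - t0),
      cp_end_ms = ms(cp$end_s[i] - t0),
      pp_end_ms = ms(pp$end_s[j] - t0),
      total_cycle_ms = total,
      cp_cycle_ms = ms(cp$end_s[i] - cp$start_s[i]),
      pp_cycle_ms = ms(pp$end_s[j] - pp$start_s[j]),
      between_starts_ms = ms(pp$start_s[j] - t0),
      between_peaks_ms = ms(pp$peak_s[j] - cp$peak_s[i]),
      between_ends_ms = ms(pp$end_s[j] - cp$end_s[i]),
      time_to_next_ms = if (is.finite(t_next)) ms(t_next - pp$end_s[j])
                        else NA_real_,
      frequency_hz = if (is.finite(t_next)) 1 / (t_next - t0) else NA_real_,
      cp_pp_ratio = (cp$end_s[i] - cp$start_s[i]) /
        (pp$end_s[j] - pp$start_s[j])
    )
  }
  if (skipped > 0) {
    message(skipped, " cibarial cycle(s) skipped: no pharyngeal partner")
  }
  if (length(rows) == 0) stop("no pairable cycles", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summary timing table
#'
#' Summarizes per-cycle timing variables as mean and SD, in absolute
#' milliseconds and relative to the total cycle duration (percent).
#' With multiple specimens, per-specimen means are taken first and the
#' grand mean and SD are computed across specimens; with a single
#' specimen the summary is across cycles.
#'
#' @param cycles A per-cycle table from [timing_cycles()], or a named list
#'   of such tables (one per specimen).
#' @return A data frame with columns `variable`, `mean_ms`, `sd_ms`,
#'   `mean_rel_pct`, `sd_rel_pct` (relative columns NA for frequency and
#'   the duration ratio).
#' @export
timing_table <- function(cycles) {
  if (is.data.frame(cycles)) cycles <- list(cycles)
  vars_ms <- c("cp_start_ms", "pp_start_ms", "cp_peak_ms", "pp_peak_ms",
               "cp_end_ms", "pp_end_ms", "total_cycle_ms", "cp_cycle_ms",
               "pp_cycle_ms", "between_starts_ms", "between_peaks_ms",
               "between_ends_ms", "time_to_next_ms")
  vars_plain <- c("frequency_hz", "cp_pp_ratio")
  per_specimen <- lapply(cycles, function(cy) {
    abs_means <- vapply(vars_ms, function(v) mean(cy[[v]], na.rm = TRUE),
                        numeric(1))
    rel_means <- vapply(vars_ms, function(v) {
      mean(100 * cy[[v]] / cy$total_cycle_ms, na.rm = TRUE)
    }, numeric(1))
    plain <- vapply(vars_plain, function(v) mean(cy[[v]], na.rm = TRUE),
                    numeric(1))
    list(abs = abs_means, rel = rel_means, plain = plain)
  })
  summarize <- function(get) {
    m <- do.call(rbind, lapply(per_specimen, get))
    list(mean = colMeans(m, na.rm = TRUE),
         sd = apply(m, 2, stats::sd, na.rm = TRUE))
  }
  if (length(cycles) > 1) {
    s_abs <- summarize(function(p) p$abs)
    s_rel <- summarize(function(p) p$rel)
    s_plain <- summarize(function(p) p$plain)
  } else {
    cy <- cycles[[1]]
    s_abs <- list(
      mean = vapply(vars_ms, function(v) mean(cy[[v]], na.rm = TRUE),
                    numeric(1)),
      sd = vapply(vars_ms, function(v) stats::sd(cy[[v]], na.rm = TRUE),
                  numeric(1)))
    rel <- lapply(vars_ms, function(v) 100 * cy[[v]] / cy$total_cycle_ms)
    s_rel <- list(mean = vapply(rel, mean, numeric(1), na.rm = TRUE),
                  sd = vapply(rel, stats::sd, numeric(1), na.rm = TRUE))
    s_plain <- list(
      mean = vapply(vars_plain, function(v) mean(cy[[v]], na.rm = TRUE),
                    numeric(1)),
      sd = vapply(vars_plain, function(v) stats::sd(cy[[v]], na.rm = TRUE),
                  numeric(1)))
  }
  out <- data.frame(
    variable = c(vars_ms, vars_plain),
    mean_ms = c(s_abs$mean, s_plain$mean),
    sd_ms = c(s_abs$sd, s_plain$sd),
    mean_rel_pct = c(s_rel$mean, rep(NA_real_, length(vars_plain))),
    sd_rel_pct = c(s_rel$sd, rep(NA_real_, length(vars_plain))),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# internal: refine the extent of a large (burst) event around its peak.
# The flanking minima surviving prominence pruning can lie far from the
# event when the surrounding oscillation is much smaller than the burst,
# so the span is re-found as the contiguous region where the signal
# exceeds baseline + frac * (peak - baseline), extended outward to the
# nearest local minimum.
refine_event_span <- function(x, peak_idx, frac = 0.1) {
  n <- length(x)
  base <- stats::median(x, na.rm = TRUE)
  thr <- base + frac * (x[peak_idx] - base)
  l <- peak_idx
  while (l > 1 && !is.na(x[l - 1]) && x[l - 1] > thr) l <- l - 1L
  while (l > 1 && !is.na(x[l - 1]) && x[l - 1] <= x[l]) l <- l - 1L
  r <- peak_idx
  while (r < n && !is.na(x[r + 1]) && x[r + 1] > thr) r <- r + 1L
  while (r < n && !is.na(x[r + 1]) && x[r + 1] <= x[r]) r <- r + 1L
  c(l, r)
}

# internal: detect cycles on a vector that may contain NA spans (masked
# bursts): split into contiguous runs, detect per run, offset indices
detect_cycles_masked <- function(x, prominence) {
  ok <- !is.na(x)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  parts <- list()
  for (k in which(runs$values)) {
    seg <- x[starts[k]:ends[k]]
    if (length(seg) < 3) next
    ev <- detect_cycles_vec(seg, prominence)
    if (nrow(ev) == 0) next
    ev$start_idx <- ev$start_idx + starts[k] - 1L
    ev$peak_idx <- ev$peak_idx + starts[k] - 1L
    ev$end_idx <- ev$end_idx + starts[k] - 1L
    parts[[length(parts) + 1L]] <- ev
  }
  if (length(parts) == 0) {
    return(data.frame(start_idx = integer(0), peak_idx = integer(0),
                      end_idx = integer(0), amplitude = numeric(0)))
  }
  do.call(rbind, parts)
}

#' Full trace-analysis pipeline
#'
#' Smooths, normalizes, detects, classifies, and tabulates. Detection is
#' two-pass: a first pass on the bout-normalized trace finds all events at
#' the stated prominence; if burst events are present they dominate the
#' normalization range, so their spans are masked, the remainder is
#' re-normalized, and the continuous events are re-detected at full
#' sensitivity.
#'
#' @param trace A raw `mozpump_trace`.
#' @param prominence Detection prominence in normalized units
#'   (default 0.1).
#' @param ratio_threshold Burst classification multiple (default 3).
#' @param bouts Optional bout index ranges (see [normalize_trace()]).
#' @param window Smoothing window (default 3).
#' @return A list with per-channel classified event tables (`cp_events`,
#'   `pp_events`), the per-cycle table and summary [timing_table()] for
#'   the continuous cycles (`cycles`, `timing`), and the smoothed trace.
#' @export
analyze_trace <- function(trace, prominence = 0.1, ratio_threshold = 3,
                          bouts = NULL, window = 3L) {
  stopifnot(inherits(trace, "mozpump_trace"))
  sm <- smooth_trace(trace, window)
  norm <- normalize_trace(sm, bouts)
  events <- list()
  for (ch in c("cp", "pp")) {
    col <- channel_col(ch)
    ev1 <- detect_cycles(norm, ch, prominence)
    ev1 <- classify_mode(ev1, sm, ch, ratio_threshold)
    if (any(ev1$mode == "burst")) {
      burst <- ev1[ev1$mode == "burst", ]
      x <- sm[[col]]
      for (r in seq_len(nrow(burst))) {
        span <- refine_event_span(x, burst$peak_idx[r])
        burst$start_idx[r] <- span[1]
        burst$end_idx[r] <- span[2]
        burst$start_s[r] <- sm$time_s[span[1]]
        burst$end_s[r] <- sm$time_s[span[2]]
        x[span[1]:span[2]] <- NA
      }
      # re-normalize the unmasked remainder per bout and re-detect
      b <- resolve_bouts(sm, bouts)
      for (k in seq_len(nrow(b))) {
        i <- b[k, 1]:b[k, 2]
        if (all(is.na(x[i]))) next
        rng <- range(x[i], na.rm = TRUE)
        if (rng[2] > rng[1]) {
          x[i] <- (x[i] - rng[1]) / (rng[2] - rng[1])
        }
      }
      ev2 <- detect_cycles_masked(x, prominence)
      if (nrow(ev2) > 0) {
        ev2$start_s <- sm$time_s[ev2$start_idx]
        ev2$peak_s <- sm$time_s[ev2$peak_idx]
        ev2$end_s <- sm$time_s[ev2$end_idx]
        ev2 <- ev2[, c("start_s", "peak_s", "end_s", "start_idx",
                       "peak_idx", "end_idx", "amplitude")]
        ev2 <- classify_mode(ev2, sm, ch, ratio_threshold)
        ev2$mode <- "continuous"
      }
      burst$mode <- "burst"
      ev <- rbind(ev2, burst)
      ev <- ev[order(ev$start_s), ]
    } else {
      ev <- ev1
    }
    rownames(ev) <- NULL
    events[[ch]] <- ev
  }
  cp_cont <- events$cp[events$cp$mode == "continuous", ]
  pp_cont <- events$pp[events$pp$mode == "continuous", ]
  cycles <- NULL
  timing <- NULL
  if (nrow(cp_cont) > 0 && nrow(pp_cont) > 0) {
    cycles <- suppressMessages(timing_cycles(cp_cont, pp_cont))
    timing <- timing_table(cycles)
  }
  list(cp_events = events$cp, pp_events = events$pp,
       cycles = cycles, timing = timing, smoothed = sm)
}
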