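#' Identify transient melting events among detected steps
#'
#' During helicase unwinding, protein-mediated transient melting appears as
#' an adjacent step pair: a forward step larger than `min_step_bp` (step n)
#' followed by a backward step larger than `min_step_bp` in magnitude
#' (step n+1) within `window_points` sample periods (56 ms at 89 Hz).
#' Qualifying pairs are returned as melt events and removed from the
#' helicase step pool; ambiguous chains resolve by pairing the earliest
#' qualifying forward step.
#'
#' @param steps Time-ordered step data frame from [detect_steps()].
#' @param sampling_rate_hz Sampling rate of the detected trace, Hz.
#' @param min_step_bp Minimum step magnitude, bp (default 2, exclusive).
#' @param window_points Maximum separation in sample periods (default 5).
#' @return List with `events` (data frame: `t_melt`, `t_anneal`,
#'   `amplitude_bp`, `baseline_position`) and `steps` (the unpaired steps).
#' @export
detect_melt_events_during_unwinding <- function(steps, sampling_rate_hz,
                                                min_step_bp = 2,
                                                window_points = 5) {
  if (is.unsorted(steps$time_s)) stop("steps must be time-ordered")
  window_s <- window_points / sampling_rate_hz
  paired <- logical(nrow(steps))
  ev <- list()
  i <- 1L
  while (i < nrow(steps)) {
    if (steps$size_bp[i] > min_step_bp &&
        steps$size_bp[i + 1L] < -min_step_bp &&
        (steps$time_s[i + 1L] - steps$time_s[i]) <= window_s) {
      ev[[length(ev) + 1L]] <- data.frame(
        t_melt = steps$time_s[i], t_anneal = steps$time_s[i + 1L],
        amplitude_bp = steps$size_bp[i],
        baseline_position = steps$plateau_before[i])
      paired[c(i, i + 1L)] <- TRUE
      i <- i + 2L
    } else i <- i + 1L
  }
  list(events = if (length(ev)) do.call(rbind, ev) else .empty_melts(),
       steps = steps[!paired, , drop = FALSE])
}

.empty_melts <- function() {
  data.frame(t_melt = numeric(), t_anneal = numeric(),
             amplitude_bp = numeric(), baseline_position = numeric())
}

#' Detect transient melting events on a bare-hairpin trace
#'
#' Short-lived excursions of the closed hairpin above baseline: contiguous
#' runs of samples exceeding `crossing_frac * min_amplitude` above the
#' baseline (trace median) whose peak exceeds `min_amplitude` and whose
#' duration does not exceed `max_lifetime`.
#'
#' @param trace An `unwind_trace` of a hairpin without helicase.
#' @param min_amplitude Minimum peak excursion, bp (default 4, exclusive).
#' @param max_lifetime Maximum event duration, s (default 0.2, about 10x
#'   the characteristic ~20 ms lifetime).
#' @param crossing_frac Run-defining threshold as a fraction of
#'   `min_amplitude` (default 0.5).
#' @return Data frame `t_melt`, `t_anneal`, `amplitude_bp`,
#'   `baseline_position`.
#' @export
detect_melt_events_bare <- function(trace, min_amplitude = 4,
                                    max_lifetime = 0.2,
                                    crossing_frac = 0.5) {
  y <- trace$position
  baseline <- stats::median(y)
  above <- y > baseline + crossing_frac * min_amplitude
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  dt <- 1 / attr(trace, "sampling_rate_hz")
  ev <- lapply(keep, function(j) {
    i1 <- starts[j]; i2 <- ends[j]
    amp <- max(y[i1:i2]) - baseline
    dur <- (i2 - i1 + 1L) * dt
    if (amp > min_amplitude && dur <= max_lifetime)
      data.frame(t_melt = trace$time_s[i1] - dt / 2,
                 t_anneal = trace$time_s[i2] + dt / 2,
                 amplitude_bp = amp, baseline_position = baseline)
    else NULL
  })
  ev <- ev[!vapply(ev, is.null, logical(1))]
  if (length(ev)) do.call(rbind, ev) else .empty_melts()
}

#' Estimate the effective second-order melting on-rate
#'
#' From the mean time between successive melting events at a known protein
#' concentration: `k_on = 1 / (mean inter-event time x concentration)`.
#' The standard error follows from the exponential-rate estimator,
#' `se = k_on / sqrt(n - 1)`.
#'
#' @param events Melt-event data frame (needs `t_melt`).
#' @param concentration_M Protein concentration in molar; positive.
#' @param observation_time Total observation time, s (reported back).
#' @return List with `k_on` (1/M/s), `se`, `n_events`, `rate` (events/s),
#'   `observation_time`.
#' @export
estimate_kon <- function(events, concentration_M, observation_time = NA) {
  if (concentration_M <= 0) stop("concentration must be positive")
  n <- nrow(events)
  if (n < 2) {
    e <- simpleError(sprintf(
      "need at least 2 melting events to estimate k_on (got %d)", n))
    e$n_events <- n
    stop(e)
  }
  inter <- diff(sort(events$t_melt))
  rate <- 1 / mean(inter)
  kon <- rate / concentration_M
  list(k_on = kon, se = kon / sqrt(n - 1), n_events = n, rate = rate,
       observation_time = observation_time)
}

#' Align trace segments around melting events
#'
#' Extracts full-bandwidth segments around each event and shifts them so
#' the melting transition starts at `(t, x) = (0, 0)`: "before" segments
#' are relative to `t_melt`, "after" segments relative to `t_anneal`; both
#' use the pre-melt position as the spatial origin, so the post-anneal
#' position directly reads out any net helicase progress across the event.
#'
#' @param trace The full-bandwidth `unwind_trace`.
#' @param events Melt-event data frame.
#' @param window Half-window around the alignment times, s (default 0.25).
#' @param baseline_points Samples immediately before `t_melt` averaged for
#'   the spatial origin (default 3).
#' @return List of data frames `before` and `after`, each with columns
#'   `event`, `t`, `x`.
#' @export
align_events <- function(trace, events, window = 0.25, baseline_points = 3) {
  tt <- trace$time_s; y <- trace$position
  out_b <- list(); out_a <- list()
  for (i in seq_len(nrow(events))) {
    t_m <- events$t_melt[i]; t_a <- events$t_anneal[i]
    pre <- which(tt < t_m)
    if (length(pre) == 0) next
    base_idx <- utils::tail(pre, baseline_points)
    x0 <- mean(y[base_idx])
    sel_b <- tt >= t_m - window & tt <= t_m + window
    sel_a <- tt >= t_a - window & tt <= t_a + window
    out_b[[length(out_b) + 1L]] <-
      data.frame(event = i, t = tt[sel_b] - t_m, x = y[sel_b] - x0)
    out_a[[length(out_a) + 1L]] <-
      data.frame(event = i, t = tt[sel_a] - t_a, x = y[sel_a] - x0)
  }
  list(before = if (length(out_b)) do.call(rbind, out_b) else
         data.frame(event = integer(), t = numeric(), x = numeric()),
       after = if (length(out_a)) do.call(rbind, out_a) else
         data.frame(event = integer(), t = numeric(), x = numeric()))
}

#' Control alignment at random time points
#'
#' Repeats the alignment of [align_events()] at `n` random time points,
#' pairing each with the point `delay` seconds later (the width of the
#' melt-event search window). The resulting densities show the net
#' helicase progress expected in that much time, independent of melting.
#'
#' @param trace The full-bandwidth `unwind_trace`.
#' @param n Number of random control points.
#' @param delay Pairing delay, s (default 0.06).
#' @inheritParams align_events
#' @return As [align_events()].
#' @export
align_random_control <- function(trace, n, delay = 0.06, window = 0.25,
                                 baseline_points = 3) {
  t_lo <- min(trace$time_s) + window
  t_hi <- max(trace$time_s) - window - delay
  if (t_hi <= t_lo) stop("trace too short for the requested window")
  t0 <- stats::runif(n, t_lo, t_hi)
  events <- data.frame(t_melt = t0, t_anneal = t0 + delay,
                       amplitude_bp = NA_real_, baseline_position = NA_real_)
  align_events(trace, events, window = window,
               baseline_points = baseline_points)
}

#' Two-dimensional kernel density surface of aligned event points
#'
#' Gaussian-kernel density estimate of an aligned `(t, x)` point cloud on a
#' regular grid; every point is replaced by a 2D Gaussian kernel and the
#' kernels are summed and normalized, so the surface integrates to 1 over
#' the grid. Bandwidths default to Silverman's rule per axis.
#'
#' @param t,x Coordinates of the aligned points.
#' @param bandwidth Length-2 kernel standard deviations `(s, bp)`;
#'   default `stats::bw.nrd0` per axis.
#' @param n Grid points per axis (default 65).
#' @param lims Grid limits `c(t_lo, t_hi, x_lo, x_hi)`; default data range
#'   extended by 3 bandwidths.
#' @return List with `x` (time axis), `y` (position axis), `z` (density
#'   matrix), `bandwidth`.
#' @export
event_density <- function(t, x, bandwidth = NULL, n = 65, lims = NULL) {
  stopifnot(length(t) == length(x), length(t) >= 1)
  if (is.null(bandwidth)) {
    bw1 <- if (length(t) > 1 && stats::sd(t) > 0) stats::bw.nrd0(t) else
      max(diff(range(t)) / 10, 1e-3)
    bw2 <- if (length(x) > 1 && stats::sd(x) > 0) stats::bw.nrd0(x) else
      max(diff(range(x)) / 10, 1e-3)
    bandwidth <- c(bw1, bw2)
  }
  if (is.null(lims))
    lims <- c(range(t) + c(-5, 5) * bandwidth[1],
              range(x) + c(-5, 5) * bandwidth[2])
  # MASS::kde2d uses a normal kernel with sd = h / 4
  d <- MASS::kde2d(t, x, h = 4 * bandwidth, n = n, lims = lims)
  list(x = d$x, y = d$y, z = d$z, bandwidth = bandwidth)
}
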