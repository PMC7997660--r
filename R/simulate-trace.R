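#' Stepping-layer parameters for the trace simulator
#'
#' Phenomenological parameters for rendering base-pair-resolved unwinding
#' paths: 1 bp forward steps at a position-dependent rate with a slowdown in
#' the GC-rich stall region, occasional backsteps and backslides, transient
#' 5 nt release/recapture pairs, and repeated bursts per molecule.
#'
#' Probabilities are per stepping event. Mid-burst backslides are followed
#' by re-unwinding of the rezipped duplex; the rapid rezip that terminates
#' each burst is logged as a single terminal backslide.
#'
#' @param step_bp Elementary step size, bp.
#' @param forward_rate Net unwinding velocity target outside the stall
#'   region, bp/s.
#' @param stall_region Two-element vector, bp: interval where unwinding slows.
#' @param stall_rate_low,stall_rate_high Net velocity inside the stall region
#'   in the low- and high-processivity state, bp/s.
#' @param backstep_prob Probability a stepping event is a backstep
#'   (size in `[-2, 0)` bp).
#' @param backslide_prob Probability a stepping event is a mid-burst
#'   backslide (size `< -2` bp).
#' @param backslide_bp Magnitude of a mid-burst backslide, bp.
#' @param release_recapture_prob Probability of a transient 5 nt
#'   release/recapture pair per stepping event.
#' @param release_recapture_bp Size of the release/recapture excursion, bp.
#' @param bursts_per_molecule_mean,bursts_per_molecule_sd Number of bursts a
#'   molecule makes before dissociating (Gaussian, rounded, min 1).
#' @param rezip_rate Hairpin rezipping speed at burst end, bp/s.
#' @param interburst_mean_s Mean dwell at the hairpin base between bursts, s.
#' @return An object of class `stepping_params`.
#' @export
stepping_params <- function(step_bp = 1, forward_rate = 5,
                            stall_region = c(10, 15),
                            stall_rate_low = 1.2, stall_rate_high = 3.5,
                            backstep_prob = 0.19, backslide_prob = 0.05,
                            backslide_bp = 3,
                            release_recapture_prob = 0.01,
                            release_recapture_bp = 5,
                            bursts_per_molecule_mean = 5,
                            bursts_per_molecule_sd = 1,
                            rezip_rate = 60, interburst_mean_s = 1) {
  if (backstep_prob < 0 || backslide_prob < 0 || release_recapture_prob < 0 ||
      backstep_prob + backslide_prob + release_recapture_prob >= 1)
    stop("step-type probabilities must be non-negative and sum to < 1")
  if (step_bp <= 0) stop("step_bp must be positive")
  structure(
    list(step_bp = step_bp, forward_rate = forward_rate,
         stall_region = stall_region, stall_rate_low = stall_rate_low,
         stall_rate_high = stall_rate_high, backstep_prob = backstep_prob,
         backslide_prob = backslide_prob, backslide_bp = backslide_bp,
         release_recapture_prob = release_recapture_prob,
         release_recapture_bp = release_recapture_bp,
         bursts_per_molecule_mean = bursts_per_molecule_mean,
         bursts_per_molecule_sd = bursts_per_molecule_sd,
         rezip_rate = rezip_rate, interburst_mean_s = interburst_mean_s),
    class = "stepping_params")
}

#' Transient-melting parameters for the trace simulator
#'
#' ssDNA-binding-protein-mediated melting events are rendered as rectangular
#' openings of `amplitude_bp` base pairs arriving as a Poisson process of
#' rate `k_on * concentration` and lasting an exponential lifetime.
#'
#' @param k_on Effective second-order binding rate constant, 1/M/s
#'   (default 1.2e8).
#' @param conc_nM Protein concentration, nM.
#' @param amplitude_bp Opening amplitude, bp (default 5).
#' @param lifetime_s Mean event lifetime, s (default 0.020).
#' @return An object of class `melting_params`.
#' @export
melting_params <- function(k_on = 1.2e8, conc_nM = 0, amplitude_bp = 5,
                           lifetime_s = 0.020) {
  if (k_on < 0 || conc_nM < 0) stop("k_on and conc_nM must be non-negative")
  if (amplitude_bp <= 0 || lifetime_s <= 0)
    stop("amplitude_bp and lifetime_s must be positive")
  structure(list(k_on = k_on, conc_nM = conc_nM, amplitude_bp = amplitude_bp,
                 lifetime_s = lifetime_s,
                 event_rate = k_on * conc_nM * 1e-9),
            class = "melting_params")
}

#' Construct an unwinding trace object
#'
#' A trace is a data frame (`time_s`, `position`) on a uniform time grid
#' with acquisition metadata stored in attributes. Positions are in bp
#' unwound (`units = "bp"`) or tether-extension change in nm
#' (`units = "nm"`).
#'
#' @param time_s Uniform, strictly increasing time grid, s.
#' @param position Position samples (bp or nm).
#' @param force_pN Constant applied force, pN.
#' @param rpa2_nM ssDNA-binding-protein concentration, nM.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param units `"bp"` or `"nm"`.
#' @param molecule_id Identifier string.
#' @param seed Seed used to generate the trace (NA for measured data).
#' @param injection_log Optional list of ground-truth events (simulator only).
#' @return An object of class `unwind_trace` (a data frame).
#' @export
unwind_trace <- function(time_s, position, force_pN = NA_real_,
                         rpa2_nM = NA_real_, sampling_rate_hz = NA_real_,
                         units = "bp", molecule_id = "trace1",
                         seed = NA_integer_, injection_log = NULL) {
  stopifnot(length(time_s) == length(position))
  if (length(time_s) > 1) {
    dt <- diff(time_s)
    if (any(dt <= 0)) stop("time must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
      stop("time grid must be uniform")
    if (is.na(sampling_rate_hz)) sampling_rate_hz <- 1 / stats::median(dt)
  }
  units <- match.arg(units, c("bp", "nm"))
  structure(data.frame(time_s = time_s, position = position),
            class = c("unwind_trace", "data.frame"),
            force_pN = force_pN, rpa2_nM = rpa2_nM,
            sampling_rate_hz = sampling_rate_hz, units = units,
            molecule_id = molecule_id, seed = seed,
            injection_log = injection_log)
}

#' @export
print.unwind_trace <- function(x, ...) {
  cat(sprintf(
    "unwind_trace '%s': %d samples @ %.3g Hz, %.4g s, units %s, F = %g pN, [RPA2] = %g nM\n",
    attr(x, "molecule_id"), nrow(x), attr(x, "sampling_rate_hz"),
    if (nrow(x)) max(x$time_s) else 0, attr(x, "units"),
    attr(x, "force_pN"), attr(x, "rpa2_nM")))
  invisible(x)
}

#' @export
plot.unwind_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$position, type = "l", xlab = "time (s)",
                 ylab = paste0("position (", attr(x, "units"), ")"), ...)
}

#' Ground-truth injection log of a simulated trace
#'
#' @param trace An `unwind_trace` produced by the simulator.
#' @return List with data frames `steps` (`time_s`, `size_bp`, `type`),
#'   `melts` (`t_melt`, `t_anneal`, `amplitude_bp`), `bursts` (`t_start`,
#'   `t_end`, `apex_bp`, `category`), and `dissociation_time`.
#' @export
injection_log <- function(trace) attr(trace, "injection_log")

# render a piecewise-constant path (jump times/levels) at sample instants
.render_path <- function(t_samples, jump_times, levels) {
  idx <- findInterval(t_samples, jump_times)
  idx[idx < 1L] <- 1L
  levels[idx]
}

# melting contribution at sample instants: amplitude * number of open events
.render_melts <- function(t_samples, melts, amplitude) {
  if (is.null(melts) || nrow(melts) == 0) return(numeric(length(t_samples)))
  edges <- sort(c(melts$t_melt, melts$t_anneal))
  opens <- findInterval(t_samples, sort(melts$t_melt))
  closes <- findInterval(t_samples, sort(melts$t_anneal))
  amplitude * (opens - closes)
}

# draw Poisson melting events over [0, duration]
.draw_melts <- function(melting, duration) {
  rate <- melting$event_rate
  n <- if (rate > 0) stats::rpois(1, rate * duration) else 0L
  if (n == 0)
    return(data.frame(t_melt = numeric(), t_anneal = numeric(),
                      amplitude_bp = numeric()))
  t0 <- sort(stats::runif(n, 0, duration))
  len <- stats::rexp(n, 1 / melting$lifetime_s)
  data.frame(t_melt = t0, t_anneal = pmin(t0 + len, duration),
             amplitude_bp = melting$amplitude_bp)
}

#' Simulate a constant-force unwinding trace
#'
#' Two-layer generative model. A Gillespie state path of the kinetic scheme
#' (low / high / dissociated / crossed) sets the burst category over time;
#' a stepping layer renders each burst as 1 bp steps with a position-
#' dependent rate: low-state bursts stall in `stall_region` and terminate
#' there, high-state bursts traverse it and reach beyond the scoring
#' threshold. Transient melting excursions (rectangular, exponential
#' lifetime, Poisson arrivals at `k_on * c`) and iid Gaussian measurement
#' noise are superimposed. Samples are instantaneous point evaluations of
#' the underlying path.
#'
#' @param rates [kinetic_rates()] for the state layer.
#' @param stepping [stepping_params()].
#' @param melting [melting_params()].
#' @param force_pN Constant force, pN (metadata).
#' @param duration Trace duration, s.
#' @param noise_sd Gaussian noise s.d., bp.
#' @param sampling_rate_hz Sampling rate, Hz (89, 100 or 267 typical).
#' @param seed Integer seed.
#' @param stem_bp Hairpin stem length, bp (cap on position).
#' @param forced_bursts Optional data frame (`apex_bp`, `category`) to force
#'   the burst sequence (used in tests); overrides the state layer.
#' @return An `unwind_trace` in bp with a ground-truth [injection_log()].
#' @export
simulate_trace <- function(rates, stepping = stepping_params(),
                           melting = melting_params(),
                           force_pN = 12, duration = 120, noise_sd = 0.3,
                           sampling_rate_hz = 89, seed = NULL,
                           stem_bp = 89, forced_bursts = NULL) {
  stopifnot(inherits(stepping, "stepping_params"),
            inherits(melting, "melting_params"))
  if (duration <= 0) stop("duration must be positive")
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)

  # state layer: when is the molecule in the high state, and when off
  if (is.null(forced_bursts)) {
    path <- simulate_state_path(rates, duration)
    state_at <- function(t) {
      path$state[findInterval(t, path$entry_time)]
    }
    off_time <- if (path$state[nrow(path)] == "off")
      path$entry_time[nrow(path)] else Inf
    n_bursts <- max(1L, as.integer(round(stats::rnorm(
      1, stepping$bursts_per_molecule_mean, stepping$bursts_per_molecule_sd))))
  } else {
    state_at <- NULL
    off_time <- Inf
    n_bursts <- nrow(forced_bursts)
  }

  jt <- 0; lv <- 0        # jump times and levels of the true path
  step_log <- list(); burst_log <- list()
  t <- 0; pos <- 0
  add_jump <- function(t, new_pos) {
    jt[length(jt) + 1L] <<- t
    lv[length(lv) + 1L] <<- new_pos
    pos <<- new_pos
  }
  dissociation_time <- NA_real_

  for (b in seq_len(n_bursts)) {
    t <- t + stats::rexp(1, 1 / stepping$interburst_mean_s)
    if (t >= min(duration, off_time)) break
    if (is.null(forced_bursts)) {
      st <- state_at(t)
      if (st == "off") break
      category <- if (st %in% c("high", "crossed")) "high" else "low"
      apex <- if (category == "high")
        stats::runif(1, 26, stem_bp)
      else stats::runif(1, stepping$stall_region[1], stepping$stall_region[2])
    } else {
      category <- forced_bursts$category[b]
      apex <- forced_bursts$apex_bp[b]
    }
    t_start <- t
    # forward stepping with backsteps / backslides / release-recapture
    p_fwd <- 1 - stepping$backstep_prob - stepping$backslide_prob -
      stepping$release_recapture_prob
    drift <- p_fwd * stepping$step_bp - stepping$backstep_prob * 1 -
      stepping$backslide_prob * 0  # mid-burst backslides are re-unwound
    while (pos < apex && t < min(duration, off_time)) {
      in_stall <- pos >= stepping$stall_region[1] &&
        pos <= stepping$stall_region[2]
      v <- if (!in_stall) stepping$forward_rate
      else if (category == "high") stepping$stall_rate_high
      else stepping$stall_rate_low
      event_rate <- v / max(drift, 0.05)
      t <- t + stats::rexp(1, event_rate)
      if (t >= min(duration, off_time)) break
      u <- stats::runif(1)
      if (u < stepping$backstep_prob && pos >= 1) {
        add_jump(t, pos - 1)
        step_log[[length(step_log) + 1L]] <-
          data.frame(time_s = t, size_bp = -1, type = "backstep")
      } else if (u < stepping$backstep_prob + stepping$backslide_prob &&
                 pos > stepping$backslide_bp) {
        add_jump(t, pos - stepping$backslide_bp)
        step_log[[length(step_log) + 1L]] <-
          data.frame(time_s = t, size_bp = -stepping$backslide_bp,
                     type = "backslide")
        # re-unwind the rezipped duplex at the forward rate
        for (r in seq_len(stepping$backslide_bp)) {
          t <- t + stats::rexp(1, event_rate)
          if (t >= min(duration, off_time)) break
          add_jump(t, pos + 1)
          step_log[[length(step_log) + 1L]] <-
            data.frame(time_s = t, size_bp = 1, type = "forward")
        }
      } else if (u < stepping$backstep_prob + stepping$backslide_prob +
                 stepping$release_recapture_prob &&
                 pos >= stepping$release_recapture_bp) {
        dwell <- stats::rexp(1, 1 / 0.02)
        add_jump(t, pos - stepping$release_recapture_bp)
        step_log[[length(step_log) + 1L]] <-
          data.frame(time_s = t, size_bp = -stepping$release_recapture_bp,
                     type = "release")
        t2 <- t + dwell
        add_jump(t2, pos + stepping$release_recapture_bp)
        step_log[[length(step_log) + 1L]] <-
          data.frame(time_s = t2, size_bp = stepping$release_recapture_bp,
                     type = "recapture")
        t <- t2
      } else {
        add_jump(t, min(pos + stepping$step_bp, stem_bp))
        step_log[[length(step_log) + 1L]] <-
          data.frame(time_s = t, size_bp = stepping$step_bp, type = "forward")
      }
    }
    # terminal rezip to the hairpin base, logged as one backslide
    apex_reached <- pos
    if (apex_reached > 0 && t < duration) {
      step_log[[length(step_log) + 1L]] <-
        data.frame(time_s = t, size_bp = -apex_reached, type = "backslide")
      while (pos > 0 && t < duration) {
        t <- t + 1 / stepping$rezip_rate
        add_jump(t, pos - 1)
      }
    }
    burst_log[[length(burst_log) + 1L]] <-
      data.frame(t_start = t_start, t_end = min(t, duration),
                 apex_bp = apex_reached, category = category)
    if (t >= off_time) { dissociation_time <- off_time; break }
    if (t >= duration) break
  }
  if (is.infinite(off_time)) off_time <- NA_real_

  melts <- .draw_melts(melting, duration)
  n_samp <- floor(duration * sampling_rate_hz) + 1L
  t_samples <- (seq_len(n_samp) - 1L) / sampling_rate_hz
  position <- .render_path(t_samples, jt, lv) +
    .render_melts(t_samples, melts, melting$amplitude_bp) +
    stats::rnorm(n_samp, 0, noise_sd)

  log <- list(
    steps = if (length(step_log)) do.call(rbind, step_log) else
      data.frame(time_s = numeric(), size_bp = numeric(), type = character()),
    melts = melts,
    bursts = if (length(burst_log)) do.call(rbind, burst_log) else
      data.frame(t_start = numeric(), t_end = numeric(),
                 apex_bp = numeric(), category = character()),
    dissociation_time = dissociation_time)
  unwind_trace(t_samples, position, force_pN = force_pN,
               rpa2_nM = melting$conc_nM, sampling_rate_hz = sampling_rate_hz,
               units = "bp", seed = if (is.null(seed)) NA_integer_ else seed,
               injection_log = log)
}

#' Simulate a bare-hairpin trace (no helicase)
#'
#' Baseline-zero trace with only transient melting excursions and Gaussian
#' noise; the protein melts the closed hairpin and it reanneals.
#'
#' @inheritParams simulate_trace
#' @return An `unwind_trace` with a ground-truth [injection_log()]
#'   (`steps` and `bursts` empty).
#' @export
simulate_bare_hairpin <- function(melting = melting_params(conc_nM = 10),
                                  duration = 120, noise_sd = 0.3,
                                  sampling_rate_hz = 267, seed = NULL,
                                  force_pN = 12) {
  stopifnot(inherits(melting, "melting_params"))
  if (duration <= 0) stop("duration must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  melts <- .draw_melts(melting, duration)
  n_samp <- floor(duration * sampling_rate_hz) + 1L
  t_samples <- (seq_len(n_samp) - 1L) / sampling_rate_hz
  position <- .render_melts(t_samples, melts, melting$amplitude_bp) +
    stats::rnorm(n_samp, 0, noise_sd)
  log <- list(
    steps = data.frame(time_s = numeric(), size_bp = numeric(),
                       type = character()),
    melts = melts,
    bursts = data.frame(t_start = numeric(), t_end = numeric(),
                        apex_bp = numeric(), category = character()),
    dissociation_time = NA_real_)
  unwind_trace(t_samples, position, force_pN = force_pN,
               rpa2_nM = melting$conc_nM, sampling_rate_hz = sampling_rate_hz,
               units = "bp", seed = if (is.null(seed)) NA_integer_ else seed,
               injection_log = log)
}
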