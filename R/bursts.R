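#' Robust local-regression smoothing of a trace
#'
#' Weighted local quadratic regression over a fixed window (51 points,
#' 190 ms at 267 Hz, by default) with tricube distance weights and
#' bisquare robust reweighting, which suppresses short outliers such as
#' transient melting spikes while reproducing smooth trends exactly up to
#' second order. Implemented with `stats::loess(degree = 2,
#' family = "symmetric")` on the trace grid.
#'
#' @param trace An `unwind_trace`.
#' @param window_points Smoothing window length in samples (default 51).
#' @return The trace with smoothed positions (metadata preserved).
#' @export
smooth_robust <- function(trace, window_points = 51) {
  n <- nrow(trace)
  if (n < 5) return(trace)
  span <- min(1, window_points / n)
  # noiseless or locally degenerate windows trigger benign rank warnings
  fit <- withCallingHandlers(
    stats::loess(position ~ time_s, data = trace, degree = 2,
                 family = "symmetric", span = span,
                 control = stats::loess.control(surface = "direct")),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("pseudoinverse|neighborhood|condition number|singularities|span bigger",
                msg) || grepl("^(at|radius) +[0-9.e+-]+$", trimws(msg)))
        invokeRestart("muffleWarning")
    })
  out <- trace
  out$position <- stats::fitted(fit)
  out
}

#' Mask melting-event spans in a trace
#'
#' Replaces samples inside each melt event's `[t_melt, t_anneal]` span by
#' linear interpolation between the flanking samples, so protein-mediated
#' melting does not contribute to burst segmentation or processivity.
#'
#' @param trace An `unwind_trace`.
#' @param events Melt-event data frame (`t_melt`, `t_anneal`); NULL or
#'   empty for no masking.
#' @return The masked trace.
#' @export
mask_melt_events <- function(trace, events) {
  if (is.null(events) || nrow(events) == 0) return(trace)
  y <- trace$position
  tt <- trace$time_s
  inside <- rep(FALSE, length(y))
  for (i in seq_len(nrow(events)))
    inside <- inside | (tt >= events$t_melt[i] & tt <= events$t_anneal[i])
  if (any(inside) && !all(inside)) {
    y[inside] <- stats::approx(tt[!inside], y[!inside], xout = tt[inside],
                               rule = 2)$y
    trace$position <- y
  }
  trace
}

#' Segment a trace into unwinding bursts
#'
#' A burst is a period of significant forward progress (an excursion of
#' more than `min_excursion` bp above the preceding valley) followed by
#' significant backward motion (more than `min_excursion` bp below the
#' burst maximum). Segmentation runs on the melt-masked, robustly smoothed
#' trace; intermediate dips smaller than `min_excursion` do not split a
#' burst. Trailing activity whose closing retraction is missing is flagged
#' `complete = FALSE` and should be excluded from duration statistics.
#'
#' @param trace An `unwind_trace` in bp.
#' @param melt_events Pre-detected melt events to mask (optional).
#' @param min_excursion Excursion hysteresis, bp (default 5).
#' @param smooth_window Smoothing window passed to [smooth_robust()];
#'   0 disables smoothing.
#' @param threshold_bp Processivity threshold separating the `low` and
#'   `high` categories, bp (default 25).
#' @param baseline_tol Tolerance for the return to the pre-burst baseline
#'   that closes a burst, bp (default 2).
#' @return Data frame with columns `t_start`, `t_end`, `processivity_bp`,
#'   `duration_s`, `category` (`low`/`high`), `complete`.
#' @export
segment_bursts <- function(trace, melt_events = NULL, min_excursion = 5,
                           smooth_window = 51, threshold_bp = 25,
                           baseline_tol = 2) {
  work <- mask_melt_events(trace, melt_events)
  if (smooth_window > 0) work <- smooth_robust(work, smooth_window)
  y <- work$position
  tt <- work$time_s
  n <- length(y)
  out <- list()
  valley <- y[1]; valley_i <- 1L
  peak <- -Inf; peak_i <- NA_integer_
  start_i <- NA_integer_
  in_burst <- FALSE; down_met <- FALSE
  for (i in seq_len(n)) {
    if (!in_burst) {
      if (y[i] < valley) { valley <- y[i]; valley_i <- i }
      if (y[i] - valley >= min_excursion) {
        in_burst <- TRUE; down_met <- FALSE
        start_i <- valley_i
        peak <- y[i]; peak_i <- i
        valley <- y[i]; valley_i <- i
      }
    } else {
      if (y[i] > peak) { peak <- y[i]; peak_i <- i }
      if (!down_met && peak - y[i] >= min_excursion) down_met <- TRUE
      if (down_met) {
        if (y[i] <= y[start_i] + baseline_tol) {
          # returned to the pre-burst baseline: close here
          out[[length(out) + 1L]] <- data.frame(
            t_start = tt[start_i], t_end = tt[i],
            processivity_bp = peak, complete = TRUE)
          in_burst <- FALSE; down_met <- FALSE
          valley <- y[i]; valley_i <- i
          peak <- -Inf
          next
        }
        if (y[i] < valley) { valley <- y[i]; valley_i <- i }
        if (y[i] - valley >= min_excursion) {
          # next burst is starting: close the current one at the valley
          out[[length(out) + 1L]] <- data.frame(
            t_start = tt[start_i], t_end = tt[valley_i],
            processivity_bp = peak, complete = TRUE)
          in_burst <- TRUE; down_met <- FALSE
          start_i <- valley_i
          peak <- y[i]; peak_i <- i
          valley <- y[i]; valley_i <- i
        }
      } else {
        valley <- y[i]; valley_i <- i
      }
    }
  }
  if (in_burst)
    out[[length(out) + 1L]] <- data.frame(
      t_start = tt[start_i], t_end = if (down_met) tt[valley_i] else tt[n],
      processivity_bp = peak, complete = down_met)
  if (length(out) == 0)
    return(data.frame(t_start = numeric(), t_end = numeric(),
                      processivity_bp = numeric(), duration_s = numeric(),
                      category = character(), complete = logical()))
  res <- do.call(rbind, out)
  res$duration_s <- res$t_end - res$t_start
  res$category <- ifelse(res$processivity_bp > threshold_bp, "high", "low")
  res[, c("t_start", "t_end", "processivity_bp", "duration_s", "category",
          "complete")]
}

#' Processivity of one burst
#'
#' Maximum position on the melt-masked, smoothed trace between the burst
#' start and end times.
#'
#' @param burst A one-row burst record (list or data frame row with
#'   `t_start`, `t_end`).
#' @param trace The `unwind_trace` the burst came from.
#' @param melt_events Optional melt events to mask first.
#' @param smooth_window Smoothing window; 0 disables smoothing.
#' @return Processivity in bp.
#' @export
burst_processivity <- function(burst, trace, melt_events = NULL,
                               smooth_window = 51) {
  work <- mask_melt_events(trace, melt_events)
  if (smooth_window > 0) work <- smooth_robust(work, smooth_window)
  sel <- work$time_s >= burst$t_start & work$time_s <= burst$t_end
  if (!any(sel)) stop("burst window contains no samples")
  max(work$position[sel])
}

#' Select the unwinding portion of a burst
#'
#' Returns the time window of active unwinding, excluding the rapid
#' rezipping at burst end, by burst class: high-processivity bursts run
#' from burst start to the position maximum; low-processivity bursts with
#' stalls end at the last point above `stall_floor` (10 bp); bursts that
#' never reach `stall_floor` keep the first `frac` (75%) of their duration.
#'
#' @param burst One-row burst record (`t_start`, `t_end`,
#'   `processivity_bp`).
#' @param trace The `unwind_trace` (smoothed positions recommended).
#' @param threshold_bp High-processivity threshold, bp (default 25).
#' @param stall_floor Stall floor for low-processivity bursts, bp
#'   (default 10).
#' @param frac Duration fraction kept for sub-`stall_floor` bursts
#'   (default 0.75).
#' @return Named numeric `c(t_start_u, t_end_u)`, within the burst bounds.
#' @export
select_unwinding_portion <- function(burst, trace, threshold_bp = 25,
                                     stall_floor = 10, frac = 0.75) {
  sel <- which(trace$time_s >= burst$t_start & trace$time_s <= burst$t_end)
  if (length(sel) == 0) stop("burst window contains no samples")
  y <- trace$position[sel]; tt <- trace$time_s[sel]
  if (burst$processivity_bp > threshold_bp) {
    t_end_u <- tt[which.max(y)]
  } else if (burst$processivity_bp >= stall_floor) {
    above <- which(y > stall_floor)
    t_end_u <- if (length(above)) tt[max(above)] else tt[which.max(y)]
  } else {
    t_end_u <- burst$t_start + frac * (burst$t_end - burst$t_start)
  }
  c(t_start_u = burst$t_start, t_end_u = t_end_u)
}

#' Local unwinding velocity vs. hairpin position
#'
#' Within each burst's unwinding portion, the local velocity is the
#' least-squares slope over half-overlapping windows of `window_points`
#' samples; each window also reports its mean time and mean position.
#' Windows from all bursts are aggregated into position bins with the
#' across-window s.e.m.
#'
#' @param bursts Burst data frame from [segment_bursts()].
#' @param trace The `unwind_trace` (smoothed positions recommended).
#' @param window_points Window length in samples (default 50).
#' @param bin_bp Position bin width for aggregation, bp (default 2).
#' @param ... Passed to [select_unwinding_portion()].
#' @return Data frame `position_bp` (bin center), `velocity_bp_s`, `sem`,
#'   `n_windows`; attribute `windows` holds the per-window table.
#' @export
velocity_profile <- function(bursts, trace, window_points = 50, bin_bp = 2,
                             ...) {
  wins <- list()
  for (b in seq_len(nrow(bursts))) {
    w <- select_unwinding_portion(bursts[b, ], trace, ...)
    sel <- which(trace$time_s >= w[1] & trace$time_s <= w[2])
    if (length(sel) < window_points) next
    starts <- seq(1L, length(sel) - window_points + 1L,
                  by = max(1L, window_points %/% 2L))
    for (s in starts) {
      idx <- sel[s:(s + window_points - 1L)]
      tt <- trace$time_s[idx]; y <- trace$position[idx]
      slope <- stats::cov(tt, y) / stats::var(tt)
      wins[[length(wins) + 1L]] <- data.frame(
        burst = b, time_s = mean(tt), position_bp = mean(y),
        velocity_bp_s = slope)
    }
  }
  if (length(wins) == 0) {
    out <- data.frame(position_bp = numeric(), velocity_bp_s = numeric(),
                      sem = numeric(), n_windows = integer())
    attr(out, "windows") <- data.frame()
    return(out)
  }
  wdf <- do.call(rbind, wins)
  bin <- bin_bp * (floor(wdf$position_bp / bin_bp) + 0.5)
  agg <- do.call(rbind, lapply(split(wdf, bin), function(d) data.frame(
    position_bp = bin_bp * (floor(d$position_bp[1] / bin_bp) + 0.5),
    velocity_bp_s = mean(d$velocity_bp_s),
    sem = stats::sd(d$velocity_bp_s) / sqrt(nrow(d)),
    n_windows = nrow(d))))
  agg <- agg[order(agg$position_bp), ]
  rownames(agg) <- NULL
  attr(agg, "windows") <- wdf
  agg
}

#' Summarize bursts per experimental condition
#'
#' Bookkeeping table per condition: molecule and burst counts, bursts per
#' molecule, low/high split against the processivity threshold, fraction
#' high with binomial standard error, and mean processivity and duration
#' with s.e.m. (durations over complete bursts only). The identities
#' `n_low + n_high = n_bursts` and `fraction_high = n_high / n_bursts`
#' hold on any input.
#'
#' @param bursts Burst data frame with columns `processivity_bp`,
#'   `duration_s`, `category`, `complete`, plus a condition column and
#'   optionally `molecule_id`.
#' @param condition Name of the condition column (default `"rpa2_nM"`).
#' @return Data frame, one row per condition.
#' @export
summarize_bursts <- function(bursts, condition = "rpa2_nM") {
  if (!condition %in% names(bursts))
    stop("no condition column '", condition, "' in bursts")
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  sp <- split(bursts, bursts[[condition]])
  do.call(rbind, lapply(names(sp), function(cond_label) {
    d <- sp[[cond_label]]
    nb <- nrow(d)
    nh <- sum(d$category == "high")
    nm <- if ("molecule_id" %in% names(d))
      length(unique(d$molecule_id)) else NA_integer_
    fh <- if (nb > 0) nh / nb else NA_real_
    cd <- if ("complete" %in% names(d)) d[d$complete, , drop = FALSE] else d
    data.frame(
      condition = cond_label,
      n_molecules = nm, n_bursts = nb,
      bursts_per_molecule = if (!is.na(nm) && nm > 0) nb / nm else NA_real_,
      n_low = nb - nh, n_high = nh, fraction_high = fh,
      fraction_high_se = if (nb > 0 && !is.na(fh))
        sqrt(fh * (1 - fh) / nb) else NA_real_,
      mean_processivity = if (nb) mean(d$processivity_bp) else 0,
      processivity_sem = sem(d$processivity_bp),
      mean_duration = if (nrow(cd)) mean(cd$duration_s) else NA_real_,
      duration_sem = sem(cd$duration_s),
      row.names = NULL)
  }))
}
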