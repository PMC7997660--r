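# shared fixtures: reference rate sets and small synthetic traces

`%||%` <- function(a, b) if (is.null(a)) b else a

ref_rates_list <- function() {
  ref <- xpd_reference_rates()
  stats::setNames(lapply(ref$k1$conc_nM, xpd_reference_rates_at),
                  ref$k1$conc_nM)
}

# noiseless staircase trace: `levels` repeated `plateau` samples each
staircase_trace <- function(levels, plateau, rate_hz = 89, noise_sd = 0,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- rep(levels, each = plateau)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  unwind_trace((seq_along(y) - 1) / rate_hz, y, force_pN = 12,
               sampling_rate_hz = rate_hz)
}

# triangle burst: ramp up to `apex` and back down, `dwell` samples at base
triangle_trace <- function(apex = 20, rate_bp_s = 4, rate_hz = 89,
                           dwell_s = 3) {
  up <- seq(0, apex, by = rate_bp_s / rate_hz)
  dn <- rev(up)[-1]
  base <- rep(0, round(dwell_s * rate_hz))
  y <- c(base, up, dn, base)
  unwind_trace((seq_along(y) - 1) / rate_hz, y, force_pN = 12,
               sampling_rate_hz = rate_hz)
}

# steps df builder for melt-pairing tests
make_steps <- function(times, sizes) {
  data.frame(time_s = times, size_bp = sizes,
             plateau_before = c(0, cumsum(sizes))[seq_along(sizes)],
             plateau_after = cumsum(sizes), fit_quality = 2)
}
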