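test_that("step pairing implements the melt-event criterion", {
  # +5 then -5 within 30 ms at 89 Hz: one event
  st <- make_steps(c(1.000, 1.030), c(5, -5))
  res <- detect_melt_events_during_unwinding(st, 89)
  expect_equal(nrow(res$events), 1)
  expect_equal(res$events$amplitude_bp, 5)
  expect_equal(res$events$t_melt, 1.000)
  expect_equal(res$events$t_anneal, 1.030)
  expect_equal(nrow(res$steps), 0)  # paired steps leave the pool

  # separation beyond the 5-sample window: no event
  st2 <- make_steps(c(1.0, 1.2), c(5, -5))
  expect_equal(nrow(detect_melt_events_during_unwinding(st2, 89)$events), 0)

  # amplitude at or below 2 bp: no event
  st3 <- make_steps(c(1.000, 1.030), c(1, -1))
  expect_equal(nrow(detect_melt_events_during_unwinding(st3, 89)$events), 0)
  st4 <- make_steps(c(1.000, 1.030), c(2, -2))
  expect_equal(nrow(detect_melt_events_during_unwinding(st4, 89)$events), 0)

  # chain +3, +3, -3: earliest qualifying forward step pairs first
  st5 <- make_steps(c(1.00, 1.02, 1.04), c(3, 3, -3))
  res5 <- detect_melt_events_during_unwinding(st5, 89)
  expect_equal(nrow(res5$events), 1)
  expect_equal(res5$events$t_melt, 1.02)
  expect_equal(nrow(res5$steps), 1)
})

test_that("bare-hairpin melt detector recovers injected pulses", {
  # flat trace: nothing
  flat <- simulate_bare_hairpin(melting_params(conc_nM = 0), 60, 0.3, 267,
                                seed = 41)
  expect_equal(nrow(detect_melt_events_bare(flat)), 0)

  # injected 5 bp / 20 ms pulses at full bandwidth: >= 90% recall
  tr <- simulate_bare_hairpin(melting_params(conc_nM = 10), 300, 0.3, 267,
                              seed = 42)
  truth <- injection_log(tr)$melts
  ev <- detect_melt_events_bare(tr)
  recall <- mean(vapply(seq_len(nrow(truth)), function(i)
    any(ev$t_melt <= truth$t_anneal[i] & ev$t_anneal >= truth$t_melt[i]),
    logical(1)))
  expect_gte(recall, 0.9)

  # noiseless 3 bp pulses rejected by the 4 bp amplitude criterion
  rate <- 267
  y3 <- rep(0, 8000)
  for (s in seq(500, 7500, by = 700)) y3[s:(s + 5)] <- 3
  tr3 <- unwind_trace((seq_along(y3) - 1) / rate, y3)
  expect_equal(nrow(detect_melt_events_bare(tr3)), 0)

  # 1 s long 5 bp excursions rejected by max_lifetime
  y5 <- rep(0, 8000)
  for (s in c(1000, 4000, 7000)) y5[s:(s + rate)] <- 5
  tr5 <- unwind_trace((seq_along(y5) - 1) / rate, y5)
  expect_equal(nrow(detect_melt_events_bare(tr5, max_lifetime = 0.2)), 0)
  # the same excursions pass with a permissive lifetime cap
  expect_equal(nrow(detect_melt_events_bare(tr5, max_lifetime = 2)), 3)
})

test_that("k_on estimation is correct, invariant, and recovers the truth", {
  # exact arithmetic: inter-event times of 1 s at 10 nM
  ev <- data.frame(t_melt = 0:9, t_anneal = 0:9 + 0.02,
                   amplitude_bp = 5, baseline_position = 0)
  k <- estimate_kon(ev, 10e-9, 10)
  expect_equal(k$k_on, 1e8, tolerance = 1e-9)
  expect_equal(k$se, 1e8 / 3, tolerance = 1e-9)

  # doubling concentration halves inter-event times: same k_on
  ev2 <- data.frame(t_melt = seq(0, 4.5, by = 0.5))
  expect_equal(estimate_kon(ev2, 20e-9, 5)$k_on, 1e8, tolerance = 1e-9)

  # Poisson-process oracle: events at k_on = 1.2e8, 10 nM over 500 s
  set.seed(55)
  tev <- cumsum(rexp(600, 1.2))
  tev <- tev[tev < 500]
  k3 <- estimate_kon(data.frame(t_melt = tev), 10e-9, 500)
  expect_lt(abs(k3$k_on - 1.2e8), 2 * k3$se)

  expect_error(estimate_kon(ev[1, , drop = FALSE], 10e-9, 10), "at least 2")
  expect_error(estimate_kon(ev, 0, 10), "positive")
})

test_that("detected melt frequency is linear in concentration", {
  # mirrors the concentration-response of melting: slope > 0, R^2 > 0.9
  concs <- c(2, 5, 10, 20)
  rate <- vapply(concs, function(cn) {
    tr <- simulate_bare_hairpin(melting_params(conc_nM = cn), 250, 0.3, 267,
                                seed = 500 + cn)
    nrow(detect_melt_events_bare(tr)) / 250
  }, numeric(1))
  fit <- stats::lm(rate ~ concs)
  expect_gt(stats::coef(fit)[2], 0)
  expect_gt(summary(fit)$r.squared, 0.9)
})

test_that("false-positive melt rate without protein is below the 10 nM rate", {
  r <- xpd_reference_rates_at(0)
  rate_at <- function(cn, seed) {
    tr <- simulate_trace(r, melting = melting_params(conc_nM = cn),
                         duration = 90, seed = seed)
    st <- detect_steps(tr)
    nrow(detect_melt_events_during_unwinding(
      st, attr(tr, "sampling_rate_hz"))$events) / 90
  }
  fp0 <- mean(vapply(1:4, function(i) rate_at(0, 600 + i), numeric(1)))
  fp10 <- mean(vapply(1:4, function(i) rate_at(10, 650 + i), numeric(1)))
  expect_lt(fp0, fp10)
})
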