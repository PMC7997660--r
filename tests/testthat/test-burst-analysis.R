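test_that("robust smoothing reproduces quadratics and suppresses spikes", {
  tt <- (0:299) / 89
  quad <- 1 + 2 * tt + 3 * tt^2
  sm <- suppressWarnings(smooth_robust(unwind_trace(tt, quad)))
  expect_lt(max(abs(sm$position - quad)), 1e-8)  # degree-2 exactness

  spiked <- quad; spiked[150] <- spiked[150] + 5
  sm2 <- suppressWarnings(smooth_robust(unwind_trace(tt, spiked)))
  expect_lt(max(abs(sm2$position - quad)), 1)    # 5 bp spike suppressed

  flat <- suppressWarnings(smooth_robust(unwind_trace(tt, rep(2, 300))))
  expect_lt(max(abs(flat$position - 2)), 1e-10)  # constant unchanged
})

test_that("flat traces segment into no bursts", {
  set.seed(91)
  tr <- unwind_trace((0:499) / 89, rnorm(500, 0, 0.3))
  expect_equal(nrow(segment_bursts(tr)), 0)
})

test_that("a single up/down excursion is one low-processivity burst", {
  tr <- triangle_trace(apex = 20)
  b <- segment_bursts(tr)
  expect_equal(nrow(b), 1)
  # smoothing rounds the triangle apex slightly
  expect_lt(abs(b$processivity_bp - 20), 0.5)
  expect_equal(b$category, "low")
  expect_true(b$complete)
  # raising the threshold never increases n_high (monotone classification)
  for (thr in c(10, 15, 19)) {
    b2 <- segment_bursts(tr, threshold_bp = thr)
    expect_equal(b2$category, if (20 > thr) "high" else "low")
  }
})

test_that("processivity excludes masked melting spikes at the apex", {
  tr <- triangle_trace(apex = 30)
  # inject a 5 bp melt spike at the apex
  apex_i <- which.max(tr$position)
  y <- tr$position
  y[apex_i + (-2:2)] <- y[apex_i + (-2:2)] + 5
  spiked <- unwind_trace(tr$time_s, y)
  ev <- data.frame(t_melt = tr$time_s[apex_i - 3],
                   t_anneal = tr$time_s[apex_i + 3],
                   amplitude_bp = 5, baseline_position = 30)
  burst <- data.frame(t_start = 0, t_end = max(tr$time_s))
  expect_lt(abs(burst_processivity(burst, spiked, melt_events = ev) - 30),
            0.5)
  # on the raw (unsmoothed) trace, only masking removes the spike
  expect_gt(burst_processivity(burst, spiked, smooth_window = 0), 34)
  expect_lt(abs(burst_processivity(burst, spiked, melt_events = ev,
                                   smooth_window = 0) - 30), 0.5)
})

test_that("unwinding-portion selection applies the three class rules", {
  rate <- 89
  # high-processivity burst: start to maximum
  tr_hi <- triangle_trace(apex = 40)
  b_hi <- segment_bursts(tr_hi)
  w <- select_unwinding_portion(b_hi[1, ], smooth_robust(tr_hi))
  t_apex <- tr_hi$time_s[which.max(tr_hi$position)]
  expect_equal(unname(w["t_end_u"]), t_apex, tolerance = 0.2)

  # low burst stalling at 12 bp: ends at the last crossing of 10 bp
  up <- seq(0, 12, by = 4 / rate)
  stall <- rep(12, 5 * rate)
  dn <- seq(12, 0, by = -40 / rate)
  y <- c(rep(0, 90), up, stall, dn, rep(0, 90))
  tr_lo <- unwind_trace((seq_along(y) - 1) / rate, y)
  b_lo <- data.frame(t_start = 0, t_end = max(tr_lo$time_s),
                     processivity_bp = 12)
  w_lo <- select_unwinding_portion(b_lo, tr_lo)
  t_last_above10 <- max(tr_lo$time_s[tr_lo$position > 10])
  expect_equal(unname(w_lo["t_end_u"]), t_last_above10, tolerance = 0.05)

  # sub-10 bp burst of 10 s: first 75% kept
  b_small <- data.frame(t_start = 2, t_end = 12, processivity_bp = 8)
  tr_small <- unwind_trace(seq(0, 14, by = 1 / rate),
                           rep(4, length(seq(0, 14, by = 1 / rate))))
  w_s <- select_unwinding_portion(b_small, tr_small)
  expect_equal(unname(w_s["t_end_u"] - w_s["t_start_u"]), 7.5)
})

test_that("velocity profiles read exact slopes and resolve the stall contrast", {
  # exact ramp: every window slope is 4 bp/s
  rate <- 89
  ramp <- unwind_trace((0:499) / rate, 4 * (0:499) / rate)
  rb <- data.frame(t_start = 0, t_end = 499 / rate, processivity_bp = 25)
  vp <- velocity_profile(rb, ramp)
  expect_true(all(abs(vp$velocity_bp_s - 4) < 1e-9))

  # zero-length input
  v0 <- velocity_profile(rb[0, ], ramp)
  expect_equal(nrow(v0), 0)

  # simulated high bursts traverse the stall faster than low bursts
  r <- kinetic_rates(0.05, 0.18, 0.17, 0)
  vel_in_stall <- function(cat, seeds) {
    vals <- c()
    for (s in seeds) {
      tr <- simulate_trace(r, melting = melting_params(conc_nM = 0),
                           duration = 80, seed = s,
                           forced_bursts = data.frame(
                             apex_bp = if (cat == "high") 45 else 14.5,
                             category = cat))
      sm <- smooth_robust(tr)
      b <- segment_bursts(tr)
      if (nrow(b) == 0) next
      vp <- velocity_profile(b[1, , drop = FALSE], sm)
      vals <- c(vals, vp$velocity_bp_s[vp$position_bp >= 10 &
                                         vp$position_bp <= 14])
    }
    mean(vals)
  }
  expect_gt(vel_in_stall("high", 700 + 1:6), vel_in_stall("low", 720 + 1:6))
})

test_that("burst summaries reproduce the bookkeeping identities", {
  # reconstruct per-burst rows from the reference burst counts and check
  # the arithmetic of the summary table
  counts <- xpd_burst_counts()
  rows <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    cc <- counts[i, ]
    if (cc$n_bursts == 0) return(NULL)
    data.frame(
      rpa2_nM = cc$rpa2_nM, force_pN = cc$force_pN, protein = cc$protein,
      gp32_nM = cc$gp32_nM,
      molecule_id = paste0("cond", i, "_m",
                           rep_len(seq_len(cc$n_molecules), cc$n_bursts)),
      processivity_bp = c(rep(10, cc$n_low), rep(40, cc$n_high)),
      duration_s = 7, category = c(rep("low", cc$n_low),
                                   rep("high", cc$n_high)),
      complete = TRUE, cond = i)
  }))
  s <- summarize_bursts(rows, condition = "cond")
  expect_true(all(s$n_low + s$n_high == s$n_bursts))
  expect_equal(s$fraction_high, s$n_high / s$n_bursts)

  # the 7-8 pN no-protein condition: 141 bursts over 10 molecules
  s1 <- s[s$condition == 1, ]
  expect_equal(s1$bursts_per_molecule, 14.1)
  # 12 pN, 10 nM: 29 high of 60 bursts = 48.3%
  i10 <- which(counts$force_pN == 12 & counts$protein == "wt" &
                 counts$rpa2_nM == 10)
  expect_equal(s$fraction_high[s$condition == i10], 29 / 60)
  expect_equal(round(100 * s$fraction_high[s$condition == i10], 1), 48.3)
})

test_that("summaries handle empty and degenerate conditions", {
  b <- data.frame(rpa2_nM = factor(c("0", "0"), levels = c("0", "10")),
                  processivity_bp = c(10, 30), duration_s = c(5, 8),
                  category = c("low", "high"), complete = c(TRUE, FALSE))
  s <- summarize_bursts(b)
  expect_equal(s$n_bursts[s$condition == "0"], 2)
  # durations use complete bursts only
  expect_equal(s$mean_duration[s$condition == "0"], 5)
  # fuzz: identities hold on random tables
  set.seed(101)
  for (i in 1:20) {
    nb <- sample(1:30, 1)
    bf <- data.frame(rpa2_nM = sample(c(0, 10, 50), nb, replace = TRUE),
                     processivity_bp = runif(nb, 5, 89),
                     duration_s = runif(nb, 1, 30),
                     complete = sample(c(TRUE, FALSE), nb, replace = TRUE))
    bf$category <- ifelse(bf$processivity_bp > 25, "high", "low")
    sf <- summarize_bursts(bf)
    expect_true(all(sf$n_low + sf$n_high == sf$n_bursts))
    expect_true(all(abs(sf$fraction_high - sf$n_high / sf$n_bursts) < 1e-12))
  }
})

test_that("simulated molecules recover the configured bursts per molecule", {
  # injection-log-free oracle: segmentation vs the generator's burst count
  set.seed(111)
  n_inj <- c(); n_det <- c()
  for (i in 1:25) {
    tr <- simulate_trace(kinetic_rates(0.05, 0.18, 0.17, 0),
                         melting = melting_params(conc_nM = 0),
                         duration = 200, noise_sd = 0.3, seed = 800 + i)
    n_inj <- c(n_inj, nrow(injection_log(tr)$bursts))
    n_det <- c(n_det, nrow(segment_bursts(tr)))
  }
  expect_lt(abs(mean(n_det) - mean(n_inj)), 0.75)
  expect_lt(abs(mean(n_det) - 5), 1)
})
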