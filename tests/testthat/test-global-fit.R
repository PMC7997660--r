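test_that("weighted line fit is exact on exact lines", {
  conc <- c(0, 2, 5, 10, 50)
  y <- 2e7 * conc * 1e-9 + 1e-2
  rl <- fit_k1_vs_conc(y, conc, sigma = rep(0.01, 5))
  expect_equal(rl$slope, 2e7, tolerance = 1e-12)
  expect_equal(rl$intercept, 1e-2, tolerance = 1e-12)
  # equal sigma equals unweighted
  rl2 <- fit_k1_vs_conc(y, conc)
  expect_equal(rl2$slope, rl$slope, tolerance = 1e-12)
})

test_that("reference switching rates give the published second-order rate law", {
  # closed-form weighted-regression oracle run on the tabulated k1 values
  ref <- xpd_reference_rates()
  rl <- fit_k1_vs_conc(ref$k1$k1, ref$k1$conc_nM, sigma = ref$k1$ci95)
  # independent closed-form computation of the weighted slope/intercept
  w <- 1 / ref$k1$ci95^2
  x <- ref$k1$conc_nM * 1e-9
  xb <- sum(w * x) / sum(w); yb <- sum(w * ref$k1$k1) / sum(w)
  slope_cf <- sum(w * (x - xb) * (ref$k1$k1 - yb)) / sum(w * (x - xb)^2)
  expect_equal(rl$slope, slope_cf, tolerance = 1e-10)
  expect_equal(rl$intercept, yb - slope_cf * xb, tolerance = 1e-10)
  # slope consistent with (1.5 +/- 0.5) x 10^7 1/M/s
  expect_gt(rl$slope, 1.0e7)
  expect_lt(rl$slope, 2.0e7)
  # intercept in the (1-2) x 10^-2 1/s window
  expect_gte(rl$intercept, 0.5e-2)
  expect_lte(rl$intercept, 2e-2)
})

test_that("global fit recovers generating rates from synthetic data", {
  rates <- ref_rates_list()
  fp <- simulate_first_passage(rates, 100, 200, seed = 99)
  fit <- fit_global(fp, n_boot = 40, seed = 1)
  expect_true(fit$convergence %in% c(0, 1))
  # k2 within its bootstrap 95% CI of the generating value
  expect_gte(0.170, fit$ci["k2", 1])
  expect_lte(0.170, fit$ci["k2", 2])
  # k_off recovered to the same order
  expect_gt(fit$rates[["k_off"]], 0.01)
  expect_lt(fit$rates[["k_off"]], 0.08)
  # switching rates increase with concentration overall
  k1s <- fit$rates[grep("^k1_", names(fit$rates))]
  expect_gt(unname(k1s["k1_50"]), unname(k1s["k1_0"]))
})

test_that("free-k'off fits find a negligible high-state dissociation rate", {
  rates <- ref_rates_list()[c("0", "10", "50")]
  fp <- simulate_first_passage(rates, 120, 200, seed = 7)
  fit <- fit_global(fp, free_koff_prime = TRUE, n_boot = 0, seed = 2)
  expect_lt(fit$rates[["k_off_prime"]], 0.05)
})

test_that("degenerate inputs are handled sensibly", {
  # no crossings at all: the crossing flux k * D collapses to zero
  fp <- data.frame(molecule_id = sprintf("m%02d", 1:40),
                   conc_nM = rep(c(0, 10), each = 20),
                   t_cross_s = NA_real_, status = "censored", t_max_s = 60)
  class(fp) <- c("first_passage", class(fp))
  fit <- suppressWarnings(fit_global(fp, n_boot = 0, n_starts = 2, seed = 3))
  expect_lt(p_gt25(60, fit$params, k = unname(fit$rates[["k1_10"]])), 0.02)
  # single concentration is refused
  fp1 <- fp[fp$conc_nM == 0, ]
  class(fp1) <- c("first_passage", class(fp1))
  expect_error(fit_global(fp1), "2 concentrations")
  # sparse data warns
  expect_warning(
    fit_global(do.call(rbind, lapply(c(0, 10), function(cn) {
      d <- fp[fp$conc_nM == cn, ][1:4, ]; d
    })), n_boot = 0, n_starts = 1),
    "fewer than 10")
})

test_that("parameter recovery is unbiased enough across replicates", {
  # scaled-down replicate study: median relative bias of shared rates
  rates <- ref_rates_list()[c("0", "5", "10", "50")]
  est <- t(vapply(1:5, function(i) {
    fp <- simulate_first_passage(rates, 80, 150, seed = 2000 + i)
    f <- fit_global(fp, n_boot = 0, n_starts = 2, seed = i)
    f$rates[c("k2", "k_off", "k_minus1")]
  }, numeric(3)))
  bias <- apply(est, 2, median) / c(0.170, 0.037, 0.18) - 1
  expect_lt(abs(bias[["k2"]]), 0.35)
  expect_lt(abs(bias[["k_off"]]), 0.35)
})

test_that("empirical crossing curves are proper step functions", {
  rates <- ref_rates_list()[c("0", "50")]
  fp <- simulate_first_passage(rates, 50, 100, seed = 13)
  cf <- crossing_fraction(fp, seq(0, 100, by = 1))
  for (cn in unique(cf$conc_nM)) {
    f <- cf$fraction[cf$conc_nM == cn]
    expect_true(all(diff(f) >= 0))
    expect_equal(f[1], 0)
    expect_lte(max(f), 1)
  }
})
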