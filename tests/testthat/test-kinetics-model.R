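test_that("eigenvalues match the generator-matrix eigen-decomposition", {
  # independent oracle: eigenvalues of the explicit 2x2 generator
  matrix_lambdas <- function(r) {
    M <- matrix(c(-(r$k_off + r$k1), r$k_minus1,
                  r$k1, -(r$k_off_prime + r$k_minus1 + r$k2)),
                2, 2, byrow = TRUE)
    sort(eigen(-M, only.values = TRUE)$values)
  }
  cases <- list(
    kinetic_rates(0.2, 0.18, 0.17, 0.037),            # 10 nM reference set
    kinetic_rates(0.5, 0, 0.3, 0, 0),                 # k and D only
    kinetic_rates(1.15, 0.18, 0.17, 0.037),           # 50 nM reference set
    kinetic_rates(0.02, 0.18, 0.17, 0.037, 0.05))     # free k'off
  for (r in cases) {
    lam <- rate_eigenvalues(r)
    expect_equal(unname(lam), matrix_lambdas(r), tolerance = 1e-12)
    expect_gte(lam[["lambda_minus"]], 0)
    expect_gte(lam[["lambda_plus"]], lam[["lambda_minus"]])
  }
  # degenerate all-zero case
  expect_equal(unname(rate_eigenvalues(kinetic_rates(0, 0, 1, 0))),
               c(0, 1))
})

test_that("closed-form threshold-crossing probability matches the ODE solution", {
  ref <- xpd_reference_rates()
  tg <- seq(0, 200, by = 1)
  for (cn in ref$k1$conc_nM) {
    r <- xpd_reference_rates_at(cn)
    num <- solve_states(tg, r)
    ana <- p_gt25(num$time_s, r)
    expect_lt(max(abs(num$P_gt25 - ana)), 1e-8)
    # conservation and bounds
    expect_lt(max(abs(rowSums(num[, -1]) - 1)), 1e-9)
    expect_true(all(num[, -1] >= -1e-12 & num[, -1] <= 1 + 1e-12))
  }
})

test_that("p_gt25 has the right limits and monotonicity", {
  r <- xpd_reference_rates_at(10)
  expect_equal(p_gt25(0, r), 0)
  tg <- seq(0, 300, by = 0.5)
  p <- p_gt25(tg, r)
  expect_true(all(diff(p) >= -1e-14))

  # no leak: k_off = k'off = 0 gives P(inf) = 1
  r0 <- kinetic_rates(0.2, 0.18, 0.17, 0)
  expect_equal(p_gt25_inf(r0), 1)
  expect_equal(p_gt25(5000, r0), 1, tolerance = 1e-6)

  # long-time limit equals k D / (A k + B C)
  pinf <- p_gt25_inf(r)
  expect_equal(p_gt25(5000, r), pinf, tolerance = 1e-8)
  expect_equal(pinf, 0.2 * 0.17 / (0.17 * 0.2 + 0.037 * 0.35),
               tolerance = 1e-12)

  # monotone in k1 at fixed t
  ks <- c(0.02, 0.059, 0.2, 1.15)
  expect_true(all(diff(vapply(
    ks, function(k) p_gt25(7, kinetic_rates(k, 0.18, 0.17, 0.037)),
    numeric(1))) > 0))

  # k1 = 0 gives no crossing at all
  expect_equal(p_gt25(c(1, 10, 100), kinetic_rates(0, 0.18, 0.17, 0.037)),
               c(0, 0, 0))
})

test_that("repeated-eigenvalue limit is continuous", {
  # with A = C = D and B = k the discriminant is (k - A/2)^2, so
  # k = A/2 sits exactly on the repeated root and eps moves just off it
  p_near <- function(eps) {
    fit_params(A = 0.4, B = 0.2, C = 0.4, D = 0.4, k = 0.2 + eps)
  }
  lam <- rate_eigenvalues(p_near(0))
  expect_equal(lam[["lambda_minus"]], lam[["lambda_plus"]], tolerance = 1e-9)
  t <- c(0.5, 2, 10)
  p_limit <- p_gt25(t, p_near(0))
  p_close <- p_gt25(t, p_near(1e-7))
  expect_equal(p_limit, p_close, tolerance = 1e-5)
  expect_true(all(p_limit >= 0 & p_limit <= 1))
})

test_that("fit-parameter mapping round-trips rates", {
  r <- kinetic_rates(0.2, 0.18, 0.17, 0.037, 0.01)
  p <- as_fit_params(r)
  expect_equal(p$D, r$k2)
  expect_equal(p$B, r$k_off)
  expect_equal(p$C - p$A, r$k_minus1)
  expect_equal(p$A - p$D, r$k_off_prime)
  back <- as_kinetic_rates(p)
  expect_equal(unclass(back), unclass(r), tolerance = 1e-12)
  # constrained variant: k'off = 0 implies A = D
  p0 <- as_fit_params(kinetic_rates(0.2, 0.18, 0.17, 0.037, 0))
  expect_equal(p0$A, p0$D)
})

test_that("derived burst models behave as convex combinations", {
  r <- xpd_reference_rates_at(50)
  # burst fraction model is P(tau_low)
  expect_equal(burst_fraction_model(r, tau_low = 7), p_gt25(7, r))
  # k = 0 baseline ~ 0; increasing k increases the fraction
  expect_equal(burst_fraction_model(kinetic_rates(0, 0.18, 0.17, 0.037)), 0)
  fr <- vapply(c(0.02, 0.2, 1.15), function(k)
    burst_fraction_model(kinetic_rates(k, 0.18, 0.17, 0.037)), numeric(1))
  expect_true(all(diff(fr) > 0))

  # duration model: bounds and degenerate weights
  d <- burst_duration_model(r, tau_low = 7, tau_high = 20)
  expect_gte(d, 7); expect_lte(d, 20)
  expect_equal(burst_duration_model(kinetic_rates(0, 0.18, 0.17, 0.037),
                                    tau_low = 7, tau_high = 20), 7)
  expect_equal(burst_duration_model(kinetic_rates(0.2, 0.18, 0.17, 0),
                                    tau_low = 7, tau_high = 20), 20)
  # against an explicit mixture-weight computation at 50 nM
  pinf <- p_gt25_inf(r)
  expect_equal(d, 7 * (1 - pinf) + 20 * pinf, tolerance = 1e-12)
})

test_that("mean bound lifetime exceeds 25 s at the reference k_off", {
  r <- xpd_reference_rates_at(0)
  expect_equal(mean_bound_lifetime(r), 1 / 0.037, tolerance = 1e-12)
  expect_gt(mean_bound_lifetime(r), 25)
  expect_equal(mean_bound_lifetime(kinetic_rates(0, 0, 0, 1e6)), 1e-6)
  expect_equal(mean_bound_lifetime(kinetic_rates(0, 0, 0, 0)), Inf)
})
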