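#' Rate constants of the processivity-switch kinetic scheme
#'
#' Four-state scheme for a helicase that interconverts between a
#' low-processivity and a high-processivity state. From `low` the enzyme
#' switches to `high` at rate `k1` (concentration-dependent when an
#' ssDNA-binding protein drives the switch) or dissociates at `k_off`; from
#' `high` it switches back at `k_minus1`, crosses the scoring threshold
#' (25 bp by default elsewhere) at `k2`, or dissociates at `k_off_prime`
#' (0 by default: dissociation only from the low state).
#'
#' @param k1 low -> high switching rate, 1/s.
#' @param k_minus1 high -> low switching rate, 1/s.
#' @param k2 threshold-crossing rate from the high state, 1/s.
#' @param k_off dissociation rate from the low state, 1/s.
#' @param k_off_prime dissociation rate from the high state, 1/s (default 0).
#' @return An object of class `kinetic_rates`.
#' @export
kinetic_rates <- function(k1, k_minus1, k2, k_off, k_off_prime = 0) {
  vals <- c(k1 = k1, k_minus1 = k_minus1, k2 = k2, k_off = k_off,
            k_off_prime = k_off_prime)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all rate constants must be finite and non-negative")
  structure(as.list(vals), class = "kinetic_rates")
}

#' @export
print.kinetic_rates <- function(x, ...) {
  cat(sprintf(
    "kinetic rates (1/s): k1 = %g, k-1 = %g, k2 = %g, koff = %g, k'off = %g\n",
    x$k1, x$k_minus1, x$k2, x$k_off, x$k_off_prime))
  invisible(x)
}

#' Grouped fit parameterization of the kinetic scheme
#'
#' The first-passage solution depends on the rates only through four
#' concentration-independent groups `A`, `B`, `C`, `D` and the
#' concentration-dependent switching rate `k`:
#' `k1 = k`, `k2 = D`, `k_minus1 = C - A`, `k_off_prime = A - D`,
#' `k_off = B`. With dissociation restricted to the low state
#' (`k_off_prime = 0`), `A = D`.
#'
#' @param A,B,C,D Grouped parameters, 1/s.
#' @param k Switching rate(s) `k1`, 1/s; may be a named vector, one entry
#'   per concentration (names are concentrations in nM).
#' @return An object of class `fit_params`.
#' @export
fit_params <- function(A, B, C, D, k) {
  if (any(!is.finite(c(A, B, C, D, k)))) stop("fit parameters must be finite")
  if (C < A - 1e-12) stop("C must be >= A (k_minus1 = C - A must be >= 0)")
  if (A < D - 1e-12) stop("A must be >= D (k_off_prime = A - D must be >= 0)")
  if (any(c(A, B, C, D, k) < -1e-12)) stop("implied rates must be non-negative")
  structure(list(A = A, B = B, C = C, D = D, k = k), class = "fit_params")
}

#' @rdname fit_params
#' @param rates A [kinetic_rates()] object to convert.
#' @export
as_fit_params <- function(rates) {
  stopifnot(inherits(rates, "kinetic_rates"))
  A <- rates$k_off_prime + rates$k2
  fit_params(A = A, B = rates$k_off, C = rates$k_minus1 + A, D = rates$k2,
             k = rates$k1)
}

#' @rdname fit_params
#' @param params A [fit_params()] object to convert back to rates; if `k` has
#'   several entries, `which_k` selects one (by name or index).
#' @param which_k Entry of `k` to use.
#' @export
as_kinetic_rates <- function(params, which_k = 1L) {
  stopifnot(inherits(params, "fit_params"))
  kinetic_rates(k1 = unname(params$k[which_k]), k_minus1 = params$C - params$A,
                k2 = params$D, k_off = params$B,
                k_off_prime = params$A - params$D)
}

# (1 - exp(-lambda * t)) / lambda, stable as lambda -> 0 (limit t)
.expm1_ratio <- function(lambda, t) {
  if (abs(lambda) < 1e-12) return(t * (1 - lambda * t / 2))
  -expm1(-lambda * t) / lambda
}

#' Relaxation eigenvalues of the kinetic scheme
#'
#' The two decay constants governing the transient states,
#' `lambda_pm = (k + B + C)/2 +/- sqrt(((k + B + C)/2)^2 - (A k + B C))`.
#' These are the eigenvalues of the 2x2 generator restricted to the
#' `low`/`high` states; `A k + B C` is its determinant.
#'
#' @param params A [fit_params()] or [kinetic_rates()] object.
#' @param k Switching rate `k1` (1/s); defaults to `params$k` (first entry).
#' @return Named vector `c(lambda_minus, lambda_plus)`, 1/s.
#' @export
rate_eigenvalues <- function(params, k = NULL) {
  if (inherits(params, "kinetic_rates")) params <- as_fit_params(params)
  stopifnot(inherits(params, "fit_params"))
  if (is.null(k)) k <- unname(params$k[1L])
  s <- (k + params$B + params$C) / 2
  disc <- s^2 - (params$A * k + params$B * params$C)
  if (disc < -1e-10 * max(s^2, 1))
    stop("negative discriminant: unphysical parameter combination")
  disc <- max(disc, 0)
  c(lambda_minus = s - sqrt(disc), lambda_plus = s + sqrt(disc))
}

#' Closed-form first-passage probability past the scoring threshold
#'
#' Probability that a molecule starting in the low-processivity state at
#' `t = 0` has crossed the threshold (entered the `>25 bp` absorbing state)
#' by time `t`:
#' `P(t) = k D / (lambda_minus - lambda_plus) *
#'   ((1 - exp(-lambda_plus t)) / lambda_plus -
#'    (1 - exp(-lambda_minus t)) / lambda_minus)`.
#' The repeated-eigenvalue limit is evaluated analytically, and
#' `(1 - exp(-lambda t)) / lambda` is evaluated in a form stable as
#' `lambda -> 0`.
#'
#' @param t Time(s), s; non-negative.
#' @param params A [fit_params()] or [kinetic_rates()] object.
#' @param k Switching rate `k1` (1/s); defaults to `params$k` (first entry).
#' @return Vector of probabilities, same length as `t`.
#' @export
p_gt25 <- function(t, params, k = NULL) {
  if (inherits(params, "kinetic_rates")) params <- as_fit_params(params)
  stopifnot(inherits(params, "fit_params"))
  if (is.null(k)) k <- unname(params$k[1L])
  if (any(t < 0)) stop("t must be non-negative")
  lam <- rate_eigenvalues(params, k)
  lm <- lam[["lambda_minus"]]; lp <- lam[["lambda_plus"]]
  kD <- k * params$D
  if (kD == 0) return(rep(0, length(t)))
  if ((lp - lm) < 1e-9 * lp) {
    # repeated root: P(t) = k D (1 - e^{-lam t} (1 + lam t)) / lam^2
    lam0 <- (lp + lm) / 2
    return(kD * (1 - exp(-lam0 * t) * (1 + lam0 * t)) / lam0^2)
  }
  rp <- if (lp < 1e-12) t else -expm1(-lp * t) / lp
  rm <- if (lm < 1e-12) t else -expm1(-lm * t) / lm
  kD / (lm - lp) * (rp - rm)
}

#' @rdname p_gt25
#' @details `p_gt25_inf()` returns the long-time limit
#'   `k D / (A k + B C)`, the asymptotic fraction of molecules that ever
#'   cross the threshold.
#' @export
p_gt25_inf <- function(params, k = NULL) {
  if (inherits(params, "kinetic_rates")) params <- as_fit_params(params)
  if (is.null(k)) k <- unname(params$k[1L])
  denom <- params$A * k + params$B * params$C
  if (denom == 0) return(if (k * params$D > 0) 1 else 0)
  k * params$D / denom
}

#' Numerical solution of the four-state master equations
#'
#' Integrates
#' `dP_low = k_minus1 P_high - (k_off + k1) P_low`,
#' `dP_high = k1 P_low - (k_off' + k_minus1 + k2) P_high`,
#' `dP_off = k_off P_low + k_off' P_high`,
#' `dP_gt25 = k2 P_high`
#' from `P_low(0) = 1` with a stiff ODE solver. Serves as the independent
#' numerical route to the closed form [p_gt25()].
#'
#' @param t_grid Times at which to report the solution (first entry 0 is
#'   added if absent), s.
#' @param rates A [kinetic_rates()] object.
#' @return Data frame with columns `time_s`, `P_low`, `P_high`, `P_off`,
#'   `P_gt25`.
#' @export
solve_states <- function(t_grid, rates) {
  stopifnot(inherits(rates, "kinetic_rates"))
  tg <- sort(unique(c(0, t_grid)))
  deriv <- function(t, y, p) {
    list(c(
      p$k_minus1 * y[2] - (p$k_off + p$k1) * y[1],
      p$k1 * y[1] - (p$k_off_prime + p$k_minus1 + p$k2) * y[2],
      p$k_off * y[1] + p$k_off_prime * y[2],
      p$k2 * y[2]))
  }
  out <- deSolve::lsoda(c(1, 0, 0, 0), tg, deriv, rates,
                        rtol = 1e-10, atol = 1e-12)
  res <- data.frame(time_s = out[, 1], P_low = out[, 2], P_high = out[, 3],
                    P_off = out[, 4], P_gt25 = out[, 5])
  res[res$time_s %in% t_grid | res$time_s == 0, , drop = FALSE]
}

#' Mean DNA-bound lifetime of the helicase
#'
#' For the model variant with dissociation only from the low state, the mean
#' bound lifetime when switching is off (`k1 = 0`) is `1 / k_off`.
#'
#' @param rates A [kinetic_rates()] object.
#' @return Mean lifetime in s (`Inf` when `k_off = 0`).
#' @export
mean_bound_lifetime <- function(rates) {
  stopifnot(inherits(rates, "kinetic_rates"))
  if (rates$k_off == 0) return(Inf)
  1 / rates$k_off
}

#' Model for the fraction of high-processivity bursts
#'
#' The fraction of bursts scored high-processivity at a given concentration
#' is modeled as the first-passage probability evaluated at the mean
#' low-processivity burst duration: `P(tau_low)`.
#'
#' @param params [fit_params()] or [kinetic_rates()] object.
#' @param k Switching rate `k1` at the concentration of interest, 1/s.
#' @param tau_low Mean low-processivity burst duration, s (default 7).
#' @return Model fraction in `[0, 1]`.
#' @export
burst_fraction_model <- function(params, k = NULL, tau_low = 7) {
  p_gt25(tau_low, params, k)
}

#' Model for the mean burst duration
#'
#' Convex combination of the low- and high-processivity burst durations
#' weighted by the long-time threshold-crossing probability:
#' `<t_burst> = tau_low (1 - P_inf) + tau_high P_inf`.
#'
#' @param params [fit_params()] or [kinetic_rates()] object.
#' @param k Switching rate `k1` at the concentration of interest, 1/s.
#' @param tau_low,tau_high Mean burst durations of the two categories, s.
#' @return Model mean burst duration, s.
#' @export
burst_duration_model <- function(params, k = NULL, tau_low = 7, tau_high = 20) {
  pinf <- p_gt25_inf(params, k)
  tau_low * (1 - pinf) + tau_high * pinf
}

#' Reference rate constants for XPD unwinding in the presence of RPA2
#'
#' Best-fit rate constants of the processivity-switch model for FacXPD
#' helicase with FacRPA2, used as simulator defaults and as reference inputs
#' for desk-scale checks: shared rates `k_minus1 = 0.18`, `k2 = 0.170`,
#' `k_off = 0.037`, `k_off_prime = 0` (all 1/s), and the
#' concentration-dependent switching rate `k1` at 0, 2, 5, 10 and 50 nM
#' RPA2. Uncertainties are half-widths of 95% confidence intervals.
#'
#' @return A list with elements `k1` (data frame: `conc_nM`, `k1`, `ci95`),
#'   `k_minus1`, `k2`, `k_off`, `k_off_prime`, and the shared uncertainties
#'   `ci95` (named vector).
#' @export
xpd_reference_rates <- function() {
  list(
    k1 = data.frame(
      conc_nM = c(0, 2, 5, 10, 50),
      k1 = c(0.02, 0.059, 0.065, 0.200, 1.15),
      ci95 = c(0.006, 0.017, 0.019, 0.059, 0.39)),
    k_minus1 = 0.18, k2 = 0.170, k_off = 0.037, k_off_prime = 0,
    ci95 = c(k_minus1 = 0.13, k2 = 0.017, k_off = 0.019))
}

#' @rdname xpd_reference_rates
#' @param conc_nM Concentration in nM; must be one of the tabulated values.
#' @return `xpd_reference_rates_at()` returns the full [kinetic_rates()]
#'   object at one tabulated concentration.
#' @export
xpd_reference_rates_at <- function(conc_nM) {
  ref <- xpd_reference_rates()
  i <- match(conc_nM, ref$k1$conc_nM)
  if (is.na(i)) stop("conc_nM must be one of ",
                     paste(ref$k1$conc_nM, collapse = ", "), " nM")
  kinetic_rates(k1 = ref$k1$k1[i], k_minus1 = ref$k_minus1, k2 = ref$k2,
                k_off = ref$k_off, k_off_prime = ref$k_off_prime)
}

#' Reference burst bookkeeping for XPD with RPA2
#'
#' Observed burst counts from the single-molecule XPD/RPA2 hairpin-unwinding
#' data set: number of molecules, bursts, and low/high-processivity bursts
#' per condition (force, protein, concentration). Used for bookkeeping
#' checks of the burst summary arithmetic.
#'
#' @return Data frame with columns `force_pN`, `protein`, `rpa2_nM`,
#'   `gp32_nM`, `n_molecules`, `n_bursts`, `n_low`, `n_high`.
#' @export
xpd_burst_counts <- function() {
  data.frame(
    force_pN   = c(7.5, 7.5, 9, 9, 9, 9, 12, 12, 12, 12, 12, 12, 12),
    protein    = c("wt", "wt", "wt", "wt", "H202A", "H202A",
                   "wt", "wt", "wt", "wt", "wt", "H202A", "H202A"),
    rpa2_nM    = c(0, 0, 0, 10, 0, 10, 0, 2, 5, 10, 50, 0, 10),
    gp32_nM    = c(0, 250, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    n_molecules = c(10, 8, 6, 25, 11, 11, 20, 19, 27, 20, 21, 29, 16),
    n_bursts   = c(141, 23, 54, 74, 38, 67, 94, 123, 79, 60, 82, 123, 79),
    n_low      = c(141, 23, 54, 60, 36, 63, 86, 109, 61, 31, 45, 46, 36),
    n_high     = c(0, 0, 0, 14, 2, 4, 8, 14, 18, 29, 37, 77, 43))
}
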