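#' Extract first-passage times from traces
#'
#' The first-passage time of a molecule is the first time its trace crosses
#' the scoring threshold. A short running median suppresses isolated
#' noise-driven crossings. Molecules that never cross are censored at the
#' end of their trace.
#'
#' @param traces List of `unwind_trace` objects (one per molecule).
#' @param threshold_bp Crossing threshold, bp (default 25).
#' @param median_points Running-median length for de-noising (odd,
#'   default 5; 1 disables).
#' @return A `first_passage` data frame.
#' @export
first_passage_from_traces <- function(traces, threshold_bp = 25,
                                      median_points = 5) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    y <- tr$position
    if (median_points > 1 && length(y) >= median_points)
      y <- stats::runmed(y, median_points)
    hit <- which(y > threshold_bp)
    data.frame(
      molecule_id = as.character(attr(tr, "molecule_id")),
      conc_nM = as.numeric(attr(tr, "rpa2_nM")),
      t_cross_s = if (length(hit)) tr$time_s[hit[1]] else NA_real_,
      status = if (length(hit)) "crossed" else "censored",
      t_max_s = max(tr$time_s))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("first_passage", class(out))
  out
}

# rate-space parameter vector -> fit_params; theta lives in rate space so
# all box constraints are simple non-negativity bounds
.theta_to_params <- function(theta, concs, free_koff_prime) {
  if (free_koff_prime) {
    k2 <- theta[1]; koff <- theta[2]; km1 <- theta[3]; koffp <- theta[4]
    k <- theta[-(1:4)]
  } else {
    k2 <- theta[1]; koff <- theta[2]; km1 <- theta[3]; koffp <- 0
    k <- theta[-(1:3)]
  }
  A <- koffp + k2
  names(k) <- concs
  fit_params(A = A, B = koff, C = km1 + A, D = k2, k = k)
}

.fp_objective <- function(theta, concs, emp, free_koff_prime) {
  params <- try(.theta_to_params(theta, concs, free_koff_prime),
                silent = TRUE)
  if (inherits(params, "try-error")) return(1e10)
  total <- 0
  for (j in seq_along(concs)) {
    e <- emp[[j]]
    pred <- p_gt25(e$time_s, params, k = unname(params$k[j]))
    total <- total + sum(e$w * (e$fraction - pred)^2)
  }
  if (!is.finite(total)) 1e10 else total
}

#' Global fit of the first-passage model across concentrations
#'
#' Fits the closed-form threshold-crossing probability [p_gt25()] to
#' empirical fraction-crossed-vs-time curves, with the grouped parameters
#' `A`, `B`, `C`, `D` shared across all concentrations and one switching
#' rate `k` per concentration. By default dissociation from the
#' high-processivity state is excluded (`k_off_prime = 0`, hence `A = D`),
#' reducing the shared parameters to three rates
#' (`k2`, `k_off`, `k_minus1`); setting `free_koff_prime = TRUE` adds
#' `k_off_prime` as a fourth.
#'
#' Each curve point is weighted by inverse binomial variance
#' `n / (p (1 - p))`, floored at `4 n`. Confidence intervals are
#' percentile intervals from a parametric bootstrap: synthetic molecules
#' are redrawn from the fitted model and refit.
#'
#' @param fp A `first_passage` data frame (>= 2 concentrations).
#' @param t_grid Time grid for the empirical curves (default 101 points to
#'   the common `t_max`).
#' @param free_koff_prime Allow dissociation from the high state.
#' @param n_boot Parametric bootstrap resamples for 95% CIs (default 200;
#'   0 disables).
#' @param n_starts Random multi-starts around the heuristic initial point.
#' @param seed Seed for the bootstrap.
#' @return Object of class `fp_fit`: list with `rates` (named estimates:
#'   `k2`, `k_off`, `k_minus1`, `k_off_prime`, `k1_<conc>`), `ci` (95%
#'   bootstrap percentile intervals), `params` ([fit_params()]), `concs`,
#'   `loss`, `convergence`, `n_molecules`, `boot` (resample matrix).
#' @export
fit_global <- function(fp, t_grid = NULL, free_koff_prime = FALSE,
                       n_boot = 200, n_starts = 4, seed = NULL) {
  stopifnot(all(c("conc_nM", "t_cross_s", "status", "t_max_s") %in% names(fp)))
  concs <- sort(unique(fp$conc_nM))
  if (length(concs) < 2) stop("need at least 2 concentrations for a global fit")
  n_by <- table(fp$conc_nM)
  if (any(n_by < 10))
    warning("fewer than 10 molecules at some concentration; ",
            "estimates may be unstable")
  t_max <- max(fp$t_max_s)
  if (is.null(t_grid)) {
    # dense at early times, where the fast concentrations carry information
    t_grid <- unique(sort(c(seq(0, min(15, t_max), by = 0.25),
                            seq(0, t_max, length.out = 101L))))
  }
  cf <- crossing_fraction(fp, t_grid)
  emp <- lapply(concs, function(cn) {
    e <- cf[cf$conc_nM == cn, ]
    v <- pmax(e$fraction * (1 - e$fraction) / e$n, 1 / (4 * e$n^2))
    e$w <- 1 / v
    e
  })

  # heuristic start: k2 ~ 0.2; koff from the never-crossing fraction;
  # k_j from the final crossed fraction
  f_end <- vapply(emp, function(e) e$fraction[length(t_grid)], numeric(1))
  start0 <- c(0.2, 0.05, 0.2, if (free_koff_prime) 0.01,
              pmax(0.02, 0.3 * f_end / pmax(0.05, 1 - f_end)))
  lower <- rep(1e-6, length(start0))
  upper <- rep(50, length(start0))
  run_fit <- function(start) {
    stats::nlminb(start, .fp_objective, lower = lower, upper = upper,
                  concs = concs, emp = emp,
                  free_koff_prime = free_koff_prime,
                  control = list(iter.max = 500, eval.max = 1000))
  }
  fits <- list(run_fit(start0))
  if (n_starts > 1) {
    if (!is.null(seed)) set.seed(seed)
    for (s in seq_len(n_starts - 1))
      fits[[s + 1]] <- run_fit(pmin(pmax(
        start0 * stats::rlnorm(length(start0), 0, 0.7), lower), upper))
  }
  objs <- vapply(fits, function(f) f$objective, numeric(1))
  best <- fits[[which.min(objs)]]
  if (!best$convergence %in% c(0, 1) && min(objs) > 1e9) {
    e <- simpleError("global first-passage fit did not converge")
    e$best_point <- best$par; e$objective <- best$objective
    stop(e)
  }
  params <- .theta_to_params(best$par, concs, free_koff_prime)
  rates <- c(k2 = params$D, k_off = params$B, k_minus1 = params$C - params$A,
             k_off_prime = params$A - params$D,
             stats::setNames(unname(params$k), paste0("k1_", concs)))

  boot_mat <- NULL; ci <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed + 1L)
    boot_mat <- matrix(NA_real_, n_boot, length(rates),
                       dimnames = list(NULL, names(rates)))
    for (b in seq_len(n_boot)) {
      bs <- do.call(rbind, lapply(seq_along(concs), function(j)
        sample_first_passage_model(params, unname(params$k[j]),
                                   n = as.integer(n_by[as.character(concs[j])]),
                                   t_max = t_max, conc_nM = concs[j])))
      class(bs) <- c("first_passage", class(bs))
      bf <- try(fit_global(bs, t_grid = t_grid,
                           free_koff_prime = free_koff_prime,
                           n_boot = 0, n_starts = 1), silent = TRUE)
      if (!inherits(bf, "try-error")) boot_mat[b, ] <- bf$rates
    }
    ci <- t(apply(boot_mat, 2, stats::quantile,
                  probs = c(0.025, 0.975), na.rm = TRUE))
  }

  structure(list(rates = rates, ci = ci, params = params, concs = concs,
                 loss = best$objective, convergence = best$convergence,
                 n_molecules = as.vector(n_by), boot = boot_mat,
                 t_grid = t_grid),
            class = "fp_fit")
}

#' @export
print.fp_fit <- function(x, ...) {
  cat("Global first-passage fit (", length(x$concs), " concentrations)\n",
      sep = "")
  for (nm in names(x$rates)) {
    cat(sprintf("  %-12s %8.4f 1/s", nm, x$rates[[nm]]))
    if (!is.null(x$ci) && nm %in% rownames(x$ci))
      cat(sprintf("  [%.4f, %.4f]", x$ci[nm, 1], x$ci[nm, 2]))
    cat("\n")
  }
  cat(sprintf("  loss %.4g, convergence code %d\n", x$loss, x$convergence))
  invisible(x)
}

#' Weighted linear fit of the switching rate vs. concentration
#'
#' Inverse-variance-weighted least-squares line through `k1` vs. protein
#' concentration. The slope is the effective second-order rate constant
#' for the protein driving the processivity switch (1/M/s); the intercept
#' is the basal switching rate (1/s).
#'
#' @param k1 Switching rates, 1/s.
#' @param conc_nM Concentrations, nM (converted to molar internally).
#' @param sigma Optional standard errors of `k1`; weights are `1/sigma^2`
#'   (equal weights when omitted).
#' @return Object of class `rate_law`: list with `slope` (1/M/s),
#'   `intercept` (1/s), `slope_se`, `intercept_se`, and the underlying
#'   `lm` fit.
#' @export
fit_k1_vs_conc <- function(k1, conc_nM, sigma = NULL) {
  stopifnot(length(k1) == length(conc_nM), length(k1) >= 2)
  conc_M <- conc_nM * 1e-9
  w <- if (is.null(sigma)) rep(1, length(k1)) else 1 / sigma^2
  fit <- stats::lm(k1 ~ conc_M, weights = w)
  # degenerate exact-line inputs make summary() warn about perfect fits
  s <- suppressWarnings(summary(fit))$coefficients
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_se = s[2, 2], intercept_se = s[1, 2], fit = fit),
            class = "rate_law")
}

#' @export
print.rate_law <- function(x, ...) {
  cat(sprintf("linear rate law: slope %.3g +/- %.2g 1/M/s, intercept %.3g +/- %.2g 1/s\n",
              x$slope, x$slope_se, x$intercept, x$intercept_se))
  invisible(x)
}
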