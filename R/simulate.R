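#' Simulate one state path of the kinetic scheme
#'
#' Exact continuous-time Markov jump path by the Gillespie direct method.
#' The molecule starts in the low-processivity state at `t = 0`; `off`
#' (dissociated) and `crossed` (past the scoring threshold) are absorbing.
#'
#' @param rates A [kinetic_rates()] object.
#' @param t_max Maximum simulated time, s; the path is censored there.
#' @param seed Optional integer seed for reproducibility.
#' @return Data frame with columns `state` (`low`, `high`, `off`, `crossed`)
#'   and `entry_time` (s), one row per state entered, in order. Attribute
#'   `t_max` records the censoring horizon.
#' @export
simulate_state_path <- function(rates, t_max, seed = NULL) {
  stopifnot(inherits(rates, "kinetic_rates"))
  if (!is.finite(t_max) || t_max <= 0) stop("t_max must be positive")
  if (!is.null(seed)) set.seed(seed)
  state <- "low"; t <- 0
  states <- "low"; times <- 0
  repeat {
    if (state == "low") {
      out_rates <- c(high = rates$k1, off = rates$k_off)
    } else {
      out_rates <- c(low = rates$k_minus1, crossed = rates$k2,
                     off = rates$k_off_prime)
    }
    total <- sum(out_rates)
    if (total == 0)
      stop("no exit rates from transient state '", state,
           "': configuration error")
    t <- t + stats::rexp(1, total)
    if (t > t_max) break
    state <- sample(names(out_rates), 1, prob = out_rates / total)
    states <- c(states, state); times <- c(times, t)
    if (state %in% c("off", "crossed")) break
  }
  structure(data.frame(state = states, entry_time = times), t_max = t_max)
}

#' Simulate a first-passage dataset across concentrations
#'
#' One record per molecule per concentration: the first time the molecule
#' enters the threshold-crossed state, or a censoring flag when it
#' dissociates or the observation window ends first. A single global seed is
#' expanded into independent per-molecule substreams, so each molecule's
#' path is reproducible.
#'
#' @param rates_by_conc Named list of [kinetic_rates()] objects; names are
#'   concentrations in nM.
#' @param n_molecules Molecules per concentration.
#' @param t_max Observation window, s.
#' @param seed Integer seed.
#' @return Data frame of class `first_passage` with columns `molecule_id`,
#'   `conc_nM`, `t_cross_s` (NA when censored), `status`
#'   (`crossed` / `dissociated` / `censored`), `t_max_s`.
#' @export
simulate_first_passage <- function(rates_by_conc, n_molecules, t_max,
                                   seed = NULL) {
  stopifnot(is.list(rates_by_conc), !is.null(names(rates_by_conc)))
  if (n_molecules == 0) {
    out <- data.frame(molecule_id = character(), conc_nM = numeric(),
                      t_cross_s = numeric(), status = character(),
                      t_max_s = numeric())
    class(out) <- c("first_passage", class(out))
    return(out)
  }
  if (!is.null(seed)) set.seed(seed)
  n_total <- n_molecules * length(rates_by_conc)
  substreams <- sample.int(.Machine$integer.max - 1L, n_total)
  rows <- vector("list", n_total)
  idx <- 0L
  for (cn in names(rates_by_conc)) {
    for (m in seq_len(n_molecules)) {
      idx <- idx + 1L
      path <- simulate_state_path(rates_by_conc[[cn]], t_max,
                                  seed = substreams[idx])
      final <- path$state[nrow(path)]
      status <- switch(final, crossed = "crossed", off = "dissociated",
                       "censored")
      rows[[idx]] <- data.frame(
        molecule_id = sprintf("c%s_m%03d", cn, m),
        conc_nM = as.numeric(cn),
        t_cross_s = if (status == "crossed")
          path$entry_time[nrow(path)] else NA_real_,
        status = status, t_max_s = t_max)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("first_passage", class(out))
  out
}

#' Empirical fraction of molecules past the threshold vs. time
#'
#' For each concentration, the fraction of all molecules whose first-passage
#' time is `<= t`, evaluated on a common time grid. Dissociated and censored
#' molecules stay in the denominator and never contribute a crossing, which
#' is how the analytic [p_gt25()] treats them.
#'
#' @param fp A `first_passage` data frame.
#' @param t_grid Evaluation times, s.
#' @return Data frame with columns `conc_nM`, `time_s`, `fraction`, `n`.
#' @export
crossing_fraction <- function(fp, t_grid) {
  stopifnot(inherits(fp, "first_passage") || all(
    c("conc_nM", "t_cross_s", "status") %in% names(fp)))
  do.call(rbind, lapply(split(fp, fp$conc_nM), function(d) {
    tc <- d$t_cross_s[d$status == "crossed"]
    data.frame(conc_nM = d$conc_nM[1], time_s = t_grid,
               fraction = vapply(t_grid, function(t) sum(tc <= t), 0) / nrow(d),
               n = nrow(d), row.names = NULL)
  }))
}

#' Sample first-passage times from the fitted analytic model
#'
#' Draws per-molecule crossing times directly from the closed-form
#' first-passage distribution: a molecule crosses within the window with
#' probability `P(t_max)` and, conditionally, its time is drawn by inverse
#' transform sampling from `P(t) / P(t_max)`. Used for parametric
#' bootstrap resampling.
#'
#' @param params [fit_params()] object.
#' @param k Switching rate at this concentration, 1/s.
#' @param n Number of molecules.
#' @param t_max Observation window, s.
#' @param conc_nM Concentration label for the output.
#' @return A `first_passage` data frame (non-crossers labelled `censored`).
#' @export
sample_first_passage_model <- function(params, k, n, t_max, conc_nM = NA) {
  grid <- seq(0, t_max, length.out = 512L)
  cdf <- p_gt25(grid, params, k)
  p_end <- cdf[length(cdf)]
  crossed <- stats::runif(n) < p_end
  t_cross <- rep(NA_real_, n)
  if (any(crossed) && p_end > 0) {
    u <- stats::runif(sum(crossed)) * p_end
    t_cross[crossed] <- stats::approx(cdf, grid, xout = u, ties = "ordered",
                                      rule = 2)$y
  }
  out <- data.frame(
    molecule_id = sprintf("c%s_b%03d", conc_nM, seq_len(n)),
    conc_nM = as.numeric(conc_nM), t_cross_s = t_cross,
    status = ifelse(crossed, "crossed", "censored"), t_max_s = t_max)
  class(out) <- c("first_passage", class(out))
  out
}
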