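#' Detect discrete steps in a trace by iterative chi-square step fitting
#'
#' Piecewise-constant step fitting in the style of Kerssemakers et al.:
#' steps are placed one at a time at the location that maximally reduces
#' the residual sum of squares of a plateau fit, giving a sequence of
#' candidate fits with 1, 2, ... steps. The number of steps is chosen by a
#' Schwarz-type penalized chi-square, `n log(chi2(m) / n) + penalty *
#' log(n) * m`, which stays at zero steps on featureless noise while
#' following genuine staircases. The selected fit is then scored by the
#' ratio of the chi-square of a "counter-fit" (steps forced to the plateau
#' midpoints of the fit, the worst locations) to its own chi-square, and
#' accepted only if the ratio exceeds `quality_threshold`: a genuine
#' staircase gives a large ratio, noise a ratio near 1.
#'
#' @param trace An `unwind_trace` (uniform grid, at least 3 samples).
#' @param max_steps Maximum number of steps to place. Default
#'   `min(500, floor(n / 4))`.
#' @param penalty Penalty per step in units of `log(n)` (default 2: one
#'   location and one level per step).
#' @param quality_threshold Minimum counter-fit / step-fit chi-square
#'   ratio for accepting the selected fit (default 1.2).
#' @return Data frame with columns `time_s` (step midpoint), `size_bp`,
#'   `plateau_before`, `plateau_after`, `fit_quality` (the accepted ratio,
#'   identical for all steps of one trace), sorted by time. Zero rows when
#'   no steps are accepted.
#' @export
detect_steps <- function(trace, max_steps = NULL, penalty = 2,
                         quality_threshold = 1.2) {
  y <- trace$position
  tt <- trace$time_s
  n <- length(y)
  if (n < 3) stop("trace must contain at least 3 samples")
  if (is.null(max_steps)) max_steps <- min(500L, max(1L, n %/% 4L))

  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  seg_sse <- function(i, j) {  # inclusive 1-based bounds, vectorized
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s^2 / (j - i + 1)
  }
  # best split of plateau [i, j]: boundary after index k, k in i..j-1
  best_split <- function(i, j) {
    if (j - i < 1) return(c(NA, 0))
    k <- i:(j - 1)
    sseL <- seg_sse(rep.int(i, length(k)), k)
    sseR <- seg_sse(k + 1, rep.int(j, length(k)))
    tot <- sseL + sseR
    m <- which.min(tot)
    c(k[m], seg_sse(i, j) - tot[m])
  }
  sse_of_breaks <- function(breaks) {  # breaks: sorted boundary indices
    lo <- c(1, breaks + 1)
    hi <- c(breaks, n)
    sum(seg_sse(lo, hi))
  }

  # greedy placement
  bounds <- integer(0)                       # current breakpoints
  plat_lo <- 1L; plat_hi <- n                # parallel plateau bounds
  splits <- list(best_split(1L, n))          # cached best split per plateau
  fits <- list()                             # breakpoints after m steps
  chi_fit <- numeric(0)
  sse_floor <- 1e-12 * (seg_sse(1, n) + 1)
  for (m in seq_len(max_steps)) {
    gains <- vapply(splits, `[`, numeric(1), 2L)
    pick <- which.max(gains)
    if (!is.finite(gains[pick]) || gains[pick] <= sse_floor) break
    kb <- splits[[pick]][1]
    lo <- plat_lo[pick]; hi <- plat_hi[pick]
    # replace plateau `pick` with its two children
    plat_lo <- append(plat_lo[-pick], c(lo, kb + 1L))
    plat_hi <- append(plat_hi[-pick], c(kb, hi))
    splits <- append(splits[-pick],
                     list(best_split(lo, kb), best_split(kb + 1L, hi)))
    bounds <- sort(c(bounds, kb))
    fits[[m]] <- bounds
    chi_fit[m] <- sse_of_breaks(bounds)
  }
  if (length(fits) == 0)
    return(.empty_steps())

  # model-size selection: penalized chi-square over 0..m steps
  bic <- n * log(pmax(c(seg_sse(1, n), chi_fit), sse_floor) / n) +
    penalty * log(n) * (0:length(chi_fit))
  best <- which.min(bic) - 1L
  if (best == 0L)
    return(.empty_steps())

  # acceptance gate: counter-fit (steps at plateau midpoints) vs. fit
  b <- fits[[best]]
  lo <- c(1, b + 1); hi <- c(b, n)
  cb <- unique(pmin((lo + hi) %/% 2L, n - 1L))
  cb <- cb[cb >= 1L]
  chi_c <- sse_of_breaks(sort(cb))
  quality <- chi_c / max(chi_fit[best], sse_floor)
  if (quality < quality_threshold)
    return(.empty_steps())

  means <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  data.frame(
    time_s = (tt[b] + tt[b + 1]) / 2,
    size_bp = diff(means),
    plateau_before = means[-length(means)],
    plateau_after = means[-1],
    fit_quality = quality)
}

.empty_steps <- function() {
  data.frame(time_s = numeric(), size_bp = numeric(),
             plateau_before = numeric(), plateau_after = numeric(),
             fit_quality = numeric())
}

#' Classify detected steps by size
#'
#' Steps are labelled `forward` (size > 0), `backstep` (size in `[-2, 0)`
#' bp) or `backslide` (size < -2 bp). Adjacent back/forward pairs of about
#' 5 bp (transient release/recapture of ssDNA from a secondary binding
#' site) are flagged.
#'
#' @param steps A step data frame from [detect_steps()].
#' @param pair_size Nominal release/recapture size, bp (default 5).
#' @param pair_tol Tolerance on the pair size, bp (default 1).
#' @return List with `fractions` (named vector over
#'   forward/backstep/backslide, summing to 1), `steps` (input with a
#'   `class` column and a logical `release_recapture` flag), and `n`.
#' @export
classify_steps <- function(steps, pair_size = 5, pair_tol = 1) {
  if (nrow(steps) == 0)
    return(list(fractions = c(forward = NA_real_, backstep = NA_real_,
                              backslide = NA_real_),
                steps = steps, n = 0L))
  cls <- ifelse(steps$size_bp > 0, "forward",
                ifelse(steps$size_bp >= -2, "backstep", "backslide"))
  rr <- logical(nrow(steps))
  if (nrow(steps) > 1) {
    s <- steps$size_bp
    is_pair <- abs(s[-length(s)] + pair_size) <= pair_tol &
      abs(s[-1] - pair_size) <= pair_tol
    rr[which(is_pair)] <- TRUE
    rr[which(is_pair) + 1L] <- TRUE
  }
  steps$class <- cls
  steps$release_recapture <- rr
  frac <- c(forward = mean(cls == "forward"),
            backstep = mean(cls == "backstep"),
            backslide = mean(cls == "backslide"))
  list(fractions = frac, steps = steps, n = nrow(steps))
}
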