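---
title: "Analyzing single-molecule hairpin unwinding and the processivity switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing single-molecule hairpin unwinding and the processivity switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unwindr)
```

## The experiment this package models

In a dual-trap optical tweezers assay, a DNA hairpin (an 89 bp stem capped
by a dT tetraloop, flanked by long dsDNA handles) is held at constant force
below its mechanical unzipping point. A single XPD helicase loaded on a
10 nt ssDNA site unwinds the stem; every broken base pair releases two
nucleotides of ssDNA, so unwinding shows up as an increase in the tether's
end-to-end extension. XPD works in repeated *bursts*: forward unwinding
followed by rezipping to the hairpin base, typically a handful of bursts
before the enzyme dissociates. The single-stranded-DNA binding protein
RPA2 changes the character of these bursts: with more RPA2 in solution, a
larger fraction of bursts passes a ~25 bp threshold and often unwinds the
entire stem.

`unwindr` implements the full analysis chain for such recordings —
polymer-mechanics conversion of extension to base pairs, step and
melting-event detection, burst segmentation and statistics, and a
four-state kinetic model of the processivity switch — together with a
synthetic-trace generator so that every stage can be tested against known
ground truth.

## Polymer mechanics

Tether extension is modeled as a sum of worm-like chain contributions,
`x(F) = N_ds xi_ds(F) + N_ss xi_ss(F)`, with the extensible Marko–Siggia
interpolation per monomer:

`xi(F) = h (1 - 1/2 sqrt(kT / (F P)) + F / S)`.

Defaults: dsDNA `P = 50` nm, `h = 0.34` nm/bp; ssDNA `P = 1.0` nm,
`h = 0.59` nm/nt; both `S = 1000` pN; `kT = 4.11` pN nm (298 K; the assay
temperature is configurable but unwinding experiments are run at room
temperature). The literature offers several interpolations (Marko–Siggia,
Odijk, higher-order fits) that differ by a few percent in `xi_ss` at these
forces; we use the Marko–Siggia form with an additive enthalpic term, the
standard choice in trap work at 5–15 pN. Base pairs unwound follow from
`n(t) = Delta x(t) / (2 xi_ss(F))`; the output is deliberately real-valued —
discretization is the step detector's job, not the unit conversion's.

```{r wlc}
monomer_extension(12, wlc_ssdna())   # nm per nt at 12 pN
bp_unwound(77.25, 12)                # a 77 nm extension gain at 12 pN
```

## The four-state kinetic model

The central model treats XPD as switching between a low- and a
high-processivity state, with dissociation allowed from the low state and
threshold crossing from the high state:

* `low -> high` at `k1` (the only RPA2-dependent rate),
* `high -> low` at `k_minus1`,
* `high -> crossed` at `k2` (the >25 bp scoring event),
* `low -> off` at `k_off` (and optionally `high -> off` at `k_off_prime`,
  zero by default).

Starting from `P_low(0) = 1`, the probability of having crossed by time
`t` has the closed form implemented in `p_gt25()`, with decay constants
`lambda_±` given by the trace and determinant of the 2x2 generator
restricted to the transient states. Two numerical points deserve note:

* at `lambda_+ = lambda_-` the generic expression is indeterminate; the
  implementation switches to the analytic repeated-root limit
  `k D (1 - e^(-lambda t)(1 + lambda t)) / lambda^2` when the eigenvalue
  gap falls below `1e-9 lambda_+`;
* `(1 - e^(-lambda t)) / lambda` is evaluated through `expm1` and clamped
  to its `t` limit as `lambda -> 0`, so leak-free or rate-degenerate
  parameter sets remain finite.

`solve_states()` integrates the same master equations with a stiff ODE
solver and is used in the test suite as an independent route: the two
agree to better than `1e-8` over 200 s for all tabulated parameter sets.

```{r kinetics}
r10 <- xpd_reference_rates_at(10)   # reference rates at 10 nM RPA2
p_gt25(7, r10)                      # crossing probability by 7 s
p_gt25_inf(r10)                     # asymptotic crossing fraction
```

## Global fitting of first-passage data

The data for the kinetic model are per-molecule first crossing times of
the 25 bp threshold, grouped by RPA2 concentration, with molecules that
dissociate or run out of observation window contributing censored
records. Fitting works on the empirical fraction-crossed-vs-time curves:
the grouped parameters `A, B, C, D` are shared across concentrations, one
switching rate `k` is fitted per concentration, and by default
`k_off_prime = 0` (so `A = D`), mirroring the observation that a freely
fitted high-state dissociation rate is statistically indistinguishable
from zero.

Decisions that were genuinely open:

* **Loss.** The reference analysis does not state its objective. We
  minimize weighted least squares between empirical and analytic curves,
  each point weighted by inverse binomial variance `p(1-p)/n` with
  `p(1-p)` floored at `1/(4n)` to keep endpoints finite. Equal-weight and
  Anscombe-adjusted variants were compared during development and move
  the estimates negligibly relative to their sampling spread.
* **Optimizer.** Box-constrained quasi-Newton (`nlminb`) in rate space
  (`k2, k_off, k_minus1, k_j >= 0`), with a heuristic start plus a few
  log-normal multi-starts. Non-convergence raises a diagnostic error
  carrying the best point found.
* **Uncertainty.** Percentile CIs from a parametric bootstrap: synthetic
  molecules are redrawn from the fitted model (inverse-CDF sampling of
  the closed form) and refit. The default is 200 resamples; the test
  suite uses 40 to stay fast.
* **Identifiability.** The curve family is sloppy: `k1` and `k2` trade
  off along nearly identical curves, so individual estimates at moderate
  sample sizes scatter widely while the curves themselves are pinned
  down. This is visible in the wide bootstrap intervals and mirrors the
  wide printed confidence intervals of the reference parameter table;
  consistency was verified at large sample sizes during development.

The derived models reuse the same machinery: the fraction of
high-processivity bursts at a concentration is `P(tau_low)` with
`tau_low = 7` s (the mean low-processivity burst duration), and the mean
burst duration is the `P(inf)`-weighted mixture of `tau_low` and
`tau_high`. The switching rate `k1` is regressed on concentration with
inverse-variance weights; the slope is the effective second-order rate
constant of the protein–helicase interaction. Weighting matters: the
tabulated `k1` values span two orders of magnitude in precision, and an
unweighted fit is dominated by the highest concentration.

## The synthetic-trace generator

The generator is two-layered. A Gillespie path of the four-state scheme
drives the molecule's state; a stepping layer renders position vs. time:

* 1 bp forward steps at a position-dependent rate, targeting ~5 bp/s net
  velocity away from the stall and slower inside the GC-rich stall region
  (10–15 bp): 1.2 bp/s in the low state (long stalls), 3.5 bp/s in the
  high state;
* backsteps of 1 bp with per-event probability 0.19;
* mid-burst backslides of 3 bp with per-event probability 0.05, each
  followed by re-unwinding of the rezipped duplex; the rapid rezip that
  ends every burst is logged as one terminal backslide. A per-event
  backslide probability as large as the observed ~18% *fraction of
  detected steps* would give the walk negative drift, so the observed
  fraction is reproduced by the combination of rare mid-burst slides and
  terminal rezips rather than used directly as a generative probability;
* 5 nt release/recapture pairs (brief -5/+5 excursions) at low rate;
* burst apexes drawn in the stall region for low-state bursts and between
  26 and 89 bp for high-state bursts; the number of bursts per molecule
  is Gaussian with mean 5 and s.d. 1, matching the repetitive behavior of
  single molecules;
* transient melting events: rectangular openings of 5 bp arriving as a
  Poisson process of rate `k_on * c` (`k_on = 1.2e8` 1/M/s) with
  exponential ~20 ms lifetimes. (An inset of the reference data suggests
  ~8 bp for bare-hairpin events while the text reports 5–6 bp; the
  default is 5 bp and configurable.)
* iid Gaussian measurement noise, default 0.3 bp, at 89, 100, or 267 Hz.

Samples are instantaneous point evaluations of the underlying
piecewise-constant path. Real instruments average over the acquisition
interval (and the reference data were boxcar-filtered from 267 Hz); point
sampling is simpler and keeps step edges sharp, but it means a melting
event shorter than one sample period leaves *no* trace in the data. At
89 Hz about a quarter of 20 ms events are invisible in principle, which
depresses naive inter-event-rate estimates by the same factor; detection
validation therefore runs at the full 267 Hz bandwidth, where ~91% of
events touch a sample. Every simulated trace carries an injection log —
the true steps, melting events, and bursts — so detectors are scored
against ground truth rather than against themselves.

What the generator does *not* emulate: bead/trap Brownian dynamics and
force-feedback transients, sequence-dependent base-pairing energies (the
stall is phenomenological, not thermodynamic), drift, and instrument
artifacts. Passing tests therefore demonstrate correctness of the
analysis chain under the model's statistical assumptions, not robustness
to every pathology of real trap data.

## Step detection

Steps are found by iterative chi-square step placement in the style of
Kerssemakers et al.: each iteration adds the step that maximally reduces
the residual sum of squares of a piecewise-constant fit. Two details are
not specified by the cited method and were decided here:

* **Model size.** The number of steps minimizes a Schwarz-type penalized
  chi-square, `n log(chi2(m)/n) + penalty log(n) m` with `penalty = 2`
  (a location and a level per step). On featureless noise the penalty
  keeps the selection at zero steps.
* **Acceptance.** The selected fit must beat its *counter-fit* — the same
  number of steps forced to the plateau midpoints, i.e. the worst
  placements — by a chi-square ratio of at least 1.2 (configurable). A
  genuine staircase gives ratios well above 2; noise hovers near 1.
  During development the ratio alone proved insufficient as a stopping
  rule (greedy fits on pure noise beat midpoint counter-fits by a
  growing margin as steps accumulate), which is why selection is
  penalized and the ratio serves as a final gate.

Whether the reference analysis ran its detector on raw or smoothed data
is not stated; `detect_steps()` takes the trace as given, and the melt
detector documented next consumes its output.

## Melting events, classification, and alignment

During unwinding, protein-mediated melting appears as an adjacent step
pair: a forward step > 2 bp followed by a backward step > 2 bp within
five sample periods (56 ms at 89 Hz). Qualifying pairs become
`MeltEvent`s and leave the helicase step pool; ambiguous chains pair the
earliest qualifying forward step (first match). On bare-hairpin traces,
events are excursions above half the 4 bp amplitude criterion whose peak
exceeds 4 bp and whose duration is at most 0.2 s ("short-lived", ten
characteristic lifetimes; configurable). The on-rate estimate is
`k_on = 1 / (mean inter-event time x c)` with the exponential-rate
standard error `k_on / sqrt(n - 1)`.

Steps classify as forward (`> 0`), backstep (`[-2, 0)` bp), or backslide
(`< -2` bp), with -5/+5 adjacent pairs flagged as ssDNA release/recapture.
Event alignment shifts full-bandwidth segments so melting transitions
start at `(0, 0)` ("before" relative to `t_melt`, "after" relative to
`t_anneal`, both with the pre-melt position as spatial origin), and a
control variant aligns random time points paired 0.06 s apart. Aligned
clouds are summarized by a 2D Gaussian kernel density with Silverman
bandwidths per axis (unstated in the reference; Silverman is standard and
reproducible), normalized on a grid extended five bandwidths beyond the
data.

## Burst analysis

Segmentation encodes the manual criteria of the reference analysis as a
deterministic hysteresis rule on the melt-masked, robustly smoothed
trace: a burst opens after a rise of more than 5 bp above the preceding
valley and closes when the trace, having dropped more than 5 bp from its
maximum, returns within 2 bp of the pre-burst baseline (or at the valley
before the next rise). Trailing activity without a closing retraction is
flagged incomplete and excluded from duration statistics. Robust
smoothing is local quadratic regression over 51 samples with tricube
weights and bisquare reweighting — reproducing smooth trends exactly to
second order while suppressing single-sample spikes.

Processivity is the maximum (masked, smoothed) position within the
burst; the category threshold is 25 bp. The *unwinding portion* of a
burst follows three rules: high-processivity bursts run from start to
maximum; low-processivity bursts with stalls end at the last point above
10 bp; bursts never reaching 10 bp keep their first 75%. Velocity is the
least-squares slope over half-overlapping 50-sample windows, aggregated
into 2 bp position bins with s.e.m. Bursts ending in dissociation close
at the dissociation-driven rezip; how the reference handled bursts that
unwound past the loop is unstated, and such bursts carry the same
`complete` flag machinery rather than special-casing.

## Problem sizes and reproducibility

The test suite runs everything at desk scale, chosen as the smallest
sizes at which the statistical assertions are sharp: 1200–1500 Gillespie
molecules per concentration for the simulator/model equivalence check
(joint 99% binomial bands over the nine deciles of each concentration),
100 molecules per concentration for parameter recovery with a 40-resample
bootstrap, 5-replicate scaled-down bias checks, and 250–500 s of
simulated trace for detector validation. All simulations derive
per-molecule substreams from a single seed, so every reported number is
bit-reproducible, and `scripts/acceptance.R` regenerates the headline
quantities from scratch for any seed.

## Known limitations

* The curve-based least-squares fit is statistically less efficient than
  a per-molecule likelihood; with few molecules its individual rate
  estimates scatter widely even though the fitted curves are accurate.
* Point-sampled rendering under-represents sub-sample melting events at
  low bandwidths (see above).
* The stall phenomenology is parametric; the generator cannot predict
  how processivity would change with hairpin sequence.
* Burst segmentation assumes rezips return near the baseline; exotic
  behaviors (mid-hairpin strand switching without rezip) end up merged
  into one burst or flagged incomplete rather than resolved.
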