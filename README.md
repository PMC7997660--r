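# unwindr

Analysis of single-molecule optical-trap recordings of helicase-mediated
DNA hairpin unwinding, built around the kinetics of a *processivity
switch*: a helicase (the model system is *Ferroplasma acidarmanus* XPD)
that interconverts between a low- and a high-processivity state, with a
single-stranded-DNA binding protein (RPA2) shifting the balance toward
the processive state.

In the underlying assay an 89 bp DNA hairpin is held at constant force
between trapped beads; each base pair a helicase unwinds releases two
nucleotides of ssDNA and lengthens the tether. The enzyme unwinds in
repeated bursts, and the question the analysis answers is *why* some
bursts cross a ~25 bp threshold and others stall and rezip — and how the
protein concentration changes that fraction.

## What the package does

* **Polymer mechanics** — extensible worm-like chain (Marko–Siggia with
  enthalpic stretch) conversion between force, tether extension and base
  pairs unwound: `monomer_extension()`, `construct_extension()`,
  `bp_unwound()`, `extension_for_bp()`.
* **Synthetic traces** — a Gillespie simulator of the four-state kinetic
  scheme plus a stepping-level renderer (bursts, stalls, backsteps,
  backslides, transient melting events, Gaussian noise), every trace
  carrying a ground-truth injection log: `simulate_state_path()`,
  `simulate_first_passage()`, `simulate_trace()`,
  `simulate_bare_hairpin()`.
* **Event detection** — iterative chi-square (Kerssemakers-style) step
  fitting with penalized model-size selection and counter-fit
  acceptance; melting-event identification during unwinding (paired
  >2 bp up/down steps within 56 ms) and on bare hairpins (>4 bp
  short-lived excursions); on-rate estimation from inter-event times;
  event alignment and 2D kernel densities: `detect_steps()`,
  `detect_melt_events_during_unwinding()`, `detect_melt_events_bare()`,
  `estimate_kon()`, `classify_steps()`, `align_events()`,
  `event_density()`.
* **Burst analysis** — robust local-quadratic smoothing, burst
  segmentation with 5 bp hysteresis, processivity and the 25 bp
  low/high classification, unwinding-portion rules, velocity profiles,
  and bookkeeping summaries: `smooth_robust()`, `segment_bursts()`,
  `velocity_profile()`, `summarize_bursts()`.
* **Kinetics** — the four-state master equations and their closed-form
  first-passage solution

  `P(t) = k1 k2 / (λ− − λ+) · [ (1 − e^{−λ+ t})/λ+ − (1 − e^{−λ− t})/λ− ]`,

  `λ± = (k1 + k−1 + k2 + koff)/2 ± sqrt( ((k1 + k−1 + k2 + koff)/2)² − (k1 k2 + koff (k−1 + k2)) )`

  (shown for koff′ = 0), global fitting across concentrations with
  shared parameters and parametric-bootstrap CIs, and the weighted
  linear rate law k1([RPA2]): `p_gt25()`, `solve_states()`,
  `fit_global()`, `fit_k1_vs_conc()`, `burst_fraction_model()`,
  `burst_duration_model()`.

Traces, events, bursts and first-passage tables read and write as plain
TSV with commented metadata headers (`read_trace()`, `write_trace()`,
`read_result_table()`, ...), all thresholds live in a validated YAML
configuration (`default_config()`, `load_config()`), and a thin command
line tool wraps the pipeline (`inst/cli/unwind-tool.R`, subcommands
`simulate | detect | bursts | fpt | fit | report`).

## Worked example

```r
library(unwindr)

# simulate one molecule unwinding at 10 nM RPA2, 12 pN, 89 Hz
trace <- simulate_trace(xpd_reference_rates_at(10),
                        melting = melting_params(conc_nM = 10),
                        duration = 120, seed = 42)
trace
#> unwind_trace 'trace1': 10681 samples @ 89 Hz, 120 s, units bp, F = 12 pN, [RPA2] = 10 nM

segment_bursts(trace)[, c("t_start", "t_end", "processivity_bp", "category")]
#>   t_start t_end processivity_bp category
#> 1   0.124  12.3            13.3      low
#> 2  12.438  33.1            73.0     high
#> 3  33.225  45.9            40.2     high
#> 4  45.989  71.5            85.2     high
#> 5  71.618  93.2            80.2     high
#> 6  95.124 113.1            50.5     high
```

One low-processivity burst stalls near 13 bp and rezips; the others cross
the 25 bp threshold, as expected at 10 nM where the switch is engaged
about half the time.

```r
# first-passage kinetics across all five concentrations
ref   <- xpd_reference_rates()
rates <- setNames(lapply(ref$k1$conc_nM, xpd_reference_rates_at), ref$k1$conc_nM)
fp  <- simulate_first_passage(rates, n_molecules = 100, t_max = 200, seed = 1)
fit <- fit_global(fp, n_boot = 0, seed = 2)
fit
#> Global first-passage fit (5 concentrations)
#>   k2             0.1701 1/s
#>   k_off          0.0399 1/s
#>   ...
#>   k1_50          1.1184 1/s

# second-order rate law from the tabulated switching rates
fit_k1_vs_conc(ref$k1$k1, ref$k1$conc_nM, sigma = ref$k1$ci95)
#> linear rate law: slope 1.4e+07 +/- 3.4e+06 1/M/s, intercept 0.0195 +/- 0.0065 1/s
```

The global fit recovers the threshold-crossing rate `k2 = 0.17 s⁻¹`
(25 bp at ~4–5 bp/s) and a dissociation rate `k_off ≈ 0.04 s⁻¹` (bound
lifetime ≈ 25–27 s) from synthetic first-passage data, and the weighted
line through k1 vs. concentration gives the effective second-order rate
constant of the protein–helicase interaction, ~1.4×10⁷ M⁻¹s⁻¹ with a
basal switching rate of ~0.02 s⁻¹.

See `vignettes/unwinding-analysis.Rmd` for the model, the generator's
assumptions, and every numerical design decision.

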