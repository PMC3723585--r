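# cyclescope

Cell-cycle-resolved transcription rate inference from single-cell
fluorescent-reporter time series, with the simulation machinery to validate
every step against known ground truth.

Single-cell mRNA and protein levels are famously variable, and that
variability is usually attributed to stochastic transcriptional bursting.
But in budding yeast a large share of it can come from something far more
structured: transcription rates that differ between G1 and S/G2/M. Testing
that idea requires extracting an *instantaneous, per-cell transcription
rate* from reporter movies — and the machinery to do so reliably:

* **simulation** (`sim_config`, `simulate_cell`, `gen_*` generators,
  `simulate_chase`, `simulate_population_snapshot`, `make_spot_truth`,
  `render_fish_image`) — single-cell lineages with two-phase volume growth,
  mRNA birth–death under a time-varying transcription rate `A(t)`,
  fluorophore maturation, division partitioning, measurement noise;
  asynchronous-population count snapshots (Gillespie, compiled); chase
  traces; synthetic FISH images with ground truth;
* **inference** (`build_running_total`, `fit_smoothing_spline`,
  `infer_rates`, `select_beta`, `estimate_maturation`, `check_decay`) —
  running-total protein traces fit by a penalized cubic smoothing spline and
  inverted through the transcription–translation model
  `dP/dt = k_t M`, `dM/dt = A − γ_M M`, giving `M(t) = P′/k_t` and
  `A(t) = (P″ + γ_M P′)/k_t`; the smoothing weight is calibrated by
  simulation;
* **cell-cycle synchronization** (`segment_cycles`, `rescale_progression`,
  `cycle_profile`, `growth_rate_series`) — division-to-division segments
  rescaled so division sits at progression 0/1 and budding at the
  population-average point, binned with bootstrap errors;
* **event detection** (`binarize`, `steptest_delays`, `delays_by_phase`,
  `coactivation`) — ON/OFF calling above a robust background, the 5-step
  step-test procedure for response delays relative to TF nuclear
  localization, and 2×2 co-activation statistics (chi-square, phi) between
  homologous loci;
* **snapshot distribution models** (`model_spec`, `predict_model`, `fit_f`,
  `fit_negative_binomial`, `compare_models`) — cell-cycle-phase-dependent
  Poisson-mixture models in which transcription changes `f`-fold at the
  G1→S/G2/M transition (sharply, within a randomized 40-min window, or by
  gene-dosage doubling), fit to phase-stratified mRNA counts;
* **FISH quantification** (`calibrate_threshold`, `detect_spots`,
  `count_mrna`, `classify_nascent`, `classify_phase`, `quantify_image`) —
  threshold calibration against negative controls, local-maxima spot
  detection, mode-normalized multi-mRNA counting, nascent-site
  classification, and bud-size-based phase labels.

The analysis workflow lives in `analysis/01_simulate.R` …
`analysis/08_distribution_models.R`: numbered, self-contained drivers that
exercise the package end to end and write their tables under `results/`.

## Worked example

Simulate a noisy lineage with a square pulse of transcription, recover the
rate, and time the activation:

```r
library(cyclescope)

cfg <- sim_config()                        # 5-min sampling, t_cyc = 100 min,
                                           # mu = 10, sigma^2 = 2.4e4, CFP-like k_m
gen <- gen_square_pulse(100, 200, cfg$gamma_M * cfg$mu)
set.seed(1)
tr  <- simulate_cell(cfg, gen, n_cycles = 3)

rates <- infer_from_trace(list(times = tr$running_total$time,
                               P = tr$running_total$P_obs),
                          gamma_M = cfg$gamma_M, k_t = cfg$k_t)
ev <- binarize(rates, threshold = 0.5 * cfg$gamma_M * cfg$mu)
ev$activation_times
#> [1] 115.2012
```

The pulse truly starts at t = 100 min; the inferred activation at ~115 min
shows the systematic observation delay caused by fluorophore maturation
(half-life 10 min) plus spline smoothing. Across 1000 such traces the mean
delay is ~11.9 min with a mean absolute deviation of ~2.2 min
(`analysis/03_timing_accuracy.R`).

Fit the phase-dependent fold change to a simulated snapshot:

```r
m  <- model_spec(k_G1 = 0.2, f = 2)        # 2-fold rate change at budding
pc <- simulate_population_snapshot(m, 2000, seed = 11)
fit_f(pc)$f_hat
#> [1] 2.050268
```

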