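---
title: "Inferring cell-cycle-resolved transcription from single-cell reporter data"
author: "cyclescope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cell-cycle-resolved transcription from single-cell reporter data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclescope)
```

## The problem

Fluorescent-reporter time series from growing yeast cells confound
transcription with everything downstream of it: translation, fluorophore
maturation, growth dilution, and the partitioning of molecules at cell
division. cyclescope implements the computational chain that untangles
these: a forward simulator of single-cell lineages, a smoothing-spline
inversion that recovers the instantaneous transcription rate from total
fluorescence, in-silico cell-cycle synchronization, ON/OFF event detection,
phase-dependent stochastic models for snapshot mRNA counts, and spot
counting for single-molecule FISH images. Every stage can be validated
against simulated ground truth at desk scale.

## The transcription–translation model and its inversion

The core model is linear:

$$\frac{dM}{dt} = A(t) - \gamma_M M, \qquad \frac{dP}{dt} = k_t M,$$

where $M(t)$ is mRNA per cell, $A(t)$ the instantaneous transcription rate,
$\gamma_M$ the mRNA degradation rate and $k_t$ the translation rate. $P(t)$
is the *running total* of stable reporter protein: the mother compartment's
integrated fluorescence plus, after each division, the separated progeny's
totals. Summing over the lineage removes division and dilution from the
bookkeeping — for a stable reporter $P(t)$ only ever grows. Inverting the
pair gives

$$M(t) = P'(t)/k_t, \qquad A(t) = \bigl(P''(t) + \gamma_M P'(t)\bigr)/k_t.$$

Derivatives of noisy data are ill-posed, so $P(t)$ is first fit by a cubic
smoothing spline (`fit_smoothing_spline()`, built on `stats::smooth.spline`)
minimizing

$$\sum_i \bigl(P_i - f(t_i)\bigr)^2 + \beta \int f''(t)^2\,dt,$$

with time in minutes and fluorescence in raw AU. Because both terms scale
with the square of the fluorescence units, the fit is equivariant under
intensity rescaling (`infer_rates` applied to $cP$ gives exactly $cM$, $cA$).

$k_t$ is unidentifiable from fluorescence alone and defaults to 1, so $M$
and $A$ are reported in arbitrary units unless an absolute calibration is
supplied. Translation is treated as cell-cycle independent throughout.
Derivatives within two samples of a trace boundary are flagged
low-confidence and excluded from event detection.

## Choosing the smoothing parameter

$\beta$ trades bias against variance, and its numerical value depends on
the penalty convention, so it is fixed by simulation rather than imported:
`select_beta()` simulates noisy, asynchronous traces whose generator is
known, re-infers $A(t)$ across a log grid of $\beta$, and scores the RMS
residual against the truth (`analysis/02_beta_calibration.R`). At the
canonical study conditions (100 traces per parameter set; expression levels
$\mu = 10$ and $30$, cycle lengths 100 and 70 min) the residual curve has an
interior minimum at $\beta = 1000$, which is the package default
(`default_beta()`). Noiseless traces show no interior minimum — less
smoothing is then always better — which is the qualitative signature that
the optimum reflects measurement noise rather than the model. Each
parameter set's random stream is derived from its parameter values, so the
calibration is invariant to the order of the sets.

## The simulator and what it emulates

`simulate_cell()` generates one tracked mother lineage under the canonical
study conditions (defaults of `sim_config()`):

* 5-min sampling; 100-min cycle; budding at 27% of cycle progression;
* two-phase exponential volume growth, twice as fast after budding as
  before, normalized so the compartment doubles per cycle;
* mRNA birth–death with a piecewise-constant generator $A(t)$
  (`gen_constant`, `gen_step`, `gen_square_pulse`, `gen_cycle_modulated`
  with a 2:1 peak:trough cycle modulation by default);
* translation into an immature protein pool at $k_t M$ and first-order
  maturation at $k_m$ (CFP-like half-life 10 min by default);
* additive white Gaussian noise of variance $\sigma^2 = 2.4\times10^4$
  AU$^2$ on total fluorescence;
* division partitioning by volume fraction — deterministic in `ode` mode,
  binomial in `ssa` (Gillespie) mode.

In `ode` mode the linear cascade is integrated exactly by cached
matrix-exponential steps between generator change points, so the
deterministic path carries no discretization error. The protein scale is
set by $k_t = 20$ AU/(mRNA·min): at $\mu = 10$ this accumulates
$\sim 2\times10^4$ AU of integrated fluorescence per cycle, the scale of
experimental traces, which fixes the signal-to-noise ratio implied by
$\sigma^2$.

Two simplifications matter when interpreting results. Daughters inherit
molecular content at division and that content continues to decay,
translate and mature, but daughters do not transcribe — the lineage running
total is therefore governed by the mother's $A(t)$ alone, which is exactly
the situation the running-total construction assumes. And the measurement
noise is white, whereas real integrated-fluorescence noise has structure at
high frequency; the calibrated $\beta$ would shift somewhat under colored
noise. Passing tests therefore certify the inference chain against this
generative model, not against segmentation errors, focus drift, or other
features of real microscopy.

`simulate_chase()` models the translation-inhibition (cycloheximide) assay:
after inhibition the immature pool converts at $k_m$ while both pools decay
at $\gamma_P$ (0 for stable reporters), giving the closed form
$F(t) = e^{-\gamma_P t}\bigl(F_0 + I_0(1 - e^{-k_m t})\bigr)$ that
`estimate_maturation()` fits back by nonlinear least squares. Fits whose
immature-pool amplitude is below three residual standard deviations are
flagged rather than reported — a flat trace carries no information about
$k_m$.

## Timing accuracy of event calls

Because maturation is present in cells but deliberately absent from the
inversion, inferred activations lag the truth. The timing study
(`analysis/03_timing_accuracy.R`, also the acceptance script) simulates
1000 noisy square-pulse traces, infers $A(t)$, and calls activation at 50%
of the population steady-state rate. The observed delay distribution has a
mean near 12 min — close to the 10-min maturation half-life plus a
smoothing contribution — with a mean absolute deviation near 2 min. Event
detection (`binarize()`) removes ON runs shorter than two samples and
places crossings by linear interpolation; the detection floor defaults to
three median absolute deviations of $A(t)$ over known-OFF reference
periods.

## Cell-cycle synchronization and profiles

`segment_cycles()` cuts a trace at divisions; complete cycles contain
exactly one budding event. `rescale_progression()` maps each complete cycle
with the two-piece linear map $[t_{div}, t_{bud}] \to [0, b]$,
$[t_{bud}, t_{div}'] \to [b, 1]$, where $b$ is the population-average
pre-bud fraction, so division sits at 0 and 1 and every bud at $b$ exactly
(at 5-min sampling the bud instant generally falls between samples; the map
is exact, the sampled points straddle the kink). `cycle_profile()` bins by
progression (20 equal bins by default), averages per-cycle bin means, and
reports bootstrap SEMs obtained by resampling whole cycles — never
individual samples, which would break the within-cycle correlation — plus
the across-cycle SD. A `rescale = FALSE` variant bins raw time from budding
instead, to show trends survive without time rescaling.

Profiled on ground-truth rates, a 2:1 cycle-modulated population recovers a
post-/pre-bud ratio of 2.00; profiled on *inferred* rates the same data
yield a gradual rise and a smaller apparent ratio, because smoothing and
maturation spread the sharp transition over ~30 min. This is a property of
the measurement chain worth keeping in mind when reading rate profiles.
Volume growth rates come from per-cycle splines (volume is discontinuous at
division, so each stretch is fit separately).

## Step-test response delays

`steptest_delays()` implements the five-step threshold procedure for
timing gene activation against TF nuclear localization after a step input:
(1) the transcription threshold is 50% of the population steady-state rate;
(2) each cell's localization level is read 15 min (`tau_obs`, the
observation lag) before its transcription crossing; (3) the values are
pooled; (4) the effective localization threshold is the pool's 5th
percentile; (5) each cell's localization time is its first crossing of that
threshold. The response delay is the difference. Cells that never cross are
censored, reported but excluded from delay statistics. `delays_by_phase()`
compares pre- vs post-budding delay distributions with a two-sample K-S
test; with a simulated 10-min extra G1 delay at $n = 120$ the difference is
detected at $p < 10^{-4}$.

## Co-activation of homologous loci

`coactivation()` scores each S/G2/M period by whether each locus turned ON,
forms the 2×2 table, and reports Pearson's chi-square without continuity
correction plus the phi coefficient as the correlation measure (the natural
correlation for binary outcomes; an alternative reading of the reported
correlation as Pearson on a continuous summary is possible, so phi is
exposed explicitly). A shared-trigger generative model with per-locus
failures — $\phi = r(1-q)/(1-qr)$ — tuned to $\phi = 0.42$ is recovered
within 0.05 at 1000 periods, and under independence the chi-square p-values
are uniform.

## Phase-dependent snapshot models

`model_spec()` describes transcription at rate $k_{G1}$ before the
G1→S/G2/M transition and $f k_{G1}$ after, with three options: a sharp
transition at budding, a transition time uniform on a 40-min window after
budding, and gene-dosage doubling at a replication point inside S
($f = 2$ at budding is the pure dosage expectation; basal expression is the
$f \to \infty$ limit, specified directly as $k_{G1} = 0$ with an explicit
S/G2/M rate). The asynchronous age density is
$p(a) \propto 2^{-a/t_{cyc}}$ on $[0, t_{cyc}]$ with symmetric binomial
division.

Because the model is linear with Poisson noise and binomial thinning, the
count distribution at the cyclic steady state is exactly Poisson at every
age, and the snapshot law is a Poisson mixture over age (and over the
transition time for the randomized variant). `predict_model()` evaluates
this analytically — the newborn mean solves the cyclic consistency
$m_0 = \mathbb{E}_\tau[m(T\,|\,\tau)]/\,(2 - e^{-\gamma_M T})$, using the
population-average newborn mean for the randomized variant — and the same
law is estimated by the Gillespie engine (`simulate_population_snapshot()`,
compiled code) as an independent oracle; per-phase means agree within Monte
Carlo error for $f \in \{1, 2, 10\}$ at $n = 20{,}000$ cells. Phases map
ages to G1 (pre-bud) and three equal-duration S/G2/M thirds; note that the
experimental proxy, ranked bud size, produces equal-*count* bins, which
agree with duration thirds only approximately (~90%) under the non-uniform
age density.

`fit_f()` maximizes the Poisson-mixture likelihood over $(k_{G1}, f)$ — a
log grid in $f$ with golden-section refinement, profiling $k_{G1}$ at each
$f$ — and reports a likelihood-ratio confidence interval; estimates that
keep improving at the top of the grid are reported as censored ("$f >$
bound"), the natural reporting for basal data. Median relative recovery
error is under 25% for $f \in \{2, 5, 10\}$ at 2000 cells.
`fit_negative_binomial()` gives the standard bursting moment estimators
$b = \mathrm{var}/\mathrm{mean} - 1$, $a = \mathrm{mean}/b$ (MLE refinement
optional): aggregate distributions from these phase-dependent models fit a
negative binomial well even though the generative process has no intrinsic
bursting, which is precisely why aggregate NB fits are weak evidence about
mechanism.

## FISH spot quantification

`detect_spots()` follows the region-based procedure: pixels above a
calibrated threshold (over the image median background), local maxima with
at least three above-threshold pixels in their 3×3 neighbourhood (a
diffraction-limited spot lights several contiguous pixels; single-pixel
noise excursions do not), maxima within 5 px merged into the brighter one
(the PSF halo width at the default $\sigma = 1.5$ px), and intensities
integrated over a 7×7 window. `calibrate_threshold()` picks the smallest
candidate threshold whose per-cell false-positive rate on blank negative
controls is below 5%. The single-mRNA intensity is the mode of the
spot-intensity histogram (kernel density peak, refined on the singles
cluster); spots at least 2-fold brighter count as
$\mathrm{round}(I/\mathrm{mode})$ overlapping mRNAs; spots above 4× the
mode *and* inside the nuclear mask are nascent transcription sites
(included in per-cell counts by default, excludable). `classify_phase()`
ranks budded cells by bud size into equal-count thirds, with unbudded cells
as G1 and remainders assigned to earlier bins.

One structural limitation follows directly from the counting rule: a
synthetic doublet's integrated intensity is exactly twice a single's, so
its measured intensity is centred on the 2-fold decision boundary and about
half of all doublets are undercounted by one, at any noise level. With 15%
multi-mRNA spots the exact-per-cell-count match rate is bounded near
88–93%; with well-separated singles (plus nascent sites) it is ~100%
(`analysis/07_fish_quantification.R` reports both). The calibrated
false-positive criterion (<5%) is met independently of this.

## Numerical choices and degenerate inputs

Tie-breaks and edge rules are deliberate: debouncing removes ON runs
shorter than 2 samples; `classify_phase` breaks bud-size ties by stable
input order and gives remainders to earlier bins; `check_decay` falls back
to a log-linear fit when the exponential fit's gradient is singular
(constant input) and flags rates inconsistent with the expected
$\gamma_M$ beyond 10%; decay checks against $\gamma_M$ wait four maturation
half-lives after shut-off so the maturation transient has cleared;
all-zero count tables and never-activating cells are flagged or censored,
never imputed. All randomness flows through explicit seeds; pipeline stages
derive their streams from a hash of the global seed and the stage name, so
toggling one stage never shifts another's draws.

## Problem sizes

The validation suite uses 1000 traces for the timing study, 100 traces per
parameter set for the $\beta$ calibration, ~200 complete cycles for
profiles, 20,000 Gillespie cells for the oracle-equivalence check, 50
replicates of 2000 cells for fold-change recovery, 500 chase traces for
maturation recovery, 100 synthetic cells across five images for FISH
accuracy, and 200 replicates for chi-square calibration. These sizes give
Monte-Carlo errors comfortably below the tolerances being checked.
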