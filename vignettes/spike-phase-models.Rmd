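---
title: "Modeling refractory and rhythmic constraints on spike timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling refractory and rhythmic constraints on spike timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikephase)
```

## The problem

A neuron's probability of firing in any given millisecond is shaped by
processes on two very different timescales. Immediately after an action
potential, afterhyperpolarization currents suppress firing for a few
milliseconds (the refractory period). On the scale of tens to hundreds of
milliseconds, rhythmic synaptic currents — visible in the local field
potential (LFP) as oscillations such as hippocampal theta (4–12 Hz) or low
gamma (35–55 Hz) — can bias spikes toward particular oscillation phases.
The two effects are confounded in naive analyses: a model with enough
spike-history flexibility can mimic rhythmicity, and a phase-only model
quietly absorbs the mean firing rate. This package separates them by
building each constraint into its own predictor, combining the predictors
in a minimal logistic model, and letting held-out predictive performance
arbitrate.

## Data model

A `TrialSet` holds aligned per-trial series on a 1 ms grid: a binary spike
matrix, and optional LFP and instantaneous-phase matrices. The default
trial is 1,500 samples at 1 kHz whose first 250 ms are *history-only*:
those samples feed lagged regressors but are never prediction targets, so
every target sample has a fully observed history and no event-onset
transient contaminates the evaluation. Trials are modeled as independent:
history never crosses trial boundaries, and each trial's LFP trace is
filtered on its own.

## The five models

**SH and LH.** Logistic regressions of the spike indicator on its own
previous 3 ms (SH) or 250 ms (LH), one coefficient per millisecond of lag.
Both minimize the normalized negative log likelihood (NNLL, natural log,
mean per sample). The LH model's 251 coefficients make it high-variance, so
its objective adds an L2 penalty `lambda * sum(beta^2)` with
`lambda = 1` by default and the intercept excluded from the penalty. Two
conventions deserve attention:

- *Penalty scale.* The penalty is added to the **normalized** NNLL. At the
  default `lambda = 1` this is strong regularization: on ~30,000 training
  samples it shrinks the LH lag coefficients to near zero, and the LH model
  behaves close to an intercept-only model. Software that penalizes the
  **summed** likelihood at unit strength corresponds to a normalized
  `lambda` of about `1/(2n)` — orders of magnitude weaker. We implement the
  normalized-objective definition literally because that is the stated
  model; any other effective strength can be obtained by passing a
  different `lambda` to `fitHistoryGLM()`. The package's own conclusions
  (which model wins where) do not hinge on this choice.
- *Optimizer.* A damped Newton (IRLS) iteration from a zero start,
  converged at gradient max-norm 1e-8, with designs kept sparse (spike
  trains at ~6 Hz are ~1% dense, so the 251×251 cross-products are cheap).
  Columns are rescaled internally for unpenalized fits (pure
  reparameterization; coefficients are mapped back). Complete separation —
  a perfectly classified training set, under which the unpenalized MLE
  diverges — is detected and raised as an error advising a penalty.
  *Quasi*-separation (e.g. zero observed spikes within 1 ms of a spike, the
  expected signature of refractoriness) is not an error: the fit converges
  in gradient norm with a large negative lag coefficient, which is the
  correct point estimate.

**Phase model.** The distribution of phases observed at spike times is
estimated with a Gaussian-kernel circular KDE: the spike-phase
distribution is wrapped across ±π (equivalently, three concatenated copies
at offsets −2π, 0, +2π are smoothed and renormalized to one copy) and
evaluated on a fixed 1,000-point grid over [−π, π), with circular linear
interpolation in between. We compute this as a linearly binned histogram
circularly convolved with a wrapped Gaussian kernel of unit quadrature
mass, which is mass-preserving — the estimate integrates to 1 on the grid
exactly — and fast enough to cross-validate densely. The kernel is
parameterized internally by its standard deviation σ (radians); the
candidate grid is specified as full width at half maximum (FWHM), 20
log-spaced values from 6% to 40% of a cycle, σ = FWHM / (2√(2 ln 2)).
(The two conventions "bandwidth = FWHM fraction" and "bandwidth =
variance" disagree in parts of the field's usage; `bandwidthGrid()` accepts
either.) The bandwidth is chosen by fivefold cross-validation over the
training spikes' phases, maximizing mean held-out log likelihood, ties
broken toward the smoother kernel; leave-one-out is available for sparse
trains. Note that this selector targets density-estimation quality: its
optimum shrinks roughly as n^(−1/5) with the spike count and is *not* an
estimate of any generative modulation width.

Bayes' rule with a uniform phase prior then gives the posterior
`p(spike | phase) = likelihood * spikePrior * 2π`, clipped to
[1e-12, 1 − 1e-12]. The spike prior counts spikes per target-region sample
of the *training* trials only, so held-out evaluation uses no test
information.

**phaseSH and phaseLH.** Logistic regressions of the spike indicator on
exactly two regressors — the log-odds of a history model's prediction and
of the phase posterior — plus an intercept. Fitting three coefficients
instead of re-estimating the history vector keeps the combination
low-variance and leaves each component interpretable. Both regressors are
computed from models trained on the same training split. Regressors are
mean-centered internally (folded back into the intercept afterward), so a
constant regressor — e.g. the phase posterior of a non-rhythmic train with
a flat KDE — degrades gracefully to a coefficient of 0 rather than an
ill-posed fit.

## Evaluation and inference

Held-out performance is the average log loss in bits/sample over
target-region samples, with predictions clipped to [1e-12, 1 − 1e-12]. The
detection procedure computes phaseSH−SH log-loss differences on each of 20
independent 50/50 train/test splits of trials (sampled without
replacement, independently per split; train size is
`floor(trainFraction * nTrials)`) and applies a one-tailed one-sample
t test at α = 0.001; this assumes rough normality of the 20 differences,
which holds well for the smooth per-split averages involved. The windowed
variant averages per-sample differences in consecutive 50 ms windows (25
windows for a 1,250 ms target region) and tests each window two-tailed at
the Bonferroni level 0.001/25 = 0.00004; medians across splits are reported
for display, the t tests use the per-split means.

The permutation control refits phase-based models after shuffling phase
values within every oscillation cycle (cycle boundaries at each upward
crossing through −π), per trial, independently per permutation. We shuffle
the full phase matrix — training and held-out trials alike — so each
permutation is a complete dataset in which spike–phase alignment is
destroyed while the phase distribution, the spike train and its history
structure are untouched; the spike-history component is fit once since it
does not depend on phase. The intact model's held-out log loss is then
located within the 100-permutation null.

The Rayleigh test is included as the classical pooled-spike reference:
mean resultant length r of the spike phases, R = ηr, Z = ηr² and the
standard approximate p-value `exp(sqrt(1 + 4η + 4(η² − R²)) − (1 + 2η))`.
A variant Z = r²/η seen in some write-ups is available behind
`variant = "printed"`; the p-value always uses the standard statistic, as
the approximation is only valid for it.

## The simulator and what passing tests mean

`makeGroundTruth()` and `sampleSpikes()` generate the four canonical
spike-train types: atemporal, refractory non-rhythmic, non-refractory
rhythmic, refractory rhythmic. Rhythmic probability tracks are a von Mises
density (peak at phase 0, κ = 2 by default) over an exact 8 Hz sawtooth
phase (125 ms cycles), scaled as
`prob = (rate/fs) * 2π * vonMisesPDF(phase; 0, κ)` so the cycle average is
exactly `rate/fs` (a uniform phase average of a von Mises density is
1/(2π)); 6 Hz by default, matching interneuron-like rates. Refractoriness
is imposed *during* sequential sampling: after each sampled spike the next
3 samples' probabilities are overridden to 1e-5. The effective
(post-override) track is stored with the sampled train and serves as the
generative reference for KL divergence (bits, both arguments clipped at
1e-12), since it is the true per-sample probability of the realized train.

The simulated phase is a noiseless sawtooth; recorded phase passes through
a third-order Butterworth bandpass (applied forward–backward for zero lag,
with reflective padding — so the effective attenuation is the squared
magnitude response) and an FFT-based Hilbert transform, per trial, phase 0
at oscillation peaks. The `lfp_noise` fixture closes this gap by coupling
spikes to the 8 Hz component of a synthesized noisy LFP and recovering the
coupling through the full filter→Hilbert→KDE→combine pipeline. What the
simulations do **not** emulate: non-stationary rhythm frequency and
amplitude, 1/f background, multi-unit contamination, bursting, rate
adaptation, and between-trial rate drift. Passing the simulation study
therefore demonstrates correctness of the procedure under its own
assumptions, not robustness to every property of real recordings.

The packaged validation study (`runSimulationStudy()`) uses 25 trains per
kind with 20 splits each — enough for detection-rate estimates at ±~6%
resolution while keeping a full run in the tens of minutes on one CPU; the
original-scale study (50 trains per kind) is one argument away.

## Numerical choices and degenerate inputs

- Probabilities are clipped to [1e-12, 1 − 1e-12] before any logarithm
  (log-odds, log loss, KL), making refractory floors and empty KDE regions
  finite by contract.
- Bandwidth CV folds split spikes, not trials (a config alternative exists);
  fold assignment, splits, and simulation draws are all seeded, and every
  derived seed is below 2^31.
- All-zero (or all-one) targets are an error for unpenalized fits; a
  single-element bandwidth grid short-circuits CV; fewer than 2 spike
  phases is an error for the KDE, and fewer spikes than folds advises
  leave-one-out.
- Zero-variance log-loss differences: all-zero means "not significant";
  nonzero constant differences are reported significant with a p = 0
  sentinel and a diagnostic note, since the t statistic is undefined.
- Window lengths must divide the target region; the error message lists
  valid divisors.

## Limitations

Phase models assume a meaningful band-limited oscillation exists; applying
them to broadband or burst-dominated signals yields phase estimates whose
predictive value the detection procedure will (correctly) reject, but the
phase values themselves are not diagnostic. The LH model at the literal
normalized-penalty default is heavily shrunk (see above) and should be
re-tuned for applications that need an expressive long-history model. The
t-test across splits treats the 20 splits as exchangeable replicates;
splits share trials, so the test is approximate — the permutation control
provides a sharper, assumption-light alternative for single neurons.
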