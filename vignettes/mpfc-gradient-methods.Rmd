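---
title: "Methods: gradient analyses and the synthetic task generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gradient analyses and the synthetic task generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpfcgradient)
```

This vignette documents the generative model behind the synthetic datasets,
the statistical conventions used by every analysis stage, and the reasoning
behind the package's default parameters and test problem sizes.

## Task model

A trial presents two offers in sequence. Offers are drawn from a three-point
mixture: a medium gamble (165 µL, 43.75%), a large gamble (240 µL, 43.75%),
and a safe option (125 µL at probability 1, 12.5%); gamble probabilities are
uniform on [0, 1]. Offer 1 appears at 0 ms, offer 2 at 1000 ms, and the
choice is registered at 2100 ms; every trial carries a 2-s pre-offer span
used by the baseline and timescale analyses. An offer's expected value is
EV = magnitude × probability.

Choices follow a logistic rule,
`P(choose offer 1) = plogis(beta * (ev1 - ev2) + side_bias * s1)`.
The default `beta = 0.0264` per µL was set with
`calibrate_choice_temperature()`: the root of
`mean(plogis(beta * |ev1 - ev2|)) = 0.8` over a Monte-Carlo sample of offer
pairs, so the simulated chooser picks the higher-EV offer on roughly 80% of
unequal-EV trials — a realistic, clearly-above-chance but imperfect level
that keeps choice-conditioned labels (chosen side, chosen value) decodable
without making them degenerate copies of the value labels.

## Spike generator

Each neuron is a doubly-stochastic Poisson process on a 10-ms grid:

```
rate(t) = baseline + tuning(t) + OU(t),  clipped at 0
```

- **Baselines** are lognormal across neurons (mean 5 spikes/s, CV 0.3).
- **Tuning** is epoch-gated and linear: offer-1 terms (probability,
  magnitude, offer-1 EV, side) act from offer-1 to offer-2 onset; offer-value
  memory and offer-2 EV act from offer-2 onset to choice; choice, chosen
  side, chosen/unchosen value and previous-trial terms act after choice
  fixation. The pre-offer span carries baseline + OU only, so it is
  independent of task variables by construction, as the timescale analysis
  requires. Tuning weights are drawn per neuron from a multivariate normal
  whose correlations implement the three population signatures
  (probability–magnitude +0.5; epoch-1 offer-1 EV vs epoch-2 offer-2 EV
  +0.5; within-epoch-2 offer-1 vs offer-2 EV −0.5); infeasible correlation
  settings are rejected by a positive-semidefiniteness check.
- **OU noise** uses the exact AR(1) discretization
  `x[t+dt] = exp(-dt/tau) x[t] + N(0, sigma^2 (1 - exp(-2 dt/tau)))`, whose
  autocovariance is exactly exponential — the same functional form the
  timescale estimator fits, which makes τ recovery a well-posed test of the
  estimator rather than of model mismatch.

**Why `ou_sigma_frac = 0.4`.** The OU stationary SD is a fraction of each
neuron's baseline. Setting it too low makes the across-trial spike-count
autocorrelation amplitude comparable to counting noise (at 0.25 the fitted
amplitude was ~0.006 and τ errors exceeded 30–120% at realistic population
sizes); at 0.4 the amplitude is ~0.02, recovery errors stay under ~10% at
150 neurons × 500 trials, and the baseline still sits 2.5 SD above zero so
rate clipping affects well under 1% of time steps. This was fixed before the
defaults were frozen, from the estimator's signal-to-noise requirement.

**The four-area preset.** `default_gradient_spec()` uses the recorded
population sizes (156, 146, 213, 129) and makes two properties rise strictly
with gradient order: OU τ (110, 150, 320, 450 ms) and tuning signal-to-noise
(`snr_scale` 0.6, 0.9, 1.0, 1.6). The SNR ladder must beat the population
sizes: area 3 has 213 neurons while area 4 has 129, and pseudo-population
decoding accuracy grows with both per-neuron SNR and neuron count (roughly
with SNR × √n). The top step 1.6/1.0 exceeds √(213/129) ≈ 1.29, so mean
battery accuracy still increases monotonically — and keeps doing so after
decimation to a common 125 neurons, where only the SNR ladder matters.

**Neuron model scope.** The generator includes tuning terms for chosen value,
unchosen value, previous choice and previous reward in addition to the offer
terms, because the 12-label decoding battery tests those labels; without
ground-truth tuning they would sit exactly at chance and the battery could
not order the areas.

## Analysis conventions

- **Epochs and binning.** Analysis epochs are 500 ms, 20-ms half-open bins
  `[start, start + w)`: a spike on a bin's right edge belongs to the next
  bin, a spike exactly at the epoch end is excluded, and total counts are
  conserved. The post-choice epoch is [500, 1000) ms after choice fixation,
  immediately following the choice epoch, keeping the four epochs disjoint.
- **Latency.** All five latency definitions report bin centers
  `(b − 0.5) · 20 ms` and break ties toward the earliest bin;
  significance-to-peak intervals that would be negative are reported missing.
- **Selectivity.** Two-sided Pearson tests at α = 0.05 per neuron; the
  population test is the exact binomial upper tail against a 5% null rate.
  Zero-variance neurons are flagged rather than dropped silently.
- **Signatures.** Regressors are standardized before per-neuron OLS so weight
  vectors are comparable; population weight correlations report the Fisher-z
  95% CI on r plus the regression slope and its CI; "unsigned" variants
  correlate absolute weights to measure population overlap. When both weights
  of a signature come from the same regression (integration, inhibition),
  their OLS sampling errors are correlated — roughly by minus the regressor
  correlation, which is −0.32 for offer-1 probability vs magnitude under this
  task's offer mixture — so a naive correlation would be biased to ≈ +0.3
  even for untuned neurons. These signatures are therefore cross-fitted: one
  weight is estimated on odd trials, the other on even trials, making the
  null expectation zero at the cost of some attenuation.
- **Timescale.** `R(kΔ) = A [exp(−kΔ/τ) + B]` fitted by bounded
  Levenberg–Marquardt (τ ∈ [1, 5000] ms, A ∈ [0, 2], B ∈ [−1, 1]),
  multi-started from τ₀ ∈ {50, 100, 300, 600} ms with the best SSE kept;
  fits on a bound or on a flat curve are flagged unconverged, and the
  cross-area Pearson test refuses unconverged inputs.
- **Decoding.** Pseudo-trials resample each neuron's trials of one label
  level with replacement, independently across neurons (this deliberately
  destroys noise correlations). Each repeat redraws pseudo-trials, splits
  each class in half, z-scores features on training statistics only, and
  fits a linear SVM (C = 1). The shuffle control permutes class labels over
  all pseudo-trials before the split. Continuous labels are binarized by a
  mean split with ties assigned to the low class. The multinomial EV control
  uses quantile bins by default so every class keeps a usable trial count
  under the task's skewed EV distribution (12.5% of offers sit at exactly
  125 µL); equal-width binning is available as an option.
- **Gradient tests.** Spearman rank correlation against the order 1–4, exact
  p-values in scalar mode at n ≤ 10; Pearson for the timescales. The
  intrinsic-property controls (baseline rate, Fano factor in 100-ms bins,
  PCA explained-variance slopes) run through the same machinery so a
  spurious global gradient in nuisance properties would be visible.
- **Seeding.** One master seed spawns named substreams (trial generation,
  weight draws, spike draws, each decoder repeat, decimation draws) via a
  deterministic 31-bit hash, so a full run is bitwise reproducible and any
  single stage can be replayed in isolation.

## Problem sizes in the test suite

The sizes used by the tests are the package's own choices, balancing
statistical power against runtime:

- Shuffle calibration runs at full size (125 neurons, 1000 pseudo-trials per
  class, 200 repeats) because its tolerance (50% ± 2 points) is a direct
  claim about those sizes.
- Timescale recovery uses 150 neurons × 500 trials per area, where the ±20%
  tolerance holds with a comfortable margin (~10% typical error).
- Type-I calibration uses 1000 untuned neurons so the binomial SE on the
  selective fraction (~0.7%) makes the ±2-point check meaningful, and the
  null signature correlations get |r| < 0.1 ≈ 3 SE at that n.
- The end-to-end gradient check runs the full four-area preset at 500 trials
  but decodes with 250 pseudo-trials per class and 20 repeats; the ordering
  of battery means is stable at these sizes and the linear SVM dominates the
  runtime (about one second per fit at the full 1000-per-class size on
  unseparable data, which is why the battery is scaled down while the
  calibration target is not).

## Limitations

The generator is linear and Poisson: no adaptation, bursting, or
noise correlations (the pseudo-population construction would discard the
latter anyway), a single shared OU timescale per area rather than a
distribution, and choice behaviour that depends only on the EV difference
and a side bias. These are the minimal ingredients the analyses measure;
anything richer would not change what the estimators are being validated
against.
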