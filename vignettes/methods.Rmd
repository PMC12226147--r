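---
title: "Directed activity flow and SOZ localisation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed activity flow and SOZ localisation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

In focal epilepsy, the seizure onset zone (SOZ) — the set of intracranial
electrode contacts where seizures first appear — is hypothesised to play two
opposite network roles: between seizures it behaves as a *sink*, dominantly
receiving directed neural activity from the rest of the implanted network
(consistent with the idea that surrounding tissue suppresses it), while during
seizures it becomes a *source*, dominantly transmitting activity outward.
`sozflow` implements a data-driven test of both hypotheses and a machine-learning
SOZ localiser built on the same quantities, with a synthetic cohort generator so
that every stage can be exercised and validated without clinical recordings.

The analysis chain is: multichannel iEEG recordings → preprocessing →
thirteen directed connectivity matrices per 2-s epoch → six weighted directed
graph metrics per contact → (a) Bayes-factor tests of the SOZ-vs-non-SOZ
contrast per measure × metric × period, and (b) a random-forest classifier on
the pooled 78-dimensional feature vector per contact.

## The synthetic cohort generator

Clinical iEEG is replaced by stable vector-autoregressive (VAR) network models
with *planted* directional coupling:

* Each patient receives `N` channels (default 20–36), an SOZ mask whose size is
  `round(f * N)` with `f` drawn from a normal distribution with mean 0.13 and
  s.d. 0.11 (clipped so that at least two contacts fall on each side) — the
  proportion and spread seen in multi-centre cohorts.
* The VAR coefficient matrices get: self-lags of 0.4 at lag 1 (autocorrelated
  channel dynamics); sparse baseline edges (probability 0.1, magnitude 0.1,
  random sign, random lag); and planted edges with probability 0.8 on every
  eligible directed pair — non-SOZ→SOZ with magnitude `sink_gain` in interictal
  mode, SOZ→non-SOZ with magnitude `source_gain` in ictal mode. The planted-edge
  probability is deliberately below 1 so SOZ contacts vary in strength and
  cohorts are not perfectly separable.
* All lag matrices are jointly rescaled until the companion-matrix spectral
  radius is at most 0.95 (strict stationarity with slow mixing), and every
  recording discards a 2000-sample burn-in (more than 20 time constants at that
  radius).
* A per-patient multiplicative gain factor, uniform on (0.5, 1.5) and shared
  between the interictal and ictal models by default, makes planted effect
  sizes vary across patients and makes the same patients both strong sinks and
  strong sources — the correlated switching the contrast-correlation analysis
  looks for. Setting `gain_coupling = "independent"` removes that coupling.
* Measurement artefacts: a 60-Hz sinusoid with random phase per channel
  (amplitude `line_noise_amp`), white measurement noise at 5% of the innovation
  scale, bad-channel flags with probability 0.05, and synthetic electrode
  coordinates drawn uniformly in an 80 mm cube with rejection sampling to
  ≥ 10 mm spacing (so the subsampling distance rule is exercised).
* Recording layout mirrors the clinical protocol: two 120-s interictal
  recordings and 1–5 ictal recordings per patient with durations uniform on
  20–180 s (bracketing the reported 113-s mean seizure duration without its
  long tail).

Bad channels are planted only among non-SOZ contacts, so the ≥ 2-SOZ invariant
survives bad-channel exclusion; clinical data can have bad SOZ contacts, which
this generator does not emulate. The generator default VAR order is 2; the
downstream analysis never sees that number because the estimator selects its
own order. What the generator does *not* emulate is equally important for
interpreting green tests: there is no seizure morphology (no low-voltage fast
activity, chirps or spike-waves), no within-seizure non-stationarity, no
volume conduction, and the waveforms are Gaussian. Passing tests demonstrate
that the pipeline recovers directed coupling planted in a linear stationary
world; they cannot certify performance on clinical recordings.

## Preprocessing

Recordings are resampled to exactly 256 Hz by polyphase rational resampling
(native rates 256–1024 Hz all reduce to small integer ratios), bad channels are
removed, and mains noise is removed with a zero-phase band-stop notch over
58–62 Hz. The notch is realised in the frequency domain with sharp band edges:
this makes it exactly zero-phase — any phase distortion would bias every
directed measure downstream — and exactly idempotent, which the test suite
asserts. Harmonics of 60 Hz are not notched. A smooth IIR notch (e.g. a
4th-order Butterworth band-stop) was considered and rejected: its transition
bands attenuate twice on a second pass, violating idempotence at the percent
level.

Channel subsampling keeps all SOZ contacts and fills up to 30 total with
non-SOZ contacts drawn without replacement, each required to be ≥ 10 mm from
every already-selected contact when coordinates exist. The draw is repeated 10
times by default and downstream metrics are averaged over runs; when a patient
has at most 30 channels every run returns the full set and the pipeline
collapses the duplicates. Grey-matter eligibility is represented only by the
channel status column — no anatomical processing is attempted.

Each recording contributes three 2-s epochs (512 samples): interictal at
0–2 s, 59–61 s and 118–120 s; ictal at 0–2 s, (D−2)–D s, and the 2-s window
whose *start* lies halfway between the early and late starts. "Halfway" is
ambiguous between start-anchored and centre-anchored; the start-anchored
reading is implemented (for a 6-s seizure the mid epoch is 2–4 s).

## The thirteen directed connectivity measures

The literature names the measures but typically delegates their estimators to
toolboxes; each estimator here is a documented standard formulation. All
matrices follow the destination-row/source-column convention, are non-negative
(signed scores are rectified at zero, because strengths and shortest paths are
undefined for negative weights) and have zero diagonals.

**MVAR spectral family (DTF, DCOH, PDC, SGC).** An ordinary-least-squares VAR
fit with AIC order selection over 1–10 (ties to the smaller order; the order
cap also respects one third of the sample size) gives coefficients `A_k` and
innovation covariance Σ. On a 125-bin grid of frequencies `f_k = (k+0.5)·128/125`
(bin centres spanning the full 0–128 Hz Nyquist band while avoiding DC, where
the coefficient matrix can be ill-conditioned), `Ā(f) = I − Σ_k A_k e^{−i2πfk/fs}`,
`H = Ā⁻¹`: DTF is the row-normalised `|H|²`, directed coherence weights `|H|²`
by innovation variances before row-normalising, PDC is the column-normalised
`|Ā|²`, and spectral Granger causality is Geweke's log-ratio
`ln[S_dd/(S_dd − (Σ_ss − Σ_ds²/Σ_dd)|H_ds|²)]` from *bivariate* refits per
channel pair — the conditional multivariate decomposition is deliberately
avoided because spectral factorisation of a 30-channel model on 512 samples is
ill-posed. Frequency-averaged values are reported.

**Phase family (PSI, GD).** Welch cross-spectra (128-sample Hann segments, 50%
overlap — seven segments per epoch, 2-Hz resolution). The phase slope index
sums `Im(C*(f) C(f+δf))` of the coherency across the band and is positive when
the source consistently leads; group delay fits a coherence-weighted
least-squares slope to the unwrapped cross-spectral phase and converts it to a
delay in seconds. Both raw values are antisymmetric and rectified into the two
directed entries.

**Information family (DI, CCE).** Gaussian (linear) estimators: directed
information is `½ ln[var(d_t|d⁻)/var(d_t|d⁻, s, s⁻)]` with L = 5 lags and the
instantaneous source term included; causally conditioned entropy is the same
construction restricted to strictly causal source lags, so the two differ
exactly by the instantaneous term and DI ≥ CCE when lag 0 is informative.
Nonparametric (k-NN) entropy estimators were rejected: 512 samples cannot
support them stably.

**Bivariate cause-effect family (ANM, IGCI, CDS, RECI, LMFIT).** These treat
samples as exchangeable draws and score functional asymmetry per ordered pair:
additive-noise-model residual independence via smoothing splines and distance
correlation; information-geometric slopes after min-max scaling to [0, 1];
conditional-distribution variability over 10 equal-count bins; and polynomial
regression-error comparison at degree 3 (RECI) and degree 1 (LMFIT, the single
time-domain measure). Distance covariance is computed through its expanded
form (no explicit double-centring), with per-channel distance matrices cached
across pairs.

## Graph node metrics and the feature table

Strengths are computed on raw matrices so the SOZ/non-SOZ contrast keeps its
magnitude; the walk and path metrics operate on the matrix scaled to [0, 1] by
its maximum, because the 13 measures live on incommensurable scales. Mean
first passage time uses the row-normalised walk adjacency (zero-out-strength
rows become uniform steps) and solves the absorbing-chain system `(I−Q)t = 1`
per target, aggregated *inbound* (expected steps to reach the node, the
"hard-to-reach periphery" reading); singular systems are capped at `10N²`.
Clustering is the Fagiolo weighted-directed coefficient on cube-rooted
weights. Eccentricity and betweenness run on the `1/weight` length graph via
Dijkstra/Brandes; eccentricity is taken outbound, and nodes reaching no one
are imputed with the graph maximum rather than infinity so the feature table
stays finite. Betweenness is normalised by `(N−1)(N−2)`.

Metrics are computed per (measure, epoch, subsample run) and averaged per
contact — metrics-after-averaging, not matrix-averaging, so that each epoch's
network topology contributes independently. The result is the 78-column
(13 × 6, measure-major) feature table.

## Statistics

All group contrasts use one-sample JZS Bayes-factor t-tests: a Cauchy prior
with scale √2/2 on the standardised effect size, evaluated through the Rouder
g-integral by adaptive quadrature (relative tolerance 1e-8), with the strict
evidence thresholds BF10 > 10 (H1) and BF10 < 0.1 (H0). The sink/source grid
takes per-patient SOZ-mean minus non-SOZ-mean differences — a paired design
across patients, chosen because each patient contributes both group means —
for every measure × metric × period. Contrasts whose differences are
identically zero (a metric that is constant in small dense graphs, e.g.
betweenness on a complete network) are reported as uninformative rather than
tested. Effect-size correlations are Pearson: across patients between the
interictal in-strength contrast and the ictal out-strength contrast per
measure, and across SOZ contacts within each patient.

For the classifier's per-table comparison against its label-shuffle chance
distribution, the Bayes factor uses the standardised position of the true AUC
within the chance distribution, `t = (AUC − mean)/sd(chance)`, rather than a
one-sample t-test on the individual true−chance differences: the latter has a
t-statistic that grows with the square root of the number of shuffles and
declares null tables significant. The group-level test (patient AUCs against
their chance means, paired across patients) is a regular JZS t-test.

## Localisation

A bagged ensemble of 50 decision trees (bootstrap per tree, √78 candidate
features per split, Gini impurity, unlimited depth — the conventional random
forest) classifies contacts within each patient under stratified 10-fold
cross-validation (folds shrink with a warning when the minority class is
smaller). Per fold, features are z-scored on training statistics only and the
training minority class is up-sampled by row repetition to exact balance —
never the test fold, which an identity audit in the test suite verifies. AUC
is computed on pooled out-of-fold vote fractions (threshold-free), averaged
over `n_upsample_repeats` full repetitions with fresh fold and bootstrap
randomness. Feature contributions are out-of-bag permutation importances
(mean OOB error increase divided by its s.d. across trees), averaged over
folds, and grouped by concatenating metrics within a measure (13 groups of 6)
or measures within a metric (6 groups of 13). No hyper-parameter tuning is
performed anywhere.

## Numerical and design choices

* Frequency grid: 125 bin centres over (0, 128] Hz; first bin 0.512 Hz, last
  127.488 Hz.
* VAR innovation covariance uses the small-sample divisor
  `max(T − N·p − 1, 1)`.
* Logarithm arguments in SGC and the information measures are floored at
  1e-12; constant channels raise `degenerate-signal` errors rather than
  producing NaNs.
* Sub-seeds for every stage, patient and run are derived by hashing the global
  seed with context labels, so stage-level results are reproducible
  independently of execution order; all RNG use is wrapped so the caller's
  random state is never disturbed. Identical configurations reproduce
  byte-identical cohort files and output tables (asserted on MD5 hashes).
* AIC order selection overselects with non-vanishing probability (roughly 9%
  for one extra order); the tests assert a clear majority on the true order,
  not near-certainty, and never underselection.

## Problem sizes used in the shipped analyses

The validation analyses run on deliberately desk-scale cohorts chosen once:
20 patients with 10–14 channels, two 120-s interictal plus one or two 20–120-s
ictal recordings at 512 Hz native rate, planted gains 0.6 (or 0 for the null
cohort), classifier repeats 20 and label shuffles 200, one subsample run
(with ≤ 30 channels all runs coincide). Unit tests use smaller fixtures still.
The full clinical-scale protocol (30-channel caps with 10 subsample runs,
1000 repeats/shuffles) is a configuration change, not a code path change.

## Known limitations

Linear Gaussian synthetic data cannot probe the nonlinear regimes where the
information-theoretic and cause-effect measures are supposed to shine; the
bivariate SGC ignores conditional (multivariate) structure; Gaussian DI/CCE
are blind to purely nonlinear dependence; the eccentricity imputation for
unreachable nodes compresses the top of that feature's range; and per-patient
classification with very few SOZ contacts yields noisy per-patient AUCs —
group-level statements are the reliable ones.
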