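---
title: "Detecting mind wandering from driving behavior: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mind wandering from driving behavior: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mindwander` implements a complete probe-caught mind-wandering (MW)
detection pipeline for simulated car-following: a cohort simulator that
generates labeled multichannel driving sessions, feature extraction over
pre-probe windows, and the full driver-independent and driver-dependent
classification grids with their evaluation statistics. This vignette is the
package's own account of the models, the choices behind them, and what the
synthetic experiments do and do not establish.

## The detection problem

A driver follows a lead vehicle at a 20 m target headway while the lead car
travels at 80 km/h. Once per minute a tone probe sounds and the driver
reports whether their thoughts immediately before the tone were on the task
(MW-absent) or elsewhere (MW-present). Each answered probe becomes one
classification sample: the behavioral time series in the window just before
the tone, labeled by the self-report. The question is whether ordinary
driving-log channels — lane offset, steering, pedal operation, headway
distance — carry enough state information to recover the report.

Two modeling regimes are implemented:

* **Driver-independent**: train on all participants but one, test on the
  held-out participant (leave-one-participant-out, LOPO). Models are built
  separately for participants with extreme MW proportion (below 0.33 or
  above 0.67 of answered probes) and medium MW proportion, because extreme
  reporters have nearly single-class data and strong stable traits.
* **Driver-dependent**: one model per medium-MW participant, evaluated with
  4 repetitions of stratified 5-fold cross-validation over that
  participant's ~24 samples.

## The cohort simulator

No raw behavioral data ship with the package; the simulator is a first-class
module that generates sessions with the statistical structure the analysis
assumes, so every downstream stage is testable end to end.

**Design parameters** (defaults are the study design): 40 participants,
25-minute sessions sampled at 10 Hz, one probe and one lead-vehicle brake
per minute from minute 2 through minute 25 (24 probes per session, 960
cohort-wide), and exactly 3 unanswered probes drawn uniformly across the
cohort, leaving 957 answered samples. The sampling rate is not part of the
study design we inherited, so it is a configurable default: 10 Hz is typical
of driving-simulator logs and makes the 5/10/15 s windows 50/100/150
samples.

**Ground-truth state.** Reports label only probe instants, so the simulator
needs a latent state process to give pre-probe windows a coherent label. MW
is defined at minute resolution — the probe cadence — as a two-state Markov
chain: each minute keeps the previous state with probability
`mw_persistence` (default 0.7) and otherwise redraws it from the
participant's propensity, which is the chain's stationary probability.
Propensities are Beta-distributed across participants (default
`Beta(2, 2)`, mean 0.5), which spreads the cohort over low, medium and high
MW proportions; with the default cohort size roughly half the participants
land in the extreme group, matching the reported 18/22 split in
distribution. Note that a participant's *observed* proportion over 24
autocorrelated probes is a noisy estimate of the propensity, so even a
propensity distribution concentrated near 0.5 yields observed proportions
well outside (0.33, 0.67); group assignment always uses the observed
proportions, as the original analysis must.

**Channels.** Lane offset and headway distance follow discretized
mean-reverting (Ornstein–Uhlenbeck) processes around 0 m and the 20 m set
point, with stationary SDs of 0.25 m and 1.5 m and reversion rates of 0.3/s
and 0.1/s. Steering is the lead vehicle's deterministic curvature profile
plus a bounded proportional–derivative correction on the offset plus noise;
foot operation is a baseline-plus-noise channel. Brake events add brief
deterministic excursions to foot (a pedal stab) and distance (the gap
closing and reopening). Steering and foot are clipped to [-1, 1] and
distance to non-negative values, so range safety holds for any volatility.
Per-participant traits multiply the channel scale parameters log-normally
(`trait_spread`, default 0.2), giving every driver a stable signature that
global features can pick up.

**The MW effect.** During MW minutes the innovation noise of all four
channels is multiplied by `effect_size_lambda`. This is the simulator's
single behavioral assumption, motivated by the reported positive
correlations between MW frequency and the variability measures SDLP, SDSTW
and SDFO: mind wandering loosens control, inflating variability without
shifting means. `lambda = 1` is an exact null; the default 1.5 is a
moderate effect a human-factors study could plausibly produce; the
recovery experiments use 2 (variance quadrupled), which is deliberately
strong so that pipeline failures cannot hide behind a weak generator. The
channel models are intentionally simple: the acceptance surface is
distributional (null calibration and effect-size recovery), not trajectory
realism. Real driving data add non-stationarity, report error,
road-geometry structure and non-Gaussian tails that the simulator does not
emulate, so green tests here establish the *pipeline*, not field
performance.

**Scheduling detail.** Probes are uniform within their minute, at least 5 s
from that minute's brake event, and the probe of the first eligible minute
is placed at least 15 s (the longest window) after the analysis start. The
last rule is ours: it guarantees that every answered probe admits all three
window lengths, so the feature matrix always has exactly one row per
answered probe (957 by default). Reports equal the true state by default
(`report_fidelity = 1`); lowering it injects label noise, which behavioral
data cannot distinguish from behavior noise.

## Preprocessing

The four analysis variables are assembled per sample: offset, *relative*
steering (participant minus lead-vehicle steering — the lead car drives the
track ideally, so its steering encodes road curvature and the difference
removes it), foot, and distance. The first minute (before the analysis
start) is dropped, leaving 14,400 samples per session.

Three channel transforms are available, fitted on a declared pool and
applied linearly: `none`; `zscore` (per-channel standardization); and
`pica`, an independent-component transform implemented as whitening to
identity covariance followed by a symmetric fixed-point rotation maximizing
a kurtosis contrast, with components ordered by decreasing kurtosis and
signs fixed so the largest-magnitude loading is positive. Any
independence-maximizing linear map fits the one-line definition we inherit;
the kurtosis fixed point is the classical, deterministic-given-seed choice.

Fit scope is explicit because it decides leakage: in driver-independent
LOPO the transform is refit per fold on the training participants (the
default), while `paper_faithful = TRUE` fits once on the whole group,
mirroring an apparent whole-dataset preprocessing in the original analysis.
In driver-dependent modeling the transform is fitted on the participant's
own full session: the 4x5 CV splits probes, not sessions, and the
leakage-sensitive stages there are feature selection and projection, which
are always refit per fold on training rows only.

## Features

**Global (16)**: max, min, mean, SD of each channel over the analysis
period — stable inter-individual traits, constant across a participant's
probes.

**Local (84)**: for each channel, 21 statistics of the half-open window
`[probe - W, probe)` with W in {5, 10, 15} s: mean, SD, max, min, median,
kurtosis, skewness, the window-local linear trend (intercept, slope,
coefficient of determination, with the time origin at the window start),
end-minus-start difference, Shannon entropy, five Yule–Walker AR
coefficients, and four Haar wavelet band variances.

Numerical conventions, chosen once and documented:

* **Entropy**: 10 equal-width bins over the window's own range, log base 2.
  The edges track the range, so entropy is invariant under affine channel
  maps. A constant window has entropy 0.
* **AR coefficients**: Yule–Walker on the mean-centered window, positive
  coefficient = positive dependence on that lag; a constant window yields
  zeros with a warning rather than an error, so degenerate windows cannot
  abort a grid run.
* **Wavelets**: orthonormal Haar with no signal extension. When a level has
  odd length the trailing coefficient is set aside as a boundary residual
  rather than padded or decomposed further; this keeps Parseval's identity
  exact at machine precision for every window length, keeps all
  approximation coefficients at a common scale (so a constant window gives
  exactly zero band variances), and avoids the boundary ambiguity of
  symmetric padding. Band variances are population variances of the
  full-depth coefficients.
* **Moments**: kurtosis is non-excess (normal = 3), skewness the third
  standardized moment; both defined as 0 for a zero-variance window. The
  coefficient of determination of a constant response is defined as 0. The
  median of an even-length window is the mean of the central pair.

A containment property is tested explicitly: no feature value depends on
samples at or after the probe instant.

## Selection, projection, classification

Driver-independent models screen features univariately: a feature is kept
iff both the unequal-variance t-test and the Wilcoxon rank-sum test reject
at 0.05. The intersection keeps the per-feature false-keep rate at or below
the nominal level. An empty selection — common for medium-MW groups, where
few features separate the classes — degrades to majority-class prediction
instead of erroring, so full grid runs always complete.

Driver-dependent models rank features by CFS merit,
`k r_cf / sqrt(k + k(k-1) r_ff)`, grown greedily, and keep the top 50%. The
merit rewards class correlation and penalizes redundancy; constant features
rank last.

Selected features are standardized and projected onto principal components;
the six "feature selection" grid levels are the PCA variance thresholds 50,
60, 70, 80, 90, 100% — the smallest leading component set reaching the
threshold is kept, and 100% keeps everything.

Six classifier families run at their library defaults except where the
design fixes them: linear-kernel SVM, decision tree, AdaBoost.M1 with 100
tree learners (implemented directly over `rpart` with the standard
weight-update recurrence, since no installed library provides that exact
ensemble), 1-nearest-neighbor (the original environment's KNN default),
linear discriminant analysis with a ridge-regularized fallback for singular
covariances, and Gaussian naive Bayes. Score ties and majority-class ties
predict MW-absent, the negative class. Every stochastic step is locally
seeded, so identical configuration and seed give bit-identical predictions.

## Evaluation

Pooled out-of-fold predictions feed a confusion table with MW-present as
the positive class; we report Cohen's kappa, accuracy, precision and recall
(precision and recall defined as 0 in their degenerate cases). Kappa
significance uses a one-sided permutation test (the inherited tables flag
significance without naming a method; a permutation test is distribution
free and matches the pooled-prediction construction). Configurations are
compared with a Friedman rank test blocked by CV fold, using the
tie-corrected statistic — accuracy values over small folds tie often — which
reduces to the classic form (and to `stats::friedman.test`) when no ties
occur. A significant omnibus is followed by Nemenyi critical-difference
comparisons on mean ranks. Whether a set of configurations is better than
chance overall is summarized by an exact one-sided sign test on the
configuration kappas.

Fold assignment in the repeated k-fold CV depends only on the seed,
repetition and labels — never on the configuration — so fold accuracies are
paired across the 54 driver-dependent configurations, as the Friedman
blocks require. In LOPO the blocks are participants and pairing is
automatic.

## Problem sizes and what the experiments show

The structural checks run the full default design (960 probes, 957 feature
rows, grids of 108/324/54 with Friedman dfs 107/323/53) — these are exact
counts and cost seconds. The statistical checks are scaled to what they
measure: the null calibration runs 20 seeded cohorts of 6 participants with
one window (18 configurations each) and asks that every configuration's
median kappa sit within 0.1 of zero and the univariate screen keep at most
5% of features (99% binomial band); the recovery experiment runs the full
54-configuration grid for 10 medium-MW participants at `lambda = 2` and
asks that the mean best-model kappa clear 0.3. These sizes give the
binomial and median estimates enough precision to be meaningful while
keeping a full run in minutes on one core. At `lambda = 2` the recovered
kappas are far higher than anything reported for human data — window SDs
differ by a factor of ~2 between states — which is the point: the pipeline
recovers a strong planted effect essentially perfectly, and recovers
nothing under the null. It says nothing about the effect size in real
driving.

## Known limitations

* The simulator's MW effect is purely a volatility multiplier; mean shifts,
  drift, and time-on-task effects (MW frequency rising over a session) are
  not modeled.
* Relative steering is computed per sample, which is exact for the
  simulator's time-aligned lead vehicle; real logs matched by road position
  would need odometer interpolation in the data adapter.
* Observed MW proportions over 24 dependent probes are noisy, so group
  membership is itself a random variable; analyses conditioned on the
  medium group inherit that selection.
* The permutation test for kappa ignores the dependence of pooled LOPO
  predictions within participants; its p-values are calibrated for the
  pooled vector, not a participant-level resampling.
* With ~24 samples per participant, driver-dependent results are dominated
  by selection optimism across 54 configurations; the best-of-grid kappa is
  biased upward, which is why the null calibration checks the per-config
  median rather than the maximum.
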