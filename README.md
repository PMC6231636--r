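# mindwander

Detecting mind wandering from driving behavior time series.

Mind wandering (MW) — task-unrelated thought — is common while driving and
degrades vehicle control. In probe-caught studies, a driver performing a
car-following task (20 m target headway behind a lead car at 80 km/h) hears
a tone once per minute and reports whether their thoughts just before the
tone were on the task. `mindwander` implements the full detection pipeline
for such studies: each answered probe becomes one classification sample
whose predictors are statistics of the driving channels (lane offset,
steering relative to the road curvature, pedal operation, headway distance)
and whose label is the self-report.

The package provides, as tested R functions:

* **a cohort simulator** (`simulator_config()`, `generate_cohort()`):
  labeled multichannel sessions — mean-reverting control channels whose
  innovation noise is inflated by a factor λ during ground-truth MW
  minutes, a per-minute Markov MW state with participant-specific
  propensity, per-minute probe/brake scheduling, and cohort-wide
  non-responses; sessions round-trip through plain CSV
  (`write_sessions()` / `read_sessions()`);
* **preprocessing** (`assemble_variables()`, `fit_transform()`):
  relative-steering assembly plus `none` / `zscore` / `pica` channel
  transforms, where P-ICA is whitening followed by a fixed-point
  kurtosis-contrast rotation;
* **features** (`build_feature_matrix()`): 16 global session-level
  features (max/min/mean/SD × 4 channels) and 84 local pre-probe-window
  features (moments, order statistics, linear trend, Shannon entropy,
  5th-order Yule–Walker AR coefficients, 3-level Haar wavelet band
  variances) over 5/10/15 s windows;
* **selection and projection** (`univariate_select()`, `cfs_select()`,
  `fit_projection()`): t-test ∧ Wilcoxon screening, CFS merit ranking, and
  PCA variance-level projection (50–100%);
* **modeling grids** (`run_grid()`, `lopo_cv()`, `repeated_kfold_cv()`,
  `train_and_predict()`): driver-independent leave-one-participant-out
  grids (108 global-only / 324 local or combined configurations) over six
  classifiers (linear SVM, decision tree, AdaBoost.M1 with 100 trees, 1-NN,
  discriminant analysis, naive Bayes), and driver-dependent 4×5-fold grids
  (54 configurations) with linear SVM;
* **evaluation** (`evaluate_cv()`, `cohen_kappa()`, `friedman_compare()`,
  `posthoc_pairs()`, `sign_test_median_gt0()`, `build_report()`): Cohen's
  κ = (p_o − p_e)/(1 − p_e) with one-sided permutation significance,
  accuracy/precision/recall, tie-corrected Friedman comparison across
  configurations blocked by CV fold with Nemenyi post-hoc critical
  differences, and exact sign tests on median kappa;
* **orchestration** (`validate_config()`, `run_experiment()`): a
  config-driven end-to-end run writing session files, grid tables and a
  JSON manifest, fully reproducible from a master seed.

See `vignettes/methods.Rmd` for the models, conventions and design
decisions.

## Worked example

Simulate a small cohort with a strong MW effect (λ = 2, i.e. channel
innovation SDs doubled during MW minutes), group participants by observed
MW proportion, and run the 54-configuration driver-dependent grid for one
medium-MW participant:

```r
library(mindwander)

cfg <- simulator_config(n_participants = 10, effect_size_lambda = 2,
                        mw_persistence = 0.9, mw_propensity_shape = c(40, 40),
                        n_nonresponse = 0, seed = 42)
cohort <- generate_cohort(cfg)
groups <- assign_groups(cohort)
head(groups, 4)
#>   participant_id mw_proportion   group
#> 1              1    0.58333333  medium
#> 2              2    0.04166667 extreme
#> 3              3    0.37500000  medium
#> 4              4    0.00000000 extreme

grid <- run_dependent_grid(cohort$sessions[[1]], seed = 1)
head(grid$evals[order(-grid$evals$kappa),
     c("preprocess", "window_s", "variance_level", "kappa", "accuracy")], 3)
#>  preprocess window_s variance_level     kappa  accuracy
#>        pica       15            100 0.9786477 0.9895833
#>        none       15            100 0.9784946 0.9895833
#>      zscore       15            100 0.9784946 0.9895833

fr <- build_report(setNames(list(grid), "1"), "driver_dependent")$friedman[["1"]]
sprintf("Friedman chi2(%d) = %.2f, p = %.3g", fr$df, fr$chisq, fr$p)
#> [1] "Friedman chi2(53) = 20.67, p = 1"
sign_test_median_gt0(grid$evals$kappa)
#> [1] 5.551115e-17
```

Reading the output: participant 1 reported MW on 58% of probes (medium
group). The best of the 54 configurations (P-ICA preprocessing, 15 s
window, all principal components) reaches κ ≈ 0.98 — the planted λ = 2
effect makes window variability almost perfectly informative, so nearly all
configurations succeed: the sign test on the 54 kappas is overwhelmingly
positive, and the Friedman test finds no configuration significantly better
than the rest. Under the null (λ = 1) the same grid yields per-configuration
median kappas within ±0.1 of zero.

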