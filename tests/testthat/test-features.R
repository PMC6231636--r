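test_that("histogram entropy matches closed forms", {
  expect_equal(shannon_entropy(rep(3.7, 40)), 0)
  # 50 samples filling 10 equal-width bins with 5 each
  x <- rep(seq(0.05, 0.95, by = 0.1), each = 5)
  expect_equal(shannon_entropy(x, 10), log2(10))
  expect_equal(shannon_entropy(rep(c(0, 1), 25), 10), 1)
  # affine invariance: bin edges track the window range
  set.seed(1)
  y <- rnorm(200)
  expect_equal(shannon_entropy(y), shannon_entropy(5 * y - 3))
})

test_that("trend features are exact on lines and defined on constants", {
  t <- seq(0, 5, by = 0.1)
  tr <- trend_features(2 * t + 1, t)
  expect_equal(unname(tr), c(1, 2, 1))
  tr2 <- trend_features(rep(4, 10), 1:10)
  expect_equal(unname(tr2), c(4, 0, 0))
  tr3 <- trend_features(c(1, 2, 3), c(0, 1, 2))
  expect_equal(unname(tr3[c("intercept", "slope")]), c(1, 1))
  # time origin at the window start: shifting times leaves the fit unchanged
  expect_equal(trend_features(2 * t + 1, t + 100), tr)
  expect_error(trend_features(c(1, 2, 3), rep(1, 3)), "constant time")
})

test_that("Yule-Walker coefficients recover known processes", {
  set.seed(42)
  ar1 <- as.numeric(stats::filter(rnorm(5000), 0.8, method = "recursive"))
  a <- ar_coefficients(ar1, 5)
  expect_gt(a[1], 0.75)
  expect_lt(a[1], 0.85)
  expect_true(all(abs(a[2:5]) < 0.05))

  wn <- rnorm(5000)
  expect_true(all(abs(ar_coefficients(wn, 5)) < 0.05))

  expect_warning(z <- ar_coefficients(rep(2, 100), 5), "constant")
  expect_equal(z, rep(0, 5))
})

test_that("Haar wavelet variances behave as an orthonormal transform", {
  expect_equal(unname(wavelet_variances(rep(1.3, 64))), rep(0, 4))
  set.seed(7)
  x <- rnorm(4096)
  v <- wavelet_variances(x)
  expect_true(all(abs(v[c("var_cd1", "var_cd2", "var_cd3")] - 1) < 0.1))
  # Parseval: energy preserved exactly, including odd lengths
  for (n in c(4096, 150, 151)) {
    y <- rnorm(n)
    w <- haar_dwt(y)
    expect_equal(sum(unlist(w)^2), sum(y^2), tolerance = 1e-8)
  }
  expect_error(haar_dwt(rnorm(7), 3), "shorter")
})

test_that("global features: 16 values with the documented structure", {
  ch <- assemble_variables(tiny_cohort()$sessions[[1]])
  g <- global_features(ch)
  expect_length(g, 16)
  expect_identical(names(g), paste0(
    "global_", rep(c("offset", "rel_steering", "foot", "distance"), each = 4),
    "_", rep(c("max", "min", "mean", "std"), 4)))
  expect_true(all(g[grep("_max$", names(g))] >= g[grep("_mean$", names(g))]))
  expect_true(all(g[grep("_mean$", names(g))] >= g[grep("_min$", names(g))]))
  expect_equal(unname(g["global_offset_std"]), sd(ch$values[, "offset"]))

  const <- fake_session(distance = rep(20, 1200))
  gc <- global_features(assemble_variables(const))
  expect_equal(unname(gc["global_distance_max"]), 20)
  expect_equal(unname(gc["global_distance_min"]), 20)
  expect_equal(unname(gc["global_distance_std"]), 0)
})

test_that("window extraction honors the half-open pre-probe interval", {
  ch <- assemble_variables(tiny_cohort()$sessions[[1]])
  w <- extract_window(ch, 120, 15)
  expect_equal(nrow(w$values), 150)
  expect_equal(w$times[1], 105)
  expect_equal(w$times[length(w$times)], 119.9)
  expect_equal(nrow(extract_window(ch, 120, 5)$values), 50)
  expect_error(extract_window(ch, 70, 15), "before the analysis start")
})

test_that("local features: 84 values, fixed order, sensible degenerate values", {
  ch <- assemble_variables(tiny_cohort()$sessions[[1]])
  w <- extract_window(ch, 180, 10)
  f <- local_features(w)
  expect_length(f, 84)
  feats <- c("mean", "std", "max", "min", "median", "kurtosis", "skewness",
             "intercept", "slope", "r_squared", "diff", "entropy",
             paste0("ar", 1:5), "var_cd1", "var_cd2", "var_cd3", "var_a3")
  expect_identical(names(f), paste0(
    rep(c("offset", "rel_steering", "foot", "distance"), each = 21), "_",
    rep(feats, 4)))
  expect_true(all(f[grep("_std$", names(f))] >= 0))
  expect_true(all(f[grep("_r_squared$", names(f))] >= 0 &
                    f[grep("_r_squared$", names(f))] <= 1))

  wc <- w
  wc$values[, "foot"] <- 0.25
  fc <- suppressWarnings(local_features(wc))
  expect_equal(unname(fc[paste0("foot_", c("std", "diff", "entropy", "slope",
                                           "var_cd1", "var_a3"))]),
               rep(0, 6))
})

test_that("moment conventions: non-excess kurtosis and standardized skewness", {
  set.seed(9)
  x <- rnorm(200000)
  ch <- fake_session(n = 1200)
  w <- extract_window(assemble_variables(ch), 100, 10)
  w$values[, "offset"] <- x[1:100]
  # large-sample check on the raw helpers through local_features
  big <- list(values = cbind(offset = x, rel_steering = x, foot = x,
                             distance = x),
              times = seq_along(x) / 10)
  f <- local_features(big)
  expect_equal(unname(f["offset_kurtosis"]), 3, tolerance = 0.2)
  expect_equal(unname(f["offset_skewness"]), 0, tolerance = 0.2)
})

test_that("no feature depends on samples at or after the probe instant", {
  ch <- assemble_variables(tiny_cohort()$sessions[[3]])
  probe <- 240
  before <- local_features(extract_window(ch, probe, 10))
  mutated <- ch
  idx <- mutated$times >= probe
  mutated$values[idx, ] <- 999
  after <- local_features(extract_window(mutated, probe, 10))
  expect_identical(before, after)
})

test_that("features transform predictably under channel scaling", {
  ch <- assemble_variables(tiny_cohort()$sessions[[2]])
  w <- extract_window(ch, 300, 10)
  f1 <- local_features(w)
  w2 <- w
  w2$values <- w$values * 3
  f2 <- local_features(w2)
  lin <- c("mean", "std", "max", "min", "median", "intercept", "slope", "diff")
  for (v in c("offset", "distance")) {
    expect_equal(unname(f2[paste0(v, "_", lin)]),
                 unname(3 * f1[paste0(v, "_", lin)]), tolerance = 1e-10)
    inv <- c("r_squared", "skewness", "kurtosis", "entropy", paste0("ar", 1:5))
    expect_equal(unname(f2[paste0(v, "_", inv)]),
                 unname(f1[paste0(v, "_", inv)]), tolerance = 1e-8)
    expect_equal(unname(f2[paste0(v, "_var_cd1")]),
                 unname(9 * f1[paste0(v, "_var_cd1")]), tolerance = 1e-10)
  }
})

test_that("the feature matrix has one row per answered probe", {
  co <- tiny_cohort()
  fm <- build_feature_matrix(co, NULL, "both", 10)
  expect_equal(nrow(fm), 26)
  expect_length(feature_cols(fm), 100)
  expect_equal(length(grep("^global_", names(fm))), 16)
  fml <- build_feature_matrix(co$sessions[[1]], NULL, "local", 5)
  expect_length(feature_cols(fml), 84)
  expect_equal(nrow(fml), sum(co$sessions[[1]]$probes$response != "none"))
  # global features constant within participant
  fg <- build_feature_matrix(co, NULL, "global")
  expect_length(feature_cols(fg), 16)
  expect_equal(nrow(unique(fg[fg$participant_id == 1, feature_cols(fg)])), 1)
})
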