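test_that("MW-proportion grouping uses the literal 0.33/0.67 thresholds", {
  mk <- function(n_present, n_total, id = 1) data.frame(
    participant_id = id, probe_time_s = seq_len(n_total) * 60,
    response = rep(c("present", "absent"),
                   c(n_present, n_total - n_present)),
    true_state = "present")
  pt <- rbind(mk(16, 24, 1), mk(20, 24, 2), mk(8, 24, 3), mk(2, 24, 4))
  g <- assign_groups(pt)
  expect_identical(g$group, c("medium", "extreme", "medium", "extreme"))
  # non-responses are excluded from the denominator
  pt2 <- mk(16, 24, 1)
  pt2$response[17:24] <- "none"
  expect_equal(assign_groups(pt2)$mw_proportion, 1)
})

test_that("configuration grids enumerate the documented design", {
  expect_equal(nrow(enumerate_grid("driver_independent", "global")), 108)
  expect_equal(nrow(enumerate_grid("driver_independent", "local")), 324)
  expect_equal(nrow(enumerate_grid("driver_independent", "both")), 324)
  g <- enumerate_grid("driver_dependent")
  expect_equal(nrow(g), 54)
  expect_true(all(g$classifier == "svm_linear"))
  expect_equal(anyDuplicated(g$config_id), 0)
  # deterministic enumeration order
  expect_identical(g, enumerate_grid("driver_dependent"))
})

test_that("all six classifiers separate well-separated Gaussian classes", {
  set.seed(20)
  n <- 200
  xtr <- rbind(matrix(rnorm(n * 2), n), matrix(rnorm(n * 2) + 5, n))
  ytr <- rep(c("absent", "present"), each = n)
  xte <- rbind(matrix(rnorm(100), 50), matrix(rnorm(100) + 5, 50))
  yte <- rep(c("absent", "present"), each = 50)
  for (clf in c("svm_linear", "decision_tree", "adaboost_trees_100",
                "knn", "discriminant", "naive_bayes")) {
    pred <- train_and_predict(clf, xtr, ytr, xte, seed = 1)
    expect_gte(mean(pred == yte), 0.95)
  }
})

test_that("degenerate training data yields majority-class predictions", {
  xtr <- matrix(rnorm(20), 10)
  pred <- train_and_predict("svm_linear", xtr, rep("present", 10),
                            matrix(rnorm(6), 3))
  expect_true(all(pred == "present"))
  # 1-NN predicting its own training set is perfect
  ytr <- rep(c("absent", "present"), 5)
  expect_equal(mean(train_and_predict("knn", xtr, ytr, xtr) == ytr), 1)
  # regularized discriminant fallback under a singular pooled covariance
  xs <- cbind(c(rep(0, 5), rep(1, 5)), 0)
  pred <- train_and_predict("discriminant", xs, ytr[order(xs[, 1])],
                            xs)
  expect_length(pred, 10)
})

test_that("LOPO keeps the held-out participant unseen and covers each row once", {
  X <- synth_features(n_per_class = 55, p = 6, shift = 2, n_participants = 11,
                      seed = 21)
  cfg <- model_config("driver_independent", feature_set = "local",
                      variance_level = 80, classifier = "svm_linear")
  cv <- lopo_cv(X, cfg, seed = 2)
  expect_length(cv$fold_acc, 11)
  expect_equal(nrow(cv$predictions), nrow(X))
  expect_equal(sort(table(cv$predictions$participant_id)),
               sort(table(X$participant_id)), ignore_attr = TRUE)
  # determinism
  cv2 <- lopo_cv(X, cfg, seed = 2)
  expect_identical(cv$predictions$pred, cv2$predictions$pred)
})

test_that("LOPO recovers a perfectly separable labeling", {
  X <- synth_features(n_per_class = 30, p = 3, n_participants = 6, seed = 22)
  X$f1 <- as.numeric(X$label == "present") + rnorm(60, sd = 0.01)
  cfg <- model_config("driver_independent", feature_set = "local",
                      variance_level = 100, classifier = "svm_linear")
  cv <- lopo_cv(X, cfg, seed = 3)
  expect_equal(mean(cv$predictions$pred == cv$predictions$label), 1)
})

test_that("LOPO kappa is centred at zero when labels are pure noise", {
  kappas <- sapply(1:20, function(s) {
    X <- synth_features(n_per_class = 30, p = 4, n_participants = 6,
                        seed = 100 + s)
    cfg <- model_config("driver_independent", feature_set = "local",
                        variance_level = 100, classifier = "svm_linear",
                        alpha = 0.999)
    cv <- lopo_cv(X, cfg, seed = s)
    evaluate_cv(cv)$kappa
  })
  expect_lt(abs(mean(kappas)), 0.1)
})

test_that("repeated stratified k-fold honors the partition contract", {
  X <- synth_features(n_per_class = 30, p = 5,
                      seed = 23)[c(1:12, 31:41), ]   # 12 absent, 11 present
  X$f1 <- as.numeric(X$label == "present") + rnorm(23, sd = 0.01)
  cfg <- model_config("driver_dependent", variance_level = 100)
  cv <- repeated_kfold_cv(X, cfg, repeats = 4, folds = 5, seed = 5)
  expect_length(cv$fold_acc, 20)
  # each row tested exactly once per repetition
  for (r in 1:4) {
    pr <- cv$predictions[cv$predictions$repetition == r, ]
    expect_equal(nrow(pr), 23)
  }
  # fold sizes balanced within one row
  set.seed((5 * 131 + 1 * 7919) %% 2147483647)
  f <- mindwander:::.stratified_folds(X$label, 5)
  expect_equal(sort(as.numeric(table(f))), c(4, 4, 5, 5, 5))
  # separable input classified perfectly
  expect_equal(mean(cv$fold_acc), 1)
  expect_error(repeated_kfold_cv(X[1:4, ], cfg), "fewer rows")
})

test_that("the dependent grid runner matches the per-config estimator", {
  co <- tiny_cohort()
  mixed <- vapply(co$sessions, function(s) {
    tab <- table(s$probes$response[s$probes$response != "none"])
    length(tab) == 2 && min(tab) >= 2
  }, TRUE)
  s <- co$sessions[[which(mixed)[1]]]
  gr <- run_dependent_grid(s, windows = 5, preprocess = "zscore",
                           variance_levels = c(50, 100), seed = 9)
  ch <- assemble_variables(s)
  m <- fit_transform(list(ch), "zscore", seed = 9,
                     fit_scope = "per_participant")
  fm <- build_feature_matrix(list(s), m, "local", 5)
  cfg <- model_config("driver_dependent", "zscore", "local", 5, 100)
  cv <- repeated_kfold_cv(fm, cfg, seed = 9)
  expect_equal(gr$results[["driver_dependent/local/zscore/w5/v100/svm_linear"]]$fold_acc,
               cv$fold_acc)
})

test_that("grid runners report one evaluation row per configuration", {
  co <- tiny_cohort()
  gi <- run_independent_grid(co$sessions, "global", preprocess = "none",
                             variance_levels = c(50, 100),
                             classifiers = c("knn", "naive_bayes"), seed = 4)
  expect_equal(nrow(gi$evals), 4)
  expect_true(all(gi$evals$kappa >= -1 & gi$evals$kappa <= 1))
  rep <- build_report(gi, "driver_independent")
  expect_equal(rep$friedman$df, 3)
  expect_s3_class(rep$best, "data.frame")
  expect_equal(rep$best$kappa, max(gi$evals$kappa))
})
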