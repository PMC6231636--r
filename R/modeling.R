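.classifiers <- c("svm_linear", "decision_tree", "adaboost_trees_100",
                  "knn", "discriminant", "naive_bayes")

#' One cell of the configuration grid
#'
#' @param mode `"driver_independent"` or `"driver_dependent"`.
#' @param preprocess channel transform kind: `"none"`, `"zscore"`, `"pica"`.
#' @param feature_set `"global"`, `"local"`, or `"both"` (driver-dependent
#'   models use local features only).
#' @param window_s pre-probe window length, seconds (`NA` for global-only).
#' @param variance_level PCA variance level in percent.
#' @param classifier one of the six classifier families.
#' @param alpha univariate screen level (driver-independent selection).
#' @param fraction CFS fraction (driver-dependent selection).
#' @return an object of class `mw_config` with a unique `id` string.
#' @export
model_config <- function(mode = c("driver_independent", "driver_dependent"),
                         preprocess = c("none", "zscore", "pica"),
                         feature_set = c("local", "global", "both"),
                         window_s = 10, variance_level = 100,
                         classifier = "svm_linear",
                         alpha = 0.05, fraction = 0.5) {
  mode <- match.arg(mode)
  preprocess <- match.arg(preprocess)
  feature_set <- match.arg(feature_set)
  classifier <- match.arg(classifier, .classifiers)
  if (feature_set == "global") window_s <- NA_real_
  cfg <- list(mode = mode, preprocess = preprocess, feature_set = feature_set,
              window_s = window_s, variance_level = variance_level,
              classifier = classifier, alpha = alpha, fraction = fraction)
  cfg$id <- paste(mode, feature_set, preprocess,
                  ifelse(is.na(window_s), "w-", paste0("w", window_s)),
                  paste0("v", variance_level), classifier, sep = "/")
  structure(cfg, class = "mw_config")
}

#' Enumerate a configuration grid
#'
#' Driver-independent grids cross 3 preprocessing methods, 6 PCA variance
#' levels and 6 classifiers, with 3 window sizes when local features are
#' involved (108 global-only configurations, 324 otherwise). The
#' driver-dependent grid crosses 3 preprocessing methods, 3 window sizes and
#' 6 variance levels with the linear-kernel SVM (54 configurations). The
#' enumeration order is deterministic.
#'
#' @param mode `"driver_independent"` or `"driver_dependent"`.
#' @param feature_set feature set for the driver-independent mode.
#' @param windows window lengths, seconds.
#' @param preprocess preprocessing kinds.
#' @param variance_levels PCA variance levels, percent.
#' @param classifiers classifier families (driver-dependent: linear SVM).
#' @return data frame of configurations, one row each, with a `config_id`.
#' @export
enumerate_grid <- function(mode = c("driver_independent", "driver_dependent"),
                           feature_set = c("local", "global", "both"),
                           windows = c(5, 10, 15),
                           preprocess = c("none", "zscore", "pica"),
                           variance_levels = seq(50, 100, by = 10),
                           classifiers = NULL) {
  mode <- match.arg(mode)
  feature_set <- match.arg(feature_set)
  if (mode == "driver_dependent") {
    feature_set <- "local"
    classifiers <- classifiers %||% "svm_linear"
  } else {
    classifiers <- classifiers %||% .classifiers
  }
  if (feature_set == "global") windows <- NA_real_
  g <- expand.grid(classifier = classifiers, variance_level = variance_levels,
                   window_s = windows, preprocess = preprocess,
                   stringsAsFactors = FALSE)
  g <- g[, c("preprocess", "window_s", "variance_level", "classifier")]
  g$mode <- mode
  g$feature_set <- feature_set
  g$config_id <- paste(g$mode, g$feature_set, g$preprocess,
                       ifelse(is.na(g$window_s), "w-", paste0("w", g$window_s)),
                       paste0("v", g$variance_level), g$classifier, sep = "/")
  rownames(g) <- NULL
  g
}

#' Assign participants to MW-proportion groups
#'
#' The MW proportion is the share of answered probes reported MW-present.
#' Participants with proportion above 0.67 or below 0.33 form the extreme
#' (high/low) group; those strictly between form the medium group. Boundary
#' values (exactly 0.33 or 0.67) are assigned to the medium group.
#'
#' @param probes a probe table ([probe_table()]) or an `mw_cohort`.
#' @return data frame `participant_id`, `mw_proportion`, `group`.
#' @export
assign_groups <- function(probes) {
  if (inherits(probes, "mw_cohort")) probes <- probe_table(probes)
  answered <- probes[probes$response != "none", , drop = FALSE]
  agg <- stats::aggregate(list(mw_proportion = answered$response == "present"),
                          by = list(participant_id = answered$participant_id),
                          FUN = mean)
  agg$group <- ifelse(agg$mw_proportion > 0.67 | agg$mw_proportion < 0.33,
                      "extreme", "medium")
  agg
}

# ---- classifiers -----------------------------------------------------------

.majority_pred <- function(ytr, n) {
  tab <- table(mw_factor(ytr))
  lev <- names(tab)[tab == max(tab)]
  pred <- if (length(lev) > 1) "absent" else lev   # tie -> negative class
  mw_factor(rep(pred, n))
}

# regularized linear discriminant fallback for singular class covariances
.lda_regularized <- function(xtr, ytr, xte) {
  lev <- .mw_levels
  mu <- lapply(lev, function(l) colMeans(xtr[ytr == l, , drop = FALSE]))
  ctr <- lapply(lev, function(l) scale(xtr[ytr == l, , drop = FALSE],
                                       center = TRUE, scale = FALSE))
  S <- (crossprod(ctr[[1]]) + crossprod(ctr[[2]])) / (nrow(xtr) - 2)
  S <- S + diag(mean(diag(S)) * 1e-6 + 1e-12, ncol(S))
  Si <- solve(S)
  pri <- as.numeric(table(factor(ytr, lev))) / length(ytr)
  score <- sapply(seq_along(lev), function(k)
    xte %*% (Si %*% mu[[k]]) -
      0.5 * drop(t(mu[[k]]) %*% Si %*% mu[[k]]) + log(pri[k]))
  mw_factor(lev[max.col(score, ties.method = "first")])  # tie -> absent
}

.ada_boost_predict <- function(xtr, ytr, xte, n_learners = 100) {
  df <- as.data.frame(xtr)
  df$.y <- ytr
  dfe <- as.data.frame(xte)
  names(dfe) <- names(df)[seq_len(ncol(xte))]
  n <- nrow(df)
  w <- rep(1 / n, n)
  ysign <- ifelse(ytr == "present", 1, -1)
  score <- rep(0, nrow(xte))
  any_learner <- FALSE
  for (m in seq_len(n_learners)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class")
    ptr <- predict(fit, df, type = "class")
    err <- sum(w[ptr != ytr])
    if (err >= 0.5) break
    any_learner <- TRUE
    alpha <- if (err <= 0) 10 else 0.5 * log((1 - err) / err)
    pte <- predict(fit, dfe, type = "class")
    score <- score + alpha * ifelse(pte == "present", 1, -1)
    if (err <= 0) break
    w <- w * exp(-alpha * ysign * ifelse(ptr == "present", 1, -1))
    w <- w / sum(w)
  }
  if (!any_learner) return(.majority_pred(ytr, nrow(xte)))
  mw_factor(ifelse(score > 0, "present", "absent"))   # tie -> absent
}

#' Train one classifier and predict test rows
#'
#' The six families: linear-kernel SVM, decision tree, AdaBoost.M1 ensemble
#' of 100 tree learners, 1-nearest-neighbor, linear discriminant analysis
#' (with a regularized fallback when the pooled covariance is singular), and
#' Gaussian naive Bayes. Apart from the stated settings each learner runs at
#' its library defaults. Single-class training data (or an empty feature
#' matrix) yields constant majority-class predictions, ties broken toward
#' MW-absent. Deterministic given `seed`.
#'
#' @param classifier one of
#'   `svm_linear, decision_tree, adaboost_trees_100, knn, discriminant,
#'   naive_bayes`.
#' @param xtr,xte numeric training/test matrices (same columns).
#' @param ytr training labels.
#' @param seed integer seed.
#' @return factor of predicted labels for the test rows.
#' @export
train_and_predict <- function(classifier, xtr, ytr, xte, seed = 1L) {
  classifier <- match.arg(classifier, .classifiers)
  xtr <- as.matrix(xtr); xte <- as.matrix(xte)
  ytr <- mw_factor(ytr)
  if (ncol(xtr) == 0 || nlevels(droplevels(ytr)) < 2 || nrow(xtr) < 2)
    return(.majority_pred(ytr, nrow(xte)))
  if (is.null(colnames(xtr))) colnames(xtr) <- paste0("V", seq_len(ncol(xtr)))
  colnames(xte) <- colnames(xtr)
  set.seed(seed)
  pred <- switch(classifier,
    svm_linear = {
      fit <- e1071::svm(xtr, ytr, kernel = "linear", scale = FALSE)
      predict(fit, xte)
    },
    decision_tree = {
      df <- as.data.frame(xtr); df$.y <- ytr
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      predict(fit, as.data.frame(xte), type = "class")
    },
    adaboost_trees_100 = .ada_boost_predict(xtr, ytr, xte, 100),
    knn = class::knn(xtr, xte, ytr, k = 1),
    discriminant = tryCatch({
      fit <- suppressWarnings(MASS::lda(xtr, grouping = ytr))
      predict(fit, xte)$class
    }, error = function(e) .lda_regularized(xtr, ytr, xte)),
    naive_bayes = {
      fit <- e1071::naiveBayes(as.data.frame(xtr), ytr)
      predict(fit, as.data.frame(xte))
    })
  mw_factor(pred)
}

# ---- fold model fitting (selection + projection on training rows only) -----

#' Fit the per-fold selection and projection models
#'
#' Driver-independent folds use the univariate screen; driver-dependent
#' folds the CFS ranking. The projection is fitted on the training rows of
#' the kept features. An empty univariate selection returns `projection =
#' NULL`, which downstream scores the fold as majority-class prediction.
#'
#' @param train training-fold feature matrix.
#' @param config an `mw_config`.
#' @return list with `selection` and `projection` (or `NULL`).
#' @export
fit_fold_models <- function(train, config) {
  sel <- tryCatch({
    if (config$mode == "driver_dependent")
      cfs_select(train, fraction = config$fraction)
    else
      univariate_select(train, alpha = config$alpha)
  }, error = function(e)    # e.g. single-class training fold -> majority path
    structure(list(method = "degenerate", keep = character(0)),
              class = "mw_selection"))
  if (!length(sel$keep)) return(list(selection = sel, projection = NULL))
  proj <- suppressWarnings(
    tryCatch(fit_projection(train, config$variance_level, keep = sel$keep),
             error = function(e) NULL))
  list(selection = sel, projection = proj)
}

.fold_predict <- function(models, train, test, config, seed) {
  ytr <- mw_factor(train$label)
  if (is.null(models$projection)) return(.majority_pred(ytr, nrow(test)))
  xtr <- apply_projection(train, models$projection)
  xte <- apply_projection(test, models$projection)
  train_and_predict(config$classifier, xtr, ytr, xte, seed = seed)
}

# ---- cross-validation ------------------------------------------------------

.new_cv_result <- function(config, fold_ids, fold_acc, predictions) {
  structure(list(config = config, fold_ids = fold_ids, fold_acc = fold_acc,
                 predictions = predictions), class = "mw_cv_result")
}

#' @export
print.mw_cv_result <- function(x, ...) {
  cat(sprintf("<mw_cv_result> %s: %d folds, pooled accuracy %.3f\n",
              x$config$id, length(x$fold_acc),
              mean(x$predictions$label == x$predictions$pred)))
  invisible(x)
}

#' Leave-one-participant-out cross-validation
#'
#' One fold per participant: all of that participant's rows are the test
#' set, every other participant's rows the training set. Selection and
#' projection are refit on the training rows of each fold. When
#' `fold_features` is supplied (feature matrices whose channel transform was
#' fitted excluding the held-out participant), the fold uses its own matrix,
#' so the channel preprocessing is also leakage-free. Every fold asserts
#' that the held-out participant contributes no training rows.
#'
#' @param features feature matrix with `participant_id` and `label`.
#' @param config an `mw_config` (driver-independent).
#' @param fold_features optional named list (participant id as character) of
#'   per-fold feature matrices.
#' @param seed integer seed.
#' @return an `mw_cv_result` with per-fold accuracies and pooled out-of-fold
#'   predictions.
#' @export
lopo_cv <- function(features, config, fold_features = NULL, seed = 1L) {
  pids <- unique(features$participant_id)
  if (length(pids) < 2) stop("need at least 2 participants for LOPO")
  fold_acc <- numeric(length(pids))
  preds <- vector("list", length(pids))
  for (i in seq_along(pids)) {
    p <- pids[i]
    mat <- if (!is.null(fold_features)) fold_features[[as.character(p)]] else features
    train <- mat[mat$participant_id != p, , drop = FALSE]
    test <- mat[mat$participant_id == p, , drop = FALSE]
    stopifnot(nrow(test) > 0, !any(test$participant_id %in% train$participant_id))
    models <- fit_fold_models(train, config)
    pr <- .fold_predict(models, train, test, config, seed = seed + i)
    fold_acc[i] <- mean(pr == test$label)
    preds[[i]] <- data.frame(participant_id = test$participant_id,
                             label = test$label, pred = pr)
  }
  .new_cv_result(config, pids, fold_acc, do.call(rbind, preds))
}

# stratified fold assignment: shuffle within class, deal cyclically across
# classes so fold sizes differ by at most one
.stratified_folds <- function(y, folds) {
  ord <- unlist(lapply(levels(y), function(l) sample(which(y == l))))
  f <- integer(length(y))
  f[ord] <- rep_len(seq_len(folds), length(y))
  f
}

#' Repeated stratified k-fold cross-validation (driver-dependent)
#'
#' `repeats` independent stratified partitions of one participant's probes
#' into `folds` folds (4 x 5 by default, giving 20 fold evaluations).
#' Selection (CFS) and projection are refit on the training part of every
#' fold. The fold assignment depends only on `(seed, repeat, labels)` — not
#' on the configuration — so fold accuracies are paired across
#' configurations, as the Friedman comparison requires.
#'
#' @param features one participant's feature matrix.
#' @param config an `mw_config` (driver-dependent).
#' @param repeats number of repetitions (default 4).
#' @param folds folds per repetition (default 5).
#' @param seed integer seed.
#' @return an `mw_cv_result`; `fold_acc` has `repeats * folds` entries and
#'   the pooled predictions contain each row once per repetition.
#' @export
repeated_kfold_cv <- function(features, config, repeats = 4, folds = 5,
                              seed = 1L) {
  .repeated_kfold_shared(features, list(config), repeats, folds, seed)[[1]]
}

# fold loop shared across configs that differ only in projection/classifier:
# the fold assignment and the (identical) feature selection are computed once
# per fold, so a grid over variance levels pays for selection only once.
# Every stochastic step is locally seeded, so results are identical to
# running repeated_kfold_cv per config.
.repeated_kfold_shared <- function(features, configs, repeats = 4, folds = 5,
                                   seed = 1L) {
  y <- mw_factor(features$label)
  if (nrow(features) < folds) stop("fewer rows than folds")
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  nc <- length(configs)
  fold_acc <- matrix(NA_real_, repeats * folds, nc)
  preds <- lapply(seq_len(nc), function(i) list())
  fi <- 0L
  for (r in seq_len(repeats)) {
    set.seed((seed * 131 + r * 7919) %% 2147483647)
    f <- .stratified_folds(y, folds)
    for (k in seq_len(folds)) {
      fi <- fi + 1L
      train <- features[f != k, , drop = FALSE]
      test <- features[f == k, , drop = FALSE]
      sel <- tryCatch({
        if (configs[[1]]$mode == "driver_dependent")
          cfs_select(train, fraction = configs[[1]]$fraction)
        else
          univariate_select(train, alpha = configs[[1]]$alpha)
      }, error = function(e)
        structure(list(method = "degenerate", keep = character(0)),
                  class = "mw_selection"))
      for (i in seq_len(nc)) {
        cfg <- configs[[i]]
        proj <- if (!length(sel$keep)) NULL else suppressWarnings(
          tryCatch(fit_projection(train, cfg$variance_level, keep = sel$keep),
                   error = function(e) NULL))
        pr <- .fold_predict(list(selection = sel, projection = proj),
                            train, test, cfg, seed = seed + r * folds + k)
        fold_acc[fi, i] <- mean(pr == test$label)
        preds[[i]][[fi]] <- data.frame(
          participant_id = test$participant_id, label = test$label, pred = pr,
          repetition = r)
      }
    }
  }
  lapply(seq_len(nc), function(i)
    .new_cv_result(configs[[i]], paste0("rep", seq_len(repeats)),
                   fold_acc[, i], do.call(rbind, preds[[i]])))
}

# ---- grid runners ----------------------------------------------------------

#' Run the driver-independent grid for one participant group
#'
#' For each preprocessing kind the channel transform is fitted per LOPO fold
#' on the training participants only (default) or once on the whole group
#' (`paper_faithful = TRUE`), the feature matrices are built, and every
#' (window, variance level, classifier) combination is cross-validated.
#'
#' @param sessions list of `mw_session` (one group) or an `mw_cohort`.
#' @param feature_set `"global"`, `"local"`, or `"both"`.
#' @param windows window lengths, seconds.
#' @param preprocess preprocessing kinds to run.
#' @param variance_levels PCA variance levels.
#' @param classifiers classifier families.
#' @param alpha univariate screen level.
#' @param paper_faithful fit channel transforms (and hence features) once on
#'   the full group instead of per fold.
#' @param n_perm permutations for kappa significance (0 = skip).
#' @param seed integer seed.
#' @param n_bins entropy bins.
#' @return list with the `grid` (configurations), `results` (list of
#'   `mw_cv_result`), and `evals` (data frame of metrics, one row per
#'   configuration).
#' @export
run_independent_grid <- function(sessions,
                                 feature_set = c("local", "global", "both"),
                                 windows = c(5, 10, 15),
                                 preprocess = c("none", "zscore", "pica"),
                                 variance_levels = seq(50, 100, by = 10),
                                 classifiers = .classifiers,
                                 alpha = 0.05, paper_faithful = FALSE,
                                 n_perm = 0, seed = 1L, n_bins = 10) {
  feature_set <- match.arg(feature_set)
  if (inherits(sessions, "mw_cohort")) sessions <- sessions$sessions
  pids <- vapply(sessions, function(s) s$participant_id, 1)
  grid <- enumerate_grid("driver_independent", feature_set, windows,
                         preprocess, variance_levels, classifiers)
  eff_windows <- if (feature_set == "global") NA_real_ else windows

  # per (kind, window): named list participant -> feature matrix with the
  # transform fitted excluding that participant (or one shared matrix)
  fmat <- list()
  for (kind in preprocess) {
    channels <- lapply(sessions, assemble_variables)
    shared <- NULL
    if (paper_faithful || kind == "none")
      shared <- fit_transform(channels, kind, seed = seed)
    for (w in eff_windows) {
      key <- paste(kind, w, sep = "|")
      if (!is.null(shared)) {
        fm <- build_feature_matrix(sessions, shared, feature_set,
                                   window_length_s = if (is.na(w)) 10 else w,
                                   n_bins = n_bins)
        fmat[[key]] <- list(shared = fm)
      } else {
        per_fold <- lapply(seq_along(sessions), function(i) {
          m <- fit_transform(channels[-i], kind, seed = seed)
          build_feature_matrix(sessions, m, feature_set,
                               window_length_s = if (is.na(w)) 10 else w,
                               n_bins = n_bins)
        })
        names(per_fold) <- as.character(pids)
        fmat[[key]] <- per_fold
      }
    }
  }

  results <- vector("list", nrow(grid))
  evals <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- model_config("driver_independent", grid$preprocess[g], feature_set,
                        window_s = grid$window_s[g],
                        variance_level = grid$variance_level[g],
                        classifier = grid$classifier[g], alpha = alpha)
    key <- paste(grid$preprocess[g], grid$window_s[g], sep = "|")
    fs <- fmat[[key]]
    cv <- tryCatch({
      if (!is.null(fs$shared))
        lopo_cv(fs$shared, cfg, seed = seed)
      else
        lopo_cv(fs[[1]], cfg, fold_features = fs, seed = seed)
    }, error = function(e) e)
    if (inherits(cv, "error")) {
      results[[g]] <- cv
      next
    }
    results[[g]] <- cv
    ev <- evaluate_cv(cv, n_perm = n_perm, seed = seed)
    evals[[g]] <- data.frame(config_id = cfg$id, preprocess = grid$preprocess[g],
                             window_s = grid$window_s[g],
                             variance_level = grid$variance_level[g],
                             classifier = grid$classifier[g],
                             kappa = ev$kappa, kappa_p = ev$kappa_p,
                             accuracy = ev$accuracy, precision = ev$precision,
                             recall = ev$recall)
  }
  list(grid = grid, results = results,
       evals = do.call(rbind, evals), feature_set = feature_set)
}

#' Run the driver-dependent grid for one participant
#'
#' Channel transforms are fitted on the participant's own session
#' (per-participant fit scope); for every (preprocess, window) the local
#' feature matrix is built once and each PCA variance level is scored with
#' repeated stratified k-fold cross-validation and the configured classifier
#' (linear-kernel SVM by default).
#'
#' @param session one `mw_session`.
#' @inheritParams run_independent_grid
#' @param fraction CFS fraction of features to keep.
#' @param classifier classifier family (default linear SVM).
#' @param repeats,folds cross-validation layout (default 4 x 5).
#' @return list with `grid`, `results`, `evals` as in
#'   [run_independent_grid()].
#' @export
run_dependent_grid <- function(session, windows = c(5, 10, 15),
                               preprocess = c("none", "zscore", "pica"),
                               variance_levels = seq(50, 100, by = 10),
                               fraction = 0.5, classifier = "svm_linear",
                               repeats = 4, folds = 5, n_perm = 0,
                               seed = 1L, n_bins = 10) {
  stopifnot(inherits(session, "mw_session"))
  grid <- enumerate_grid("driver_dependent", windows = windows,
                         preprocess = preprocess,
                         variance_levels = variance_levels,
                         classifiers = classifier)
  ch <- assemble_variables(session)
  results <- stats::setNames(vector("list", nrow(grid)), grid$config_id)
  for (kind in preprocess) {
    m <- fit_transform(list(ch), kind, seed = seed, fit_scope = "per_participant")
    for (w in windows) {
      fm <- build_feature_matrix(list(session), m, "local", w, n_bins = n_bins)
      sub <- which(grid$preprocess == kind & grid$window_s == w)
      cfgs <- lapply(sub, function(g)
        model_config("driver_dependent", kind, "local", window_s = w,
                     variance_level = grid$variance_level[g],
                     classifier = grid$classifier[g], fraction = fraction))
      shared <- tryCatch(
        .repeated_kfold_shared(fm, cfgs, repeats, folds, seed = seed),
        error = function(e) e)
      for (j in seq_along(sub))
        results[[sub[j]]] <- if (inherits(shared, "error")) shared else shared[[j]]
    }
  }
  evals <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cv <- results[[g]]
    if (inherits(cv, "error")) next
    cfg <- cv$config
    ev <- evaluate_cv(cv, n_perm = n_perm, seed = seed)
    evals[[g]] <- data.frame(config_id = cfg$id, preprocess = grid$preprocess[g],
                             window_s = grid$window_s[g],
                             variance_level = grid$variance_level[g],
                             classifier = grid$classifier[g],
                             kappa = ev$kappa, kappa_p = ev$kappa_p,
                             accuracy = ev$accuracy, precision = ev$precision,
                             recall = ev$recall)
  }
  list(grid = grid, results = results, evals = do.call(rbind, evals),
       participant_id = session$participant_id)
}

#' Run a full configuration grid
#'
#' Dispatcher over the two modeling modes: driver-independent grids run on a
#' participant group under leave-one-participant-out cross-validation;
#' driver-dependent grids run per medium-MW participant under repeated
#' stratified k-fold cross-validation.
#'
#' @param cohort an `mw_cohort` (or list of sessions).
#' @param mode `"driver_independent"` or `"driver_dependent"`.
#' @param group which MW-proportion group to model (`"medium"`,
#'   `"extreme"`); driver-dependent modeling always uses the medium group.
#' @param ... passed to [run_independent_grid()] or [run_dependent_grid()].
#' @return for driver-independent, one grid-result list; for
#'   driver-dependent, a named list of per-participant grid results.
#' @export
run_grid <- function(cohort, mode = c("driver_independent", "driver_dependent"),
                     group = c("medium", "extreme"), ...) {
  mode <- match.arg(mode)
  group <- match.arg(group)
  sessions <- if (inherits(cohort, "mw_cohort")) cohort$sessions else cohort
  ga <- assign_groups(probe_table(sessions))
  keep <- ga$participant_id[ga$group == group]
  sessions <- Filter(function(s) s$participant_id %in% keep, sessions)
  if (!length(sessions)) stop("no participants in the requested group")
  if (mode == "driver_independent") {
    run_independent_grid(sessions, ...)
  } else {
    out <- lapply(sessions, function(s)
      tryCatch(run_dependent_grid(s, ...), error = function(e) e))
    names(out) <- vapply(sessions, function(s) as.character(s$participant_id), "")
    out[!vapply(out, inherits, TRUE, "error")]
  }
}

# ---- reporting -------------------------------------------------------------

.best_row <- function(evals) {
  ord <- order(-evals$kappa, -evals$accuracy, evals$config_id)
  evals[ord[1], , drop = FALSE]
}

#' Build the result report for a completed grid
#'
#' For a driver-independent grid: the best-kappa configuration (ties broken
#' by accuracy, then config id), the Friedman comparison of all
#' configurations on the per-fold accuracies, the Nemenyi flag saying
#' whether the best configuration significantly beats the others, the sign
#' test on the configuration kappas and their median. For driver-dependent
#' grids (a named per-participant list): one such row per participant plus a
#' mean row across participants' best models.
#'
#' @param grid_result output of [run_independent_grid()] /
#'   [run_dependent_grid()] / [run_grid()].
#' @param mode which report to build.
#' @return list with `best` (data frame), `friedman`, `posthoc`,
#'   `sign_test_p`, `median_kappa` (per participant for the dependent mode).
#' @export
build_report <- function(grid_result,
                         mode = c("driver_independent", "driver_dependent")) {
  mode <- match.arg(mode)
  if (mode == "driver_independent") {
    evals <- grid_result$evals
    if (is.null(evals) || !nrow(evals)) stop("empty grid results")
    ok <- !vapply(grid_result$results, inherits, TRUE, "error")
    accs <- sapply(grid_result$results[ok], function(r) r$fold_acc)
    fr <- friedman_compare(accs)
    ph <- if (fr$p < 0.05) posthoc_pairs(fr) else NULL
    best <- .best_row(evals)
    best_beats <- if (!is.null(ph)) {
      idx <- which(evals$config_id == best$config_id)
      top_rank <- fr$mean_ranks[idx]
      any(abs(top_rank - fr$mean_ranks[-idx]) > ph$critical_difference)
    } else FALSE
    list(best = best, friedman = fr, posthoc = ph,
         best_beats_others = best_beats,
         sign_test_p = sign_test_median_gt0(evals$kappa),
         median_kappa = stats::median(evals$kappa),
         kappas = evals$kappa)
  } else {
    if (!length(grid_result)) stop("empty grid results")
    rows <- list(); fried <- list(); signp <- c(); medk <- c()
    for (pid in names(grid_result)) {
      gr <- grid_result[[pid]]
      ok <- !vapply(gr$results, inherits, TRUE, "error")
      evals <- gr$evals
      best <- .best_row(evals)
      best$participant_id <- pid
      rows[[pid]] <- best
      accs <- sapply(gr$results[ok], function(r) r$fold_acc)
      fried[[pid]] <- friedman_compare(accs)
      signp[pid] <- sign_test_median_gt0(evals$kappa)
      medk[pid] <- stats::median(evals$kappa)
    }
    best <- do.call(rbind, rows)
    mean_row <- data.frame(participant_id = "mean",
                           accuracy = mean(best$accuracy),
                           kappa = mean(best$kappa),
                           precision = mean(best$precision),
                           recall = mean(best$recall))
    list(best = best, mean = mean_row, friedman = fried,
         sign_test_p = signp, median_kappa = medk)
  }
}
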