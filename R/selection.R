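#' Univariate feature screen (t-test AND rank-sum)
#'
#' A feature is kept iff both the unequal-variance two-sample two-tailed
#' t-test and the Wilcoxon rank-sum test reject at level `alpha`.
#' Zero-variance features are excluded (both tests are undefined for them).
#' The intersection of the two tests makes the per-feature false-keep
#' probability at most `alpha` under the null.
#'
#' @param features a labeled feature matrix from [build_feature_matrix()],
#'   or any data frame with a `label` column and numeric feature columns.
#' @param alpha significance level (default 0.05).
#' @return an object of class `mw_selection` with the kept feature names (in
#'   input column order) and both p-value vectors.
#' @export
univariate_select <- function(features, alpha = 0.05) {
  y <- mw_factor(features$label)
  if (nlevels(droplevels(y)) < 2 || min(table(y)) < 2)
    stop("both classes must be present with at least 2 rows each")
  cols <- feature_cols(features)
  X <- feature_matrix_values(features, cols)
  a <- X[y == "absent", , drop = FALSE]
  p <- X[y == "present", , drop = FALSE]
  pt <- pw <- rep(NA_real_, length(cols))
  for (j in seq_along(cols)) {
    if (stats::sd(X[, j]) == 0) next
    pt[j] <- tryCatch(stats::t.test(a[, j], p[, j])$p.value,
                      error = function(e)
                        if (mean(a[, j]) != mean(p[, j])) 0 else 1)
    pw[j] <- suppressWarnings(stats::wilcox.test(a[, j], p[, j])$p.value)
  }
  keep <- cols[!is.na(pt) & !is.na(pw) & pt < alpha & pw < alpha]
  structure(list(method = "univariate", keep = keep, alpha = alpha,
                 p_t = stats::setNames(pt, cols),
                 p_wilcox = stats::setNames(pw, cols)),
            class = "mw_selection")
}

#' Number of features passing the univariate screen
#'
#' Convenience count used for significant-feature tables per group and
#' window.
#'
#' @inheritParams univariate_select
#' @return integer count.
#' @export
count_significant_features <- function(features, alpha = 0.05) {
  length(univariate_select(features, alpha)$keep)
}

#' Correlation-based feature selection (CFS) ranking
#'
#' Features are ranked greedily by the CFS merit of the growing set S:
#' `merit(S) = k * rcf / sqrt(k + k * (k - 1) * rff)` where `k = |S|`, `rcf`
#' is the mean absolute point-biserial correlation between the features in S
#' and the class, and `rff` the mean absolute pairwise correlation within S.
#' The merit rewards class relevance and penalizes redundancy. The top
#' `ceiling(fraction * p)` features (in rank order) are kept; constant
#' features rank last.
#'
#' @param features a labeled feature matrix.
#' @param fraction fraction of features to keep (default 0.5).
#' @return an `mw_selection` with `keep` in rank order and the full `ranking`.
#' @export
cfs_select <- function(features, fraction = 0.5) {
  cols <- feature_cols(features)
  p <- length(cols)
  if (p < 2) stop("need at least 2 features")
  X <- feature_matrix_values(features, cols)
  y <- as.numeric(mw_factor(features$label) == "present")
  constant <- apply(X, 2, stats::sd) == 0
  rcf <- abs(suppressWarnings(stats::cor(X, y)))[, 1]
  rcf[is.na(rcf)] <- 0
  rff <- abs(suppressWarnings(stats::cor(X)))
  rff[is.na(rff)] <- 0
  n_keep <- ceiling(fraction * p)

  ranking <- integer(0)
  in_set <- rep(FALSE, p)
  sum_rcf <- 0
  sum_rff_to_set <- rep(0, p)   # per candidate: sum of |cor| with current set
  sum_rff_within <- 0
  for (step in seq_len(p)) {
    cand <- which(!in_set & !constant)
    if (!length(cand)) cand <- which(!in_set)   # constants go last
    k <- step
    mean_rcf <- (sum_rcf + rcf[cand]) / k
    mean_rff <- if (k == 1) rep(0, length(cand)) else
      (sum_rff_within + sum_rff_to_set[cand]) / (k * (k - 1) / 2)
    merit <- (k * mean_rcf) / sqrt(k + k * (k - 1) * mean_rff)
    best <- cand[which.max(merit)]
    ranking <- c(ranking, best)
    in_set[best] <- TRUE
    sum_rcf <- sum_rcf + rcf[best]
    sum_rff_within <- sum_rff_within + sum_rff_to_set[best]
    sum_rff_to_set <- sum_rff_to_set + rff[, best]
  }
  structure(list(method = "cfs", keep = cols[ranking[seq_len(n_keep)]],
                 ranking = cols[ranking], fraction = fraction),
            class = "mw_selection")
}

#' @export
print.mw_selection <- function(x, ...) {
  cat(sprintf("<mw_selection> %s: %d features kept\n", x$method, length(x$keep)))
  invisible(x)
}

#' Fit the PCA variance-threshold projection
#'
#' The selected features are standardized (training mean/SD) and projected
#' onto principal components; the smallest leading set whose cumulative
#' explained variance reaches `variance_level` percent is kept (100 keeps
#' every component). Zero-variance columns are dropped with a warning before
#' the eigendecomposition.
#'
#' @param features training feature matrix.
#' @param variance_level percent of total variance to retain, in
#'   `{50, 60, 70, 80, 90, 100}` (any value in (0, 100] is accepted).
#' @param keep feature names to project (default: all feature columns).
#' @return an object of class `mw_projection`.
#' @export
fit_projection <- function(features, variance_level = 100,
                           keep = feature_cols(features)) {
  stopifnot(variance_level > 0, variance_level <= 100)
  X <- feature_matrix_values(features, keep)
  if (nrow(X) < 2) stop("need at least 2 training rows")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance feature(s) before projection: ",
            paste(keep[sds == 0], collapse = ", "))
    keep <- keep[sds > 0]
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (!length(keep)) stop("no non-constant features to project")
  ctr <- colMeans(X)
  Z <- sweep(sweep(X, 2, ctr), 2, sds, "/")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  n_comp <- which(cum >= variance_level / 100 - 1e-12)[1]
  if (variance_level == 100) n_comp <- length(ev)
  structure(list(keep = keep, center = ctr, scale = sds,
                 rotation = pc$rotation[, seq_len(n_comp), drop = FALSE],
                 variance_level = variance_level,
                 explained = cum[n_comp], n_components = n_comp),
            class = "mw_projection")
}

#' Apply selection and projection to new rows
#'
#' Rows are standardized with the training statistics stored in the model and
#' projected onto the kept loadings. Row order is preserved.
#'
#' @param features feature matrix (training or test rows).
#' @param projection an `mw_projection`.
#' @return numeric matrix (rows x components), columns `PC1..`.
#' @export
apply_projection <- function(features, projection) {
  stopifnot(inherits(projection, "mw_projection"))
  if (!all(projection$keep %in% names(features)))
    stop("feature-name mismatch between data and projection model")
  X <- feature_matrix_values(features, projection$keep)
  Z <- sweep(sweep(X, 2, projection$center), 2, projection$scale, "/")
  out <- Z %*% projection$rotation
  colnames(out) <- paste0("PC", seq_len(ncol(out)))
  out
}

#' Reconstruct standardized features from their projection (audit)
#'
#' @param scores matrix from [apply_projection()].
#' @param projection the `mw_projection` used.
#' @return matrix on the original feature scale.
#' @export
reconstruct_projection <- function(scores, projection) {
  Z <- scores %*% t(projection$rotation)
  sweep(sweep(Z, 2, projection$scale, "*"), 2, projection$center, "+")
}
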