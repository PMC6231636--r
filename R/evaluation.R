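#' Confusion table and classification rates
#'
#' The positive class is MW-present (the detection target). Precision is
#' defined as 0 when no positive predictions were made; recall is 0 when
#' there are positives but none was found.
#'
#' @param labels true labels (absent/present).
#' @param predictions predicted labels.
#' @return list with counts `tp`, `fn`, `fp`, `tn` and `accuracy`,
#'   `precision`, `recall`.
#' @export
confusion_and_rates <- function(labels, predictions) {
  y <- mw_factor(labels)
  p <- mw_factor(predictions)
  if (length(y) != length(p) || !length(y))
    stop("labels and predictions must be equal-length non-empty vectors")
  if (any(is.na(y)) || any(is.na(p)))
    stop("labels must be 'absent' or 'present'")
  tp <- sum(y == "present" & p == "present")
  fn <- sum(y == "present" & p == "absent")
  fp <- sum(y == "absent" & p == "present")
  tn <- sum(y == "absent" & p == "absent")
  n <- tp + fn + fp + tn
  list(tp = tp, fn = fn, fp = fp, tn = tn,
       accuracy = (tp + tn) / n,
       precision = if (tp + fp == 0) 0 else tp / (tp + fp),
       recall = if (tp + fn == 0) 0 else tp / (tp + fn))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_o = (tp + tn) / N` and
#' `p_e = ((tp + fn)(tp + fp) + (tn + fp)(tn + fn)) / N^2`. When the expected
#' agreement is 1 (both raters constant) kappa is defined as 0.
#'
#' @param table a confusion list with `tp`, `fn`, `fp`, `tn` (e.g. from
#'   [confusion_and_rates()]).
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(table) {
  tp <- table$tp; fn <- table$fn; fp <- table$fp; tn <- table$tn
  n <- tp + fn + fp + tn
  if (n <= 0) stop("empty confusion table")
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

# kappa straight from label/prediction vectors
.kappa_vec <- function(labels, predictions) {
  cohen_kappa(confusion_and_rates(labels, predictions))
}

#' Permutation significance of Cohen's kappa
#'
#' One-sided test of `kappa > 0`: the labels are permuted `n_perm` times and
#' `p = (1 + #[kappa_perm >= kappa_obs]) / (n_perm + 1)`.
#'
#' @param labels true labels.
#' @param predictions predicted labels.
#' @param n_perm number of permutations (default 1000, minimum 99).
#' @param seed integer seed.
#' @return list with `kappa` and the one-sided `p`.
#' @export
kappa_significance <- function(labels, predictions, n_perm = 1000, seed = 1L) {
  stopifnot(n_perm >= 99)
  y <- mw_factor(labels)
  p <- mw_factor(predictions)
  obs <- .kappa_vec(y, p)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm))
    if (.kappa_vec(sample(y), p) >= obs) hits <- hits + 1L
  list(kappa = obs, p = (1 + hits) / (n_perm + 1))
}

#' Friedman rank test across model configurations
#'
#' Blocks are cross-validation folds (rows), treatments are configurations
#' (columns). Ranks are taken within each block with mean ranks on ties; the
#' chi-square statistic uses the tie-corrected form
#' `(k - 1) * (sum_j R_j^2 - n^2 k (k+1)^2 / 4) / (A - C)` with
#' `A = sum r_ij^2` and `C = n k (k+1)^2 / 4`, which reduces to the classic
#' statistic when no ties occur. If every block ranks all configurations
#' equally the statistic is 0 and p = 1.
#'
#' @param acc_matrix numeric matrix, folds x configs, no missing cells.
#' @return list with `chisq`, `df` (= configs - 1), `p`, and `mean_ranks`.
#' @export
friedman_compare <- function(acc_matrix) {
  m <- as.matrix(acc_matrix)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 folds and 2 configurations")
  if (any(!is.finite(m))) stop("missing cells in the accuracy matrix")
  r <- t(apply(m, 1, rank))
  Rj <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  if (A - C <= 0) {
    stat <- 0
  } else {
    stat <- (k - 1) * (sum(Rj^2) - n^2 * k * (k + 1)^2 / 4) / (A - C)
  }
  df <- k - 1
  list(chisq = stat, df = df,
       p = if (stat == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE),
       mean_ranks = Rj / n, n_blocks = n)
}

#' Nemenyi post-hoc pairwise comparisons after a significant Friedman test
#'
#' Two configurations differ when their mean ranks differ by more than the
#' critical difference `q_alpha(k, Inf) / sqrt(2) * sqrt(k (k + 1) / (6 n))`
#' (studentized range at infinite df).
#'
#' @param friedman result of [friedman_compare()] (must have p < alpha).
#' @param alpha family-wise level (default 0.05).
#' @return list with the `critical_difference`, a data frame of significant
#'   `pairs`, and `top_beats`: for the best (lowest mean rank on accuracy is
#'   worst; here ranks are ascending so the top config has the highest mean
#'   rank) configuration, a logical vector saying which others it beats.
#' @export
posthoc_pairs <- function(friedman, alpha = 0.05) {
  if (friedman$p >= alpha)
    stop("post-hoc comparisons require a significant Friedman omnibus")
  mr <- friedman$mean_ranks
  k <- length(mr)
  n <- friedman$n_blocks
  cd <- stats::qtukey(1 - alpha, k, Inf) / sqrt(2) * sqrt(k * (k + 1) / (6 * n))
  pairs <- which(abs(outer(mr, mr, "-")) > cd & upper.tri(diag(k)), arr.ind = TRUE)
  top <- which.max(mr)
  list(critical_difference = cd,
       pairs = data.frame(i = pairs[, 1], j = pairs[, 2]),
       top = top,
       top_beats = abs(mr[top] - mr) > cd)
}

#' One-sided sign test for median kappa > 0
#'
#' Exact binomial test: zeros are dropped, successes are the strictly
#' positive values, `p = P(X >= successes)` for `X ~ Binomial(n, 1/2)`.
#' Returns p = 1 when every value is zero.
#'
#' @param kappas numeric vector of kappa values.
#' @return one-sided p-value.
#' @export
sign_test_median_gt0 <- function(kappas) {
  nz <- kappas[kappas != 0]
  if (!length(nz)) return(1)
  stats::binom.test(sum(nz > 0), length(nz), p = 0.5,
                    alternative = "greater")$p.value
}

#' Summarize one cross-validation result
#'
#' Pools the out-of-fold predictions of a [lopo_cv()] or
#' [repeated_kfold_cv()] result into a confusion table and computes kappa,
#' accuracy, precision and recall, optionally with permutation significance.
#'
#' @param cv an `mw_cv_result`.
#' @param n_perm permutations for [kappa_significance()]; 0 skips the test.
#' @param seed seed for the permutation test.
#' @return an object of class `mw_eval` (named list of metrics).
#' @export
evaluate_cv <- function(cv, n_perm = 0, seed = 1L) {
  stopifnot(inherits(cv, "mw_cv_result"))
  cr <- confusion_and_rates(cv$predictions$label, cv$predictions$pred)
  kap <- cohen_kappa(cr)
  kp <- NA_real_
  if (n_perm > 0)
    kp <- kappa_significance(cv$predictions$label, cv$predictions$pred,
                             n_perm = n_perm, seed = seed)$p
  structure(list(config_id = cv$config$id, kappa = kap, kappa_p = kp,
                 accuracy = cr$accuracy, precision = cr$precision,
                 recall = cr$recall, fold_acc = cv$fold_acc),
            class = "mw_eval")
}

#' @export
print.mw_eval <- function(x, ...) {
  cat(sprintf("<mw_eval> %s: kappa %.3f, accuracy %.3f, precision %.3f, recall %.3f\n",
              x$config_id, x$kappa, x$accuracy, x$precision, x$recall))
  invisible(x)
}
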