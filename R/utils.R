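# internal helpers shared across modules

.mw_levels <- c("absent", "present")

`%||%` <- function(a, b) if (is.null(a)) b else a

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Derive a stage seed from a master seed
#'
#' Stage seeds are a deterministic function of the master seed and the stage
#' name, so adding stages never shifts the random streams of existing ones.
#' The result is always a positive integer below 2^31.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
stage_seed <- function(master, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes) * 131L)
  as.integer((abs(as.numeric(master)) * 7919 + h) %% 2147483562 + 1)
}

# factor with the canonical label levels (absent = negative, present = positive)
mw_factor <- function(x) factor(as.character(x), levels = .mw_levels)

#' Feature columns of a feature matrix
#'
#' Names of the numeric feature columns (everything except the
#' `participant_id`, `label` and `window_s` metadata).
#'
#' @param features a feature matrix from [build_feature_matrix()].
#' @return character vector of column names.
#' @export
feature_cols <- function(features) {
  setdiff(names(features), c("participant_id", "label", "window_s"))
}

feature_matrix_values <- function(features, cols = feature_cols(features)) {
  as.matrix(features[, cols, drop = FALSE])
}
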