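.local_feature_names <- c("mean", "std", "max", "min", "median", "kurtosis",
                          "skewness", "intercept", "slope", "r_squared",
                          "diff", "entropy", paste0("ar", 1:5),
                          "var_cd1", "var_cd2", "var_cd3", "var_a3")
.global_feature_names <- c("max", "min", "mean", "std")

#' Session-level (global) features
#'
#' The 16 global features: max, min, mean, and standard deviation of each of
#' the four channels over the whole analysis period. They summarize stable
#' inter-individual driving traits and are constant across a participant's
#' probes.
#'
#' @param channels an `mw_channels` (transformed or raw).
#' @return named numeric vector of length 16
#'   (`global_<channel>_<max|min|mean|std>`).
#' @export
global_features <- function(channels) {
  stopifnot(inherits(channels, "mw_channels"))
  if (nrow(channels$values) == 0) stop("empty analysis period")
  out <- lapply(.channel_cols, function(v) {
    x <- channels$values[, v]
    c(max = max(x), min = min(x), mean = mean(x), std = stats::sd(x))
  })
  vals <- unlist(out)
  names(vals) <- paste0("global_",
                        rep(.channel_cols, each = 4), "_",
                        rep(.global_feature_names, 4))
  vals
}

#' Extract the pre-probe window of a channel matrix
#'
#' The half-open interval `[probe_time - W, probe_time)`, taken as the
#' `floor(W * rate)` samples immediately preceding the probe instant.
#'
#' @param channels an `mw_channels`.
#' @param probe_time_s probe instant, seconds.
#' @param window_length_s window length W, seconds.
#' @return list with `values` (samples x 4), `times`.
#' @export
extract_window <- function(channels, probe_time_s, window_length_s) {
  stopifnot(inherits(channels, "mw_channels"))
  nw <- floor(window_length_s * channels$sample_rate_hz)
  i_end <- sum(channels$times < probe_time_s)
  i_start <- i_end - nw + 1
  if (i_start < 1)
    stop("window extends before the analysis start (probe at ",
         signif(probe_time_s, 6), " s, W = ", window_length_s, " s)")
  idx <- i_start:i_end
  list(values = channels$values[idx, , drop = FALSE],
       times = channels$times[idx])
}

#' Linear trend of a windowed series
#'
#' Ordinary least squares of the value on time, with the time origin at the
#' window start (so the intercept is window-local). For a constant response
#' the slope is 0 and the coefficient of determination is defined as 0.
#'
#' @param series numeric values.
#' @param times sampling times (seconds).
#' @return named vector `intercept`, `slope`, `r_squared`.
#' @export
trend_features <- function(series, times) {
  if (length(series) < 3) stop("need at least 3 samples for a trend fit")
  t0 <- times - times[1]
  vt <- stats::var(t0)
  if (vt == 0) stop("constant time vector")
  slope <- stats::cov(t0, series) / vt
  intercept <- mean(series) - slope * mean(t0)
  sst <- sum((series - mean(series))^2)
  if (sst == 0) {
    slope <- 0
    intercept <- mean(series)
    r2 <- 0
  } else {
    sse <- sum((series - intercept - slope * t0)^2)
    r2 <- max(0, min(1, 1 - sse / sst))
  }
  c(intercept = intercept, slope = slope, r_squared = r2)
}

#' Shannon entropy of a windowed series
#'
#' Histogram entropy over `n_bins` equal-width bins spanning the window's own
#' range, in bits. A constant series has entropy 0 by convention (all mass in
#' one bin). Because the bin edges track the window range, the entropy is
#' invariant under affine maps of the channel.
#'
#' @param series numeric values.
#' @param n_bins number of bins (default 10).
#' @return entropy in bits (>= 0).
#' @export
shannon_entropy <- function(series, n_bins = 10) {
  stopifnot(length(series) >= 1, n_bins >= 1)
  rng <- range(series)
  if (diff(rng) == 0) return(0)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  idx <- findInterval(series, breaks, rightmost.closed = TRUE)
  p <- tabulate(idx, nbins = n_bins) / length(series)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Autoregressive coefficients of a windowed series
#'
#' Yule-Walker estimates of `a1..a_order` in
#' `x_t = sum_i a_i x_(t-i) + e_t` on the mean-centered series; a positive
#' coefficient means positive dependence on that lag. A (near-)constant
#' series, for which the autocovariance system is singular, yields all zeros
#' with a warning.
#'
#' @param series numeric values, length > 2 * order.
#' @param order AR order (default 5).
#' @return numeric vector of length `order`.
#' @export
ar_coefficients <- function(series, order = 5) {
  stopifnot(length(series) > 2 * order)
  if (stats::var(series) < .Machine$double.eps * max(1, mean(series)^2)) {
    warning("constant series: AR coefficients defined as 0")
    return(rep(0, order))
  }
  fit <- tryCatch(
    stats::ar(series, aic = FALSE, order.max = order, method = "yule-walker"),
    error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) != order || any(!is.finite(fit$ar))) {
    warning("degenerate autocovariance: AR coefficients defined as 0")
    return(rep(0, order))
  }
  as.numeric(fit$ar)
}

#' Orthonormal Haar discrete wavelet transform
#'
#' Pairwise sums and differences scaled by `1/sqrt(2)` per level, with no
#' signal extension: when a level has odd length the trailing coefficient is
#' set aside as a boundary residual instead of being padded. The transform is
#' therefore exactly orthonormal for any input length — Parseval's identity
#' holds to machine precision over the details, the final approximation and
#' the residuals together — and every approximation coefficient at a given
#' level has the same scale.
#'
#' @param series numeric values.
#' @param levels decomposition depth (default 3).
#' @return list with detail coefficient vectors `d1..d<levels>`, the final
#'   approximation `a<levels>`, and `tail` (boundary residuals; possibly
#'   empty).
#' @export
haar_dwt <- function(series, levels = 3) {
  if (length(series) < 2^levels)
    stop("series shorter than 2^levels samples")
  a <- series
  out <- list()
  tail_res <- numeric(0)
  for (l in seq_len(levels)) {
    n <- length(a)
    m <- n %/% 2
    odd <- a[seq(1, 2 * m, by = 2)]
    even <- a[seq(2, 2 * m, by = 2)]
    if (n %% 2 == 1) tail_res <- c(tail_res, a[n])
    out[[paste0("d", l)]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  out[[paste0("a", levels)]] <- a
  out$tail <- tail_res
  out
}

#' Wavelet-band variances of a windowed series
#'
#' Population variances of the Haar detail coefficients at levels 1..3 and of
#' the level-3 approximation coefficients.
#'
#' @param series numeric values, length >= `2^levels`.
#' @param levels decomposition depth (default 3).
#' @return named vector `var_cd1`, `var_cd2`, `var_cd3`, `var_a3`.
#' @export
wavelet_variances <- function(series, levels = 3) {
  w <- haar_dwt(series, levels)
  popvar <- function(x) mean((x - mean(x))^2)
  vals <- c(vapply(seq_len(levels), function(l) popvar(w[[paste0("d", l)]]), 0),
            popvar(w[[paste0("a", levels)]]))
  names(vals) <- c(paste0("var_cd", seq_len(levels)), paste0("var_a", levels))
  vals
}

# population skewness / non-excess kurtosis; both defined as 0 for a
# zero-variance window
.moments <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(c(kurtosis = 0, skewness = 0))
  c(kurtosis = mean((x - mean(x))^4) / m2^2,
    skewness = mean((x - mean(x))^3) / m2^1.5)
}

# the 21 local features of one channel, in the documented fixed order
.local_one <- function(x, times, n_bins) {
  tr <- trend_features(x, times)
  mo <- .moments(x)
  ar <- suppressWarnings(ar_coefficients(x, 5))
  wv <- wavelet_variances(x, 3)
  c(mean = mean(x), std = stats::sd(x), max = max(x), min = min(x),
    median = stats::median(x), kurtosis = unname(mo["kurtosis"]),
    skewness = unname(mo["skewness"]), intercept = unname(tr["intercept"]),
    slope = unname(tr["slope"]), r_squared = unname(tr["r_squared"]),
    diff = x[length(x)] - x[1], entropy = shannon_entropy(x, n_bins),
    ar1 = ar[1], ar2 = ar[2], ar3 = ar[3], ar4 = ar[4], ar5 = ar[5],
    var_cd1 = unname(wv["var_cd1"]), var_cd2 = unname(wv["var_cd2"]),
    var_cd3 = unname(wv["var_cd3"]), var_a3 = unname(wv["var_a3"]))
}

#' Local (pre-probe window) features
#'
#' The 84 local features: for each of the four channels, 21 statistics of the
#' window just before the probe — five order/location statistics, kurtosis
#' (non-excess convention, normal = 3) and skewness, the window-local linear
#' trend (intercept, slope, goodness of fit), the end-minus-start difference,
#' Shannon entropy, the five Yule-Walker AR coefficients, and the four Haar
#' wavelet-band variances.
#'
#' @param window a window from [extract_window()].
#' @param n_bins entropy histogram bins (default 10).
#' @return named numeric vector of length 84 (`<channel>_<feature>`).
#' @export
local_features <- function(window, n_bins = 10) {
  out <- lapply(.channel_cols, function(v)
    .local_one(window$values[, v], window$times, n_bins))
  vals <- unlist(out)
  names(vals) <- paste0(rep(.channel_cols, each = length(.local_feature_names)),
                        "_", rep(.local_feature_names, length(.channel_cols)))
  vals
}

#' Assemble the labeled feature matrix of a cohort
#'
#' One row per answered probe. Global features are repeated across a
#' participant's rows; local features are computed in the pre-probe window of
#' the requested length. Unanswered probes (`response = "none"`) are
#' excluded; probes whose window would extend before the analysis start are
#' dropped with a warning.
#'
#' @param sessions an `mw_cohort` or list of `mw_session`.
#' @param transform an `mw_transform` applied to every session's channels
#'   (default: none).
#' @param feature_set `"global"` (16 columns), `"local"` (84), or `"both"`
#'   (100).
#' @param window_length_s pre-probe window length in seconds (ignored for
#'   `"global"`).
#' @param n_bins entropy histogram bins.
#' @return data frame: `participant_id`, `label` (factor absent/present),
#'   `window_s`, then the feature columns in fixed order.
#' @export
build_feature_matrix <- function(sessions, transform = NULL,
                                 feature_set = c("both", "global", "local"),
                                 window_length_s = 10, n_bins = 10) {
  feature_set <- match.arg(feature_set)
  if (inherits(sessions, "mw_cohort")) sessions <- sessions$sessions
  if (inherits(sessions, "mw_session")) sessions <- list(sessions)
  rows <- list()
  meta <- list()
  for (s in sessions) {
    ch <- assemble_variables(s)
    if (!is.null(transform)) ch <- apply_transform(ch, transform)
    gf <- if (feature_set != "local") global_features(ch) else NULL
    answered <- s$probes[s$probes$response != "none", , drop = FALSE]
    for (k in seq_len(nrow(answered))) {
      lf <- NULL
      if (feature_set != "global") {
        win <- tryCatch(extract_window(ch, answered$time_s[k], window_length_s),
                        error = function(e) {
                          warning("probe excluded: ", conditionMessage(e))
                          NULL
                        })
        if (is.null(win)) next
        lf <- local_features(win, n_bins)
      }
      rows[[length(rows) + 1L]] <- c(gf, lf)
      meta[[length(meta) + 1L]] <- c(s$participant_id, answered$response[k])
    }
  }
  if (!length(rows)) stop("zero answered probes")
  vals <- do.call(rbind, rows)
  out <- data.frame(
    participant_id = as.numeric(vapply(meta, `[`, "", 1)),
    label = mw_factor(vapply(meta, `[`, "", 2)),
    window_s = if (feature_set == "global") NA_real_ else window_length_s,
    vals, check.names = FALSE)
  out
}
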