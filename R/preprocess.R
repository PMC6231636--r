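.channel_cols <- c("offset", "rel_steering", "foot", "distance")

#' Assemble the four analysis channels of a session
#'
#' Builds the fixed-order channel matrix (offset, relative steering, foot,
#' distance) from a session. Relative steering is the participant's steering
#' minus the lead vehicle's steering at the same sample (the lead vehicle
#' drives the track ideally, so its steering encodes the road curvature).
#' Samples before the analysis start are dropped.
#'
#' @param session an `mw_session`.
#' @return an object of class `mw_channels`: `participant_id`, `times`,
#'   `values` (n x 4 matrix), `transform` tag, sampling rate.
#' @export
assemble_variables <- function(session) {
  stopifnot(inherits(session, "mw_session"))
  n <- length(session$times)
  lens <- c(length(session$offset), length(session$steering),
            length(session$lead_steering), length(session$foot),
            length(session$distance))
  if (any(lens != n)) stop("channel length mismatch")
  keep <- session$times >= session$analysis_start_s
  if (!any(keep)) stop("empty analysis period")
  values <- cbind(offset = session$offset[keep],
                  rel_steering = (session$steering - session$lead_steering)[keep],
                  foot = session$foot[keep],
                  distance = session$distance[keep])
  structure(list(participant_id = session$participant_id,
                 times = session$times[keep],
                 values = values,
                 transform = "none",
                 sample_rate_hz = session$sample_rate_hz),
            class = "mw_channels")
}

# pool the rows of a list of mw_channels into one matrix
.pool_channels <- function(channels_list) {
  if (inherits(channels_list, "mw_channels")) channels_list <- list(channels_list)
  do.call(rbind, lapply(channels_list, function(ch) ch$values))
}

#' Fit a channel transform on a training pool
#'
#' `"none"` is the identity; `"zscore"` standardizes each channel by its
#' training-pool mean and standard deviation; `"pica"` is a linear
#' independent-component transform: the pooled channels are centered and
#' whitened to identity covariance, then rotated by a fixed-point iteration
#' maximizing a kurtosis-based non-Gaussianity contrast. Components are
#' ordered by decreasing output kurtosis and signed so the largest-magnitude
#' loading is positive. Deterministic given `seed`.
#'
#' @param channels_list one `mw_channels` or a list of them (the fit pool).
#' @param kind one of `"none"`, `"zscore"`, `"pica"`.
#' @param seed integer seed for the rotation initialization.
#' @param fit_scope tag recording what the pool was (`"training_pool"` or
#'   `"per_participant"`), for audit only.
#' @return an object of class `mw_transform`.
#' @export
fit_transform <- function(channels_list, kind = c("none", "zscore", "pica"),
                          seed = 1L, fit_scope = "training_pool") {
  kind <- match.arg(kind)
  X <- .pool_channels(channels_list)
  if (kind != "none") {
    if (nrow(X) < 100) stop("need at least 100 pooled training rows to fit a transform")
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0))
      stop("zero-variance channel: ", paste(colnames(X)[sds == 0], collapse = ", "))
  }
  model <- switch(kind,
    none = list(),
    zscore = list(center = colMeans(X), scale = apply(X, 2, stats::sd)),
    pica = .fit_pica(X, seed = seed)
  )
  structure(c(model, list(kind = kind, columns = colnames(X),
                          fit_scope = fit_scope)),
            class = "mw_transform")
}

# whitening + symmetric fixed-point rotation with the pow3 (kurtosis) contrast
.fit_pica <- function(X, seed = 1L, max_iter = 200, tol = 1e-8) {
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  V <- stats::cov(Xc)
  e <- eigen(V, symmetric = TRUE)
  if (any(e$values < 1e-12 * max(e$values)))
    stop("zero-variance channel: covariance is singular")
  K <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)  # symmetric whitening
  Z <- Xc %*% K
  p <- ncol(X)
  set.seed(seed)
  W <- qr.Q(qr(matrix(stats::rnorm(p * p), p)))
  for (it in seq_len(max_iter)) {
    S <- Z %*% W
    W1 <- crossprod(Z, S^3) / nrow(Z) - 3 * W
    sv <- svd(W1)
    W1 <- sv$u %*% t(sv$v)
    delta <- max(abs(abs(colSums(W * W1)) - 1))
    W <- W1
    if (delta < tol) break
  }
  A <- K %*% W                      # centered data %*% A = components
  S <- Xc %*% A
  kur <- apply(S, 2, function(s) mean((s - mean(s))^4) / mean((s - mean(s))^2)^2)
  A <- A[, order(kur, decreasing = TRUE), drop = FALSE]
  for (j in seq_len(p)) if (A[which.max(abs(A[, j])), j] < 0) A[, j] <- -A[, j]
  list(center = center, forward = A, inverse = solve(A))
}

#' Apply a fitted channel transform
#'
#' @param channels an `mw_channels`.
#' @param model an `mw_transform` from [fit_transform()].
#' @return the transformed `mw_channels` with its `transform` tag set.
#' @export
apply_transform <- function(channels, model) {
  stopifnot(inherits(channels, "mw_channels"), inherits(model, "mw_transform"))
  if (!identical(colnames(channels$values), model$columns))
    stop("column order of data does not match the fitted transform")
  channels$values <- switch(model$kind,
    none = channels$values,
    zscore = sweep(sweep(channels$values, 2, model$center), 2, model$scale, "/"),
    pica = {
      out <- sweep(channels$values, 2, model$center) %*% model$forward
      colnames(out) <- model$columns
      out
    })
  channels$transform <- model$kind
  channels
}

#' Invert a fitted channel transform (round-trip audit)
#'
#' @param channels a transformed `mw_channels`.
#' @param model the `mw_transform` that produced it.
#' @return the reconstructed `mw_channels`.
#' @export
invert_transform <- function(channels, model) {
  stopifnot(inherits(channels, "mw_channels"), inherits(model, "mw_transform"))
  channels$values <- switch(model$kind,
    none = channels$values,
    zscore = sweep(sweep(channels$values, 2, model$scale, "*"), 2, model$center, "+"),
    pica = {
      out <- sweep(channels$values %*% model$inverse, 2, model$center, "+")
      colnames(out) <- model$columns
      out
    })
  channels$transform <- "none"
  channels
}
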