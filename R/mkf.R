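#' Dead-zone threshold for decoded output
#'
#' The decoded value stays at zero until its absolute value exceeds the
#' threshold; beyond the dead zone it passes through unchanged. Applied
#' element-wise per DOF per frame.
#'
#' @param x Numeric scalar, vector or matrix.
#' @param threshold Dead-zone half-width (default 0.2).
#' @return `x` with `|x| <= threshold` zeroed.
#' @examples
#' threshold_modify(c(0.1, 0.2, -0.5))  # 0, 0, -0.5
#' @export
threshold_modify <- function(x, threshold = 0.2) {
  x * (abs(x) > threshold)
}

#' Fit a Kalman decoder by least squares
#'
#' The state is the 12-DOF kinematic position; the observations are the
#' (selected, baseline-subtracted) feature channels. The state-transition
#' matrix `A` is the least-squares map from each frame's kinematics to the
#' next, the observation matrix `H` the least-squares map from kinematics to
#' features, and `W`, `Q` the covariances of the respective residuals (the
#' maximum-likelihood estimates).
#'
#' @param features_selected Matrix `k_obs x T` of conditioned features (or a
#'   `feature_matrix`).
#' @param kin A `kin_trace` or 12 x T matrix, frame-aligned to the features.
#' @param ridge Small diagonal loading added to the normal equations.
#' @param seq_start Optional integer vector (length T) giving, for every
#'   frame, the first frame of its recording segment; transition pairs never
#'   straddle a segment boundary (used when sessions are concatenated).
#' @return An object of class `kalman_model` with fields `A`, `W`, `H`, `Q`.
#' @export
fit_kalman <- function(features_selected, kin, ridge = 1e-8,
                       seq_start = NULL) {
  Z <- if (inherits(features_selected, "feature_matrix"))
    features_selected$values else as.matrix(features_selected)
  X <- if (inherits(kin, "kin_trace")) kin$values else as.matrix(kin)
  Tn <- ncol(X)
  if (ncol(Z) != Tn) stopf("features and kinematics are not frame-aligned")
  if (Tn < nrow(X) + nrow(Z))
    stopf("too few frames (%d) to fit a %d-state, %d-observation model",
          Tn, nrow(X), nrow(Z))
  from <- seq_len(Tn - 1L)
  if (!is.null(seq_start))
    from <- from[seq_start[from] == seq_start[from + 1L]]
  X1 <- X[, from, drop = FALSE]
  X2 <- X[, from + 1L, drop = FALSE]
  G1 <- X1 %*% t(X1) + ridge * diag(nrow(X))
  A <- t(solve(G1, X1 %*% t(X2)))
  We <- X2 - A %*% X1
  W <- (We %*% t(We)) / length(from)
  G <- X %*% t(X) + ridge * diag(nrow(X))
  H <- t(solve(G, X %*% t(Z)))
  Qe <- Z - H %*% X
  Q <- (Qe %*% t(Qe)) / Tn
  structure(list(A = A, W = W, H = H, Q = Q,
                 n_state = nrow(X), n_obs = nrow(Z)),
            class = "kalman_model")
}

#' @export
print.kalman_model <- function(x, ...) {
  cat(sprintf("Kalman model: %d states, %d observation channels\n",
              x$n_state, x$n_obs))
  invisible(x)
}

#' @export
coef.kalman_model <- function(object, ...) {
  object[c("A", "W", "H", "Q")]
}

#' Run the Kalman recursion over a feature sequence
#'
#' Standard predict/update recursion from a zero (rest) initial state and a
#' large initial covariance, computed in information form (numerically
#' equivalent to the covariance form; the update inverts only
#' state-dimension matrices). Each frame's state estimate is passed through
#' [threshold_modify()] and clamped to \eqn{[-1, 1]}.
#'
#' @param object A `kalman_model` (from [fit_kalman()]).
#' @param features Matrix `k_obs x T` conditioned like the training features
#'   (or a `feature_matrix`).
#' @param threshold Dead-zone half-width; `0` disables it.
#' @param p0 Initial state covariance scale (`p0 * I`).
#' @param ... Unused.
#' @return A `decoded_trace`: list with `values` (12 x T, in `[-1, 1]`) and
#'   `raw` (unthresholded state estimates).
#' @export
predict.kalman_model <- function(object, features, threshold = 0.2,
                                 p0 = 10, ...) {
  Z <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  if (nrow(Z) != object$n_obs)
    stopf("feature channel count (%d) does not match model (%d)",
          nrow(Z), object$n_obs)
  A <- object$A; W <- object$W; H <- object$H; Q <- object$Q
  ns <- object$n_state
  Tn <- ncol(Z)
  Qh <- solve(Q + 1e-10 * diag(nrow(Q)), H)   # Q^{-1} H, k_obs x ns
  M <- t(H) %*% Qh                            # H' Q^{-1} H, ns x ns
  x <- matrix(0, ns, 1)
  P <- p0 * diag(ns)
  out <- matrix(0, ns, Tn)
  for (t in seq_len(Tn)) {
    xp <- A %*% x
    # jitter keeps Pp invertible when unused DOFs make W rank-deficient
    Pp <- A %*% P %*% t(A) + W + 1e-9 * diag(ns)
    Pinv <- solve(Pp)
    P <- solve(Pinv + M)
    x <- P %*% (Pinv %*% xp + t(Qh) %*% Z[, t])
    out[, t] <- x
  }
  structure(list(values = clamp(threshold_modify(out, threshold)),
                 raw = out),
            class = "decoded_trace")
}

#' @export
print.decoded_trace <- function(x, ...) {
  cat(sprintf("Decoded trace: %d DOFs x %d frames in [-1, 1]\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Fit the full Kalman decoder pipeline
#'
#' The user-facing fitting function: takes one or more sessions (or an
#' aggregate built with [build_aggregated_training()]), aligns the
#' kinematics for reaction lag, subtracts the rest baseline from the
#' features, selects `k` channels by Gram-Schmidt forward selection, and
#' fits the Kalman model on 100% of the (conditioned) training data.
#'
#' @param x An `emg_session`, a list of sessions, or an `emg_aggregate`.
#' @param k Number of feature channels retained.
#' @param threshold Dead-zone half-width applied at decode time.
#' @param max_lag_s Largest reaction lag searched per session.
#' @return An object of class `mkf_decoder` holding the Kalman model, the
#'   selected channel indices, and the per-channel rest baseline.
#' @seealso [predict.mkf_decoder()], [fit_cnn()]
#' @export
fit_mkf <- function(x, k = 48, threshold = 0.2, max_lag_s = 1.0) {
  agg <- as_aggregate(x, max_lag_s = max_lag_s)
  bs <- baseline_subtract(agg$features, rest_frames(agg$annotations,
                                                    ncol(agg$features$values)))
  sel <- gram_schmidt_select(bs$features, agg$kin, k = k)
  Zs <- bs$features$values[sel$selected_indices, , drop = FALSE]
  model <- fit_kalman(Zs, agg$kin, seq_start = agg$seq_start)
  structure(list(model = model, selection = sel,
                 channel_indices = sel$selected_indices,
                 baseline = bs$baseline, threshold = threshold,
                 n_features = nrow(agg$features$values),
                 frame_rate = agg$features$frame_rate),
            class = "mkf_decoder")
}

#' Decode a session or feature matrix with a fitted Kalman decoder
#'
#' Applies the training-time conditioning (baseline subtraction and channel
#' selection) to the input features and runs the thresholded, clamped
#' Kalman recursion.
#'
#' @param object An `mkf_decoder`.
#' @param newdata An `emg_session` or `feature_matrix`.
#' @param ... Passed to [predict.kalman_model()].
#' @return A `decoded_trace`.
#' @export
predict.mkf_decoder <- function(object, newdata, ...) {
  fe <- if (inherits(newdata, "emg_session")) session_features(newdata) else
    newdata
  stopifnot(inherits(fe, "feature_matrix"))
  if (nrow(fe$values) != object$n_features)
    stopf("feature count (%d) does not match training (%d)",
          nrow(fe$values), object$n_features)
  Z <- (fe$values - object$baseline)[object$channel_indices, , drop = FALSE]
  predict(object$model, Z, threshold = object$threshold, ...)
}

#' @export
print.mkf_decoder <- function(x, ...) {
  cat(sprintf(
    "Kalman decoder: %d/%d channels, dead-zone threshold %.2g\n",
    length(x$channel_indices), x$n_features, x$threshold))
  invisible(x)
}

#' @export
summary.mkf_decoder <- function(object, ...) {
  cat(sprintf("Kalman decoder (12-DOF position state)\n"))
  cat(sprintf("  features: %d total, %d selected by Gram-Schmidt\n",
              object$n_features, length(object$channel_indices)))
  cat(sprintf("  dead zone: +/- %.2g, outputs clamped to [-1, 1]\n",
              object$threshold))
  cat(sprintf("  observation noise: mean diag(Q) = %.3g\n",
              mean(diag(object$model$Q))))
  invisible(object)
}

#' @export
coef.mkf_decoder <- function(object, ...) {
  c(coef(object$model), list(channel_indices = object$channel_indices,
                             baseline = object$baseline,
                             threshold = object$threshold))
}
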