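#' Feature matrix container
#'
#' Mean-absolute-value amplitude features: one row per channel (single-ended
#' contacts first, then all ordered differential pairs), one column per
#' frame.
#'
#' @param values Nonnegative `n_features x n_frames` matrix.
#' @param frame_rate Frame rate, Hz.
#' @param channel_labels Character labels, length `n_features`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, frame_rate = 30, channel_labels = NULL) {
  values <- as.matrix(values)
  if (is.null(channel_labels))
    channel_labels <- sprintf("f%04d", seq_len(nrow(values)))
  stopifnot(length(channel_labels) == nrow(values))
  structure(list(values = values, frame_rate = frame_rate,
                 channel_labels = channel_labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d channels x %d frames at %g Hz\n",
              nrow(x$values), ncol(x$values), x$frame_rate))
  invisible(x)
}

# Labels for n single-ended contacts followed by all i<j pairs.
channel_labels <- function(n) {
  se <- sprintf("c%02d", seq_len(n))
  if (n < 2) return(se)
  p <- utils::combn(n, 2)
  c(se, sprintf("c%02d-c%02d", p[1, ], p[2, ]))
}

#' Filter specification for raw EMG conditioning
#'
#' The standard recording chain: sixth-order high-pass Butterworth at 15 Hz,
#' second-order low-pass Butterworth at 375 Hz, and 2 Hz-wide second-order
#' Butterworth band-stop notches at the mains frequency and harmonics.
#'
#' @param hp_cutoff,hp_order High-pass cutoff (Hz) and order.
#' @param lp_cutoff,lp_order Low-pass cutoff (Hz) and order.
#' @param notch_freqs Notch center frequencies, Hz.
#' @param notch_bw Notch full bandwidth, Hz.
#' @param fs Sampling rate, Hz.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(hp_cutoff = 15, hp_order = 6,
                        lp_cutoff = 375, lp_order = 2,
                        notch_freqs = c(60, 120, 180), notch_bw = 2,
                        fs = 1000) {
  if (!(hp_cutoff > 0 && hp_cutoff < lp_cutoff && lp_cutoff < fs / 2))
    stopf("need 0 < hp_cutoff < lp_cutoff < fs/2")
  structure(list(hp_cutoff = hp_cutoff, hp_order = hp_order,
                 lp_cutoff = lp_cutoff, lp_order = lp_order,
                 notch_freqs = notch_freqs, notch_bw = notch_bw, fs = fs),
            class = "filter_spec")
}

# The designed filter cascade as a list of signal::Arma objects.
filter_cascade <- function(spec) {
  ny <- spec$fs / 2
  filts <- list(
    signal::butter(spec$hp_order, spec$hp_cutoff / ny, type = "high"),
    signal::butter(spec$lp_order, spec$lp_cutoff / ny, type = "low"))
  for (f0 in spec$notch_freqs) {
    filts[[length(filts) + 1L]] <-
      signal::butter(2, c(f0 - spec$notch_bw / 2, f0 + spec$notch_bw / 2) / ny,
                     type = "stop")
  }
  filts
}

#' Band-pass and notch filter a raw EMG recording
#'
#' Applies the cascade causally (forward-only, as a real-time decoder must)
#' per channel: high-pass, low-pass, then each notch in turn.
#'
#' @param emg An `emg_recording`.
#' @param spec A [filter_spec()]; its `fs` must match the recording.
#' @return A filtered `emg_recording` of the same shape.
#' @export
bandpass_notch <- function(emg, spec = filter_spec(fs = emg$fs)) {
  stopifnot(inherits(emg, "emg_recording"), inherits(spec, "filter_spec"))
  if (spec$fs != emg$fs) stopf("filter fs (%g) does not match recording (%g)",
                               spec$fs, emg$fs)
  filts <- filter_cascade(spec)
  min_len <- 3 * max(vapply(filts, function(f) length(f$b), numeric(1)))
  if (ncol(emg$values) < min_len)
    stopf("recording too short to filter (%d samples < %d)",
          ncol(emg$values), min_len)
  out <- emg$values
  for (ch in seq_len(nrow(out))) {
    x <- out[ch, ]
    for (f in filts) x <- signal::filter(f, x)
    out[ch, ] <- x
  }
  emg$values <- out
  emg
}

#' All-pairs differential channels
#'
#' Appends every pairwise difference `row_i - row_j` (i < j, lexicographic
#' order) to the single-ended rows, giving `n + choose(n, 2)` rows. Applied
#' to the time-domain EMG before rectification.
#'
#' @param x Matrix `n x T` (channels x samples or frames).
#' @return Matrix `(n + choose(n, 2)) x T`.
#' @examples
#' nrow(differential_pairs(matrix(rnorm(32 * 10), 32)))  # 528
#' @export
differential_pairs <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) return(x)
  p <- utils::combn(n, 2)
  rbind(x, x[p[1, ], , drop = FALSE] - x[p[2, ], , drop = FALSE])
}

#' Mean-absolute-value features over a sliding window
#'
#' For frame k at time `k / frame_rate`, the MAV is the mean of `|x|` over
#' the trailing `window_ms` of samples ending at (and including) that time;
#' early frames whose window precedes the recording start use only the
#' available samples. The window is trailing (causal), matching real-time
#' use.
#'
#' @param emg An `emg_recording` (any number of channels, e.g. the output of
#'   [differential_pairs()] wrapped back into a recording, or raw contacts).
#' @param window_ms Window length, ms.
#' @param frame_rate Output frame rate, Hz.
#' @param channel_labels Optional labels for the output rows.
#' @return A `feature_matrix`.
#' @export
mav_features <- function(emg, window_ms = 300, frame_rate = 30,
                         channel_labels = NULL) {
  stopifnot(inherits(emg, "emg_recording"))
  n_samp <- ncol(emg$values)
  if (n_samp == 0) stopf("empty recording")
  if (window_ms < 1000 / frame_rate)
    stopf("window_ms must cover at least one frame period")
  w <- as.integer(round(window_ms * emg$fs / 1000))
  n_frames <- as.integer(floor(n_samp * frame_rate / emg$fs))
  ends <- as.integer(round(seq_len(n_frames) * emg$fs / frame_rate))
  starts <- pmax(ends - w + 1L, 1L)
  cs <- cbind(0, t(apply(abs(emg$values), 1, cumsum)))  # channels x (S+1)
  vals <- (cs[, ends + 1L, drop = FALSE] - cs[, starts, drop = FALSE]) /
    rep(ends - starts + 1L, each = nrow(cs))
  feature_matrix(vals, frame_rate, channel_labels)
}

#' Full feature chain for a session
#'
#' Raw-EMG sessions go through filtering, all-pairs differencing, and MAV
#' windowing; feature-level sessions return their stored features.
#'
#' @param session An `emg_session`.
#' @param spec A [filter_spec()] for the raw path.
#' @return A `feature_matrix` aligned to the session's kinematic frames.
#' @export
session_features <- function(session, spec = NULL) {
  stopifnot(inherits(session, "emg_session"))
  if (!is.null(session$features)) return(session$features)
  if (is.null(session$emg)) stopf("session has neither EMG nor features")
  if (is.null(spec)) spec <- filter_spec(fs = session$emg$fs)
  filtered <- bandpass_notch(session$emg, spec)
  n <- nrow(filtered$values)
  all_ch <- structure(list(values = differential_pairs(filtered$values),
                           fs = filtered$fs), class = "emg_recording")
  fe <- mav_features(all_ch, frame_rate = session$kin$frame_rate,
                     channel_labels = channel_labels(n))
  # windowing can yield one frame fewer/more than the kinematics; trim both
  n_fr <- min(ncol(fe$values), ncol(session$kin$values))
  fe$values <- fe$values[, seq_len(n_fr), drop = FALSE]
  fe
}

#' Estimate and remove the user's reaction lag
#'
#' The prompted kinematics lead the muscle response by the user's reaction
#' time. The lag is found as the nonnegative frame shift (up to `max_lag_s`)
#' maximizing the normalized cross-correlation between the frame-wise mean
#' of the mean-centered features and the frame-wise mean of the rectified
#' kinematics; the kinematics are then delayed by that many frames (head
#' padded with rest) so each feature frame is paired with the movement the
#' muscles were producing at that time. Trial annotations shift with the
#' kinematics.
#'
#' @param features A `feature_matrix`.
#' @param kin A `kin_trace` with the same frame count and rate.
#' @param max_lag_s Largest lag searched, seconds.
#' @return List with `lag_frames` and `kin`, the shifted trace.
#' @export
align_lag <- function(features, kin, max_lag_s = 1.0) {
  stopifnot(inherits(features, "feature_matrix"), inherits(kin, "kin_trace"))
  if (features$frame_rate != kin$frame_rate)
    stopf("frame rates differ")
  n_fr <- min(ncol(features$values), ncol(kin$values))
  x <- colMeans(features$values[, seq_len(n_fr), drop = FALSE] -
                  rowMeans(features$values[, seq_len(n_fr), drop = FALSE]))
  y <- colMeans(abs(kin$values[, seq_len(n_fr), drop = FALSE]))
  max_lag <- frames_of(max_lag_s, kin$frame_rate)
  if (all(y == 0)) {
    warning("all-zero kinematics; lag set to 0")
    lag <- 0L
  } else {
    score <- vapply(0:max_lag, function(l) {
      xs <- x[(1 + l):n_fr]
      ys <- y[1:(n_fr - l)]
      if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(-Inf)
      stats::cor(xs, ys)
    }, numeric(1))
    lag <- as.integer(which.max(score) - 1L)
  }
  kin$values <- shift_right(kin$values, lag)
  ann <- kin$annotations
  if (lag > 0 && nrow(ann) > 0) {
    ann$frame_start <- pmin(ann$frame_start + lag, ncol(kin$values))
    ann$frame_end <- pmin(ann$frame_end + lag, ncol(kin$values))
    kin$annotations <- ann
  }
  list(lag_frames = lag, kin = kin)
}

# Delay columns by `lag` frames: head padded with rest, tail truncated.
shift_right <- function(m, lag) {
  if (lag <= 0) return(m)
  f <- ncol(m)
  cbind(matrix(0, nrow(m), min(lag, f)),
        m[, seq_len(max(f - lag, 0)), drop = FALSE])
}

#' Subtract the rest-period baseline from features
#'
#' Removes each channel's mean over the given rest frames. Output may be
#' negative; this is the conditioning step for the Kalman decoder path.
#'
#' @param features A `feature_matrix`.
#' @param rest Integer vector of rest-frame indices (see [rest_frames()]).
#' @return List with `features` (baseline-removed) and `baseline` (the
#'   per-channel rest means).
#' @export
baseline_subtract <- function(features, rest) {
  stopifnot(inherits(features, "feature_matrix"))
  rest <- intersect(as.integer(rest), seq_len(ncol(features$values)))
  if (length(rest) == 0) stopf("rest frame set is empty")
  baseline <- rowMeans(features$values[, rest, drop = FALSE])
  features$values <- features$values - baseline
  list(features = features, baseline = baseline)
}
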