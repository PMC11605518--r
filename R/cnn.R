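#' Convolutional regression network specification
#'
#' The decoder maps an `N x 10` window of feature frames (current frame plus
#' nine previous) to the 12 DOF positions: one convolutional layer with ten
#' `1 x 5` filters across time only (giving an `N x 6 x 10` feature map),
#' ReLU, then two fully connected layers of `2N` units each with ReLU, and a
#' linear regression output of width 12.
#'
#' @param n_features Number of input feature channels `N` (>= 5).
#' @param window Input window length in frames.
#' @param conv_kernel Temporal kernel length.
#' @param conv_filters Number of convolutional filters.
#' @param outputs Regression output width.
#' @return An object of class `cnn_spec`; `fc_width` is fixed at `2 * N`.
#' @export
cnn_spec <- function(n_features, window = 10, conv_kernel = 5,
                     conv_filters = 10, outputs = 12) {
  if (n_features < 5) stopf("n_features must be >= 5")
  if (window < conv_kernel) stopf("window (%d) shorter than kernel (%d)",
                                  window, conv_kernel)
  structure(list(n_features = as.integer(n_features),
                 window = as.integer(window),
                 conv_kernel = as.integer(conv_kernel),
                 conv_filters = as.integer(conv_filters),
                 conv_out_len = as.integer(window - conv_kernel + 1L),
                 fc_width = 2L * as.integer(n_features),
                 outputs = as.integer(outputs)),
            class = "cnn_spec")
}

#' Total trainable parameter count for a network spec
#'
#' Closed form: `conv_filters * (conv_kernel + 1)` for the convolution,
#' plus the two hidden layers and the regression head.
#'
#' @param spec A [cnn_spec()] (or an integer `N`, using the defaults).
#' @return Integer parameter count.
#' @export
cnn_param_count <- function(spec) {
  if (is.numeric(spec)) spec <- cnn_spec(spec)
  N <- spec$n_features; Wd <- spec$fc_width
  flat <- spec$n_features * spec$conv_out_len * spec$conv_filters
  spec$conv_filters * (spec$conv_kernel + 1L) +
    (flat * Wd + Wd) + (Wd * Wd + Wd) + (Wd * spec$outputs + spec$outputs)
}

#' Build (initialize) a convolutional regression network
#'
#' He-normal weight initialization (suited to ReLU layers), zero biases.
#'
#' @param spec A [cnn_spec()].
#' @param seed Integer seed for the initial weights.
#' @return An untrained object of class `emg_cnn`.
#' @export
build_cnn <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cnn_spec"))
  flat <- spec$n_features * spec$conv_out_len * spec$conv_filters
  Wd <- spec$fc_width
  w <- with_seed(mix_seed(seed, 41), list(
    Wc = matrix(rnorm(spec$conv_filters * spec$conv_kernel,
                      0, sqrt(2 / spec$conv_kernel)),
                spec$conv_filters, spec$conv_kernel),
    bc = numeric(spec$conv_filters),
    W1 = matrix(rnorm(Wd * flat, 0, sqrt(2 / flat)), Wd, flat),
    b1 = numeric(Wd),
    W2 = matrix(rnorm(Wd * Wd, 0, sqrt(2 / Wd)), Wd, Wd),
    b2 = numeric(Wd),
    W3 = matrix(rnorm(spec$outputs * Wd, 0, sqrt(2 / Wd)), spec$outputs, Wd),
    b3 = numeric(spec$outputs)))
  structure(list(spec = spec, weights = w, standardize = NULL,
                 trained = FALSE, history = NULL),
            class = "emg_cnn")
}

# ---- forward / backward -----------------------------------------------------
# Batch input layout: `inp` is B x (N * window), column n + N*(t-1) holding
# feature n at window position t. The convolution is evaluated by taking, for
# each kernel offset k, the B x (N * conv_out_len) slice of window positions
# p + k - 1 and combining slices with the kernel weights; the flattened
# feature-map column order is (feature, position, filter).

conv_slice_idx <- function(spec) {
  N <- spec$n_features; P <- spec$conv_out_len
  lapply(seq_len(spec$conv_kernel), function(k) {
    as.vector(outer(seq_len(N), (seq_len(P) + k - 2L) * N, `+`))
  })
}

cnn_forward <- function(w, spec, inp, keep = FALSE, idx = conv_slice_idx(spec)) {
  B <- nrow(inp)
  M <- spec$n_features * spec$conv_out_len
  nf <- spec$conv_filters
  SP <- matrix(0, B * M, spec$conv_kernel)
  for (k in seq_along(idx)) SP[, k] <- inp[, idx[[k]]]
  Z <- tcrossprod(SP, w$Wc)                          # (B*M) x filters
  Z <- Z + rep(w$bc, each = B * M)
  dim(Z) <- c(B, M * nf)                             # B x (M * filters)
  m0 <- Z > 0
  A0 <- Z * m0
  H1 <- tcrossprod(A0, w$W1) + rep(w$b1, each = B)
  m1 <- H1 > 0
  H1 <- H1 * m1
  H2 <- tcrossprod(H1, w$W2) + rep(w$b2, each = B)
  m2 <- H2 > 0
  H2 <- H2 * m2
  Y <- tcrossprod(H2, w$W3) + rep(w$b3, each = B)
  if (!keep) return(Y)
  list(Y = Y, H2 = H2, m2 = m2, H1 = H1, m1 = m1, A0 = A0, m0 = m0, SP = SP)
}

cnn_backward <- function(w, spec, fw, target) {
  B <- nrow(fw$Y)
  dY <- (fw$Y - target) / B                          # d(0.5*mean_b sum_o e^2)
  g <- list()
  g$W3 <- crossprod(dY, fw$H2)
  g$b3 <- colSums(dY)
  dH2 <- (dY %*% w$W3) * fw$m2
  g$W2 <- crossprod(dH2, fw$H1)
  g$b2 <- colSums(dH2)
  dH1 <- (dH2 %*% w$W2) * fw$m1
  g$W1 <- crossprod(dH1, fw$A0)
  g$b1 <- colSums(dH1)
  dZ <- (dH1 %*% w$W1) * fw$m0
  dim(dZ) <- c(B * spec$n_features * spec$conv_out_len, spec$conv_filters)
  g$Wc <- crossprod(dZ, fw$SP)
  g$bc <- colSums(dZ)
  g
}

cnn_loss <- function(Y, target) 0.5 * mean(rowSums((Y - target)^2))

# Gather window inputs for the given frame indices. `starts[f]` gives the
# first frame of the sequence containing frame f; earlier positions are
# edge-replicated from it.
gather_windows <- function(values, frames, window, starts) {
  N <- nrow(values)
  B <- length(frames)
  inp <- matrix(0, B, N * window)
  for (t in seq_len(window)) {
    src <- pmax(frames - (window - t), starts)
    inp[, ((t - 1L) * N + 1L):(t * N)] <- t(values[, src, drop = FALSE])
  }
  inp
}

# Early-stopping controller: returns the 1-based index of the validation
# check after which training halts (checks-since-best >= patience), or
# length(losses) if the budget runs out first. A strictly worsening stream
# halts after exactly patience + 1 checks.
n_checks_until_stop <- function(losses, patience) {
  best <- Inf
  since <- 0L
  for (i in seq_along(losses)) {
    if (losses[i] < best) {
      best <- losses[i]
      since <- 0L
    } else {
      since <- since + 1L
    }
    if (since >= patience) return(i)
  }
  length(losses)
}

#' Train the convolutional regression decoder
#'
#' Fits the network to one or more calibration sessions (or an aggregate).
#' Movement trials are split 60/40 into training and validation sets (the
#' split is over trials, never frames); optimization is mini-batch
#' stochastic gradient descent with momentum on the mean-squared regression
#' error, with early stopping once the validation loss has not improved for
#' `patience` consecutive checks. The returned model carries the weights of
#' the best validation checkpoint. Deterministic given `seed`.
#'
#' @param x An `emg_session`, list of sessions, or `emg_aggregate`.
#' @param model Optional pre-built [build_cnn()] model to (re)train.
#' @param learning_rate SGD learning rate.
#' @param momentum Momentum coefficient.
#' @param batch_size Mini-batch size, windows.
#' @param patience Validation checks without improvement before stopping.
#' @param val_every Mini-batches between validation checks.
#' @param max_steps Hard cap on mini-batch steps.
#' @param split Fraction of each movement's trials used for training.
#' @param standardize Z-score features per channel with training-set
#'   statistics before the network (stored in the model and applied at
#'   prediction). `FALSE` feeds raw amplitude features.
#' @param stride Keep every `stride`-th frame as a candidate window (the
#'   windows themselves still span consecutive frames).
#' @param max_train_windows,max_val_windows Caps on the number of training /
#'   validation windows (evenly thinned when exceeded).
#' @param seed Integer seed (split, initialization, batch order).
#' @param max_lag_s Reaction-lag search bound per session.
#' @return A trained `emg_cnn`; `$history` records the validation-loss
#'   trajectory and the stopping step.
#' @export
fit_cnn <- function(x, model = NULL, learning_rate = 1e-5, momentum = 0.9,
                    batch_size = 64, patience = 20, val_every = 25,
                    max_steps = 600, split = 0.6, standardize = TRUE,
                    stride = 3, max_train_windows = 6000,
                    max_val_windows = 1000, seed = 1, max_lag_s = 1.0) {
  agg <- as_aggregate(x, max_lag_s = max_lag_s)
  values <- agg$features$values
  N <- nrow(values)
  spec <- if (is.null(model)) cnn_spec(N) else model$spec
  if (spec$n_features != N)
    stopf("model expects %d features, data has %d", spec$n_features, N)

  seg <- trial_segments(agg)
  ann <- agg$annotations
  with_seed(mix_seed(seed, 73), {
    # --- 60/40 split over movement trials
    train_tr <- logical(nrow(ann))
    for (m in unique(ann$movement_id)) {
      rows <- which(ann$movement_id == m)
      if (length(rows) < 2)
        stopf("movement '%s' has a single trial; cannot split by trial", m)
      n_tr <- max(1L, round(split * length(rows)))
      n_tr <- min(n_tr, length(rows) - 1L)
      train_tr[sample(rows, n_tr)] <- TRUE
    }
    frames_of_trials <- function(rows) {
      sort(unique(unlist(lapply(rows, function(i) seg$from[i]:seg$to[i]))))
    }
    thin <- function(f, stride, cap) {
      f <- f[seq(1, length(f), by = stride)]
      if (length(f) > cap) f <- f[round(seq(1, length(f), length.out = cap))]
      f
    }
    tr_frames <- thin(frames_of_trials(which(train_tr)), stride,
                      max_train_windows)
    va_frames <- thin(frames_of_trials(which(!train_tr)), stride,
                      max_val_windows)

    std <- NULL
    if (standardize) {
      mu <- rowMeans(values[, tr_frames, drop = FALSE])
      sdv <- pmax(apply(values[, tr_frames, drop = FALSE], 1, stats::sd),
                  1e-8)
      values <- (values - mu) / sdv
      std <- list(mean = mu, sd = sdv)
    }
    targets <- t(agg$kin$values)                     # frames x 12

    if (is.null(model)) model <- build_cnn(spec, seed = sample.int(1e9, 1))
    w <- model$weights
    vel <- lapply(w, function(p) p * 0)
    va_inp <- gather_windows(values, va_frames, spec$window, agg$seq_start[va_frames])
    va_tgt <- targets[va_frames, , drop = FALSE]
    idx <- conv_slice_idx(spec)

    best <- list(loss = Inf, w = w)
    val_hist <- numeric(0)
    since_best <- 0L
    step <- 0L
    stopped <- FALSE
    while (!stopped && step < max_steps) {
      order_idx <- sample(length(tr_frames))
      for (b0 in seq(1, length(order_idx), by = batch_size)) {
        bi <- order_idx[b0:min(b0 + batch_size - 1L, length(order_idx))]
        fr <- tr_frames[bi]
        inp <- gather_windows(values, fr, spec$window, agg$seq_start[fr])
        fw <- cnn_forward(w, spec, inp, keep = TRUE, idx = idx)
        g <- cnn_backward(w, spec, fw, targets[fr, , drop = FALSE])
        for (nm in names(w)) {
          vel[[nm]] <- momentum * vel[[nm]] - learning_rate * g[[nm]]
          w[[nm]] <- w[[nm]] + vel[[nm]]
        }
        step <- step + 1L
        if (step %% val_every == 0L) {
          vl <- cnn_loss(cnn_forward(w, spec, va_inp, idx = idx), va_tgt)
          val_hist <- c(val_hist, vl)
          if (vl < best$loss) {
            best <- list(loss = vl, w = w)
            since_best <- 0L
          } else {
            since_best <- since_best + 1L
          }
          if (since_best >= patience) { stopped <- TRUE; break }
        }
        if (step >= max_steps) { stopped <- TRUE; break }
      }
    }
    model$weights <- best$w
    model$standardize <- std
    model$trained <- TRUE
    model$history <- list(val_loss = val_hist, best_val_loss = best$loss,
                          steps = step, stopped_early = since_best >= patience)
    model
  })
}

#' Decode a feature sequence with a trained network
#'
#' Per frame `t` the input window is frames `t-9 .. t`; the first frames of
#' each sequence are edge-replicated. Outputs are clamped to \eqn{[-1, 1]}.
#'
#' @param object An `emg_cnn`.
#' @param newdata An `emg_session` or `feature_matrix`.
#' @param chunk Frames decoded per forward pass.
#' @param ... Unused.
#' @return A `decoded_trace`.
#' @export
predict.emg_cnn <- function(object, newdata, chunk = 1024, ...) {
  fe <- if (inherits(newdata, "emg_session")) session_features(newdata) else
    newdata
  stopifnot(inherits(fe, "feature_matrix"))
  values <- fe$values
  if (nrow(values) != object$spec$n_features)
    stopf("feature count (%d) does not match model (%d)",
          nrow(values), object$spec$n_features)
  if (!is.null(object$standardize))
    values <- (values - object$standardize$mean) / object$standardize$sd
  Tn <- ncol(values)
  out <- matrix(0, object$spec$outputs, Tn)
  starts <- rep(1L, Tn)
  idx <- conv_slice_idx(object$spec)
  for (c0 in seq(1, Tn, by = chunk)) {
    fr <- c0:min(c0 + chunk - 1L, Tn)
    inp <- gather_windows(values, fr, object$spec$window, starts[fr])
    out[, fr] <- t(cnn_forward(object$weights, object$spec, inp, idx = idx))
  }
  structure(list(values = clamp(out), raw = out), class = "decoded_trace")
}

#' @export
print.emg_cnn <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "Convolutional regression decoder: %d x %d input -> %d filters (1x%d) -> FC %d -> FC %d -> %d outputs\n",
    s$n_features, s$window, s$conv_filters, s$conv_kernel,
    s$fc_width, s$fc_width, s$outputs))
  cat(sprintf("  %s, %d parameters\n",
              if (x$trained) "trained" else "untrained",
              cnn_param_count(s)))
  invisible(x)
}

#' @export
summary.emg_cnn <- function(object, ...) {
  print(object)
  if (object$trained) {
    h <- object$history
    cat(sprintf("  %d SGD steps, best validation loss %.4g (%s)\n",
                h$steps, h$best_val_loss,
                if (h$stopped_early) "early-stopped" else "step budget"))
  }
  invisible(object)
}

#' @export
coef.emg_cnn <- function(object, ...) object$weights
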