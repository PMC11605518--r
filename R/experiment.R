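#' Aggregate training sessions into one dataset
#'
#' Concatenates the `K` sessions immediately preceding the train/test
#' boundary (the last `K` of the supplied list) into a single training
#' dataset: per-session reaction-lag alignment is applied before
#' concatenation, annotation frame spans are offset, and windows of
#' window-based decoders never straddle a session boundary.
#'
#' @param sessions List of `emg_session`, ordered by day.
#' @param K Number of most recent sessions to aggregate.
#' @param max_lag_s Per-session reaction-lag search bound, seconds.
#' @return An object of class `emg_aggregate`: `features`, `kin`,
#'   `annotations` (with `session` and `day_index` columns), `seq_start`
#'   (per-frame index of the owning session's first frame), `session_days`,
#'   `lags`.
#' @export
build_aggregated_training <- function(sessions, K = length(sessions),
                                      max_lag_s = 1.0) {
  if (K <= 0) stopf("K must be positive")
  if (K > length(sessions))
    stopf("K (%d) exceeds the number of sessions (%d)", K, length(sessions))
  sessions <- sessions[(length(sessions) - K + 1L):length(sessions)]
  as_aggregate(sessions, max_lag_s = max_lag_s)
}

# Coerce a session / session list / aggregate to an aggregate.
as_aggregate <- function(x, max_lag_s = 1.0) {
  if (inherits(x, "emg_aggregate")) return(x)
  if (inherits(x, "emg_session")) x <- list(x)
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "emg_session")))
  feats <- list(); kins <- list(); anns <- list(); seq_start <- integer(0)
  lags <- integer(length(x)); days <- integer(length(x))
  off <- 0L
  for (i in seq_along(x)) {
    s <- x[[i]]
    fe <- session_features(s)
    kin <- s$kin
    n_fr <- min(ncol(fe$values), ncol(kin$values))
    fe$values <- fe$values[, seq_len(n_fr), drop = FALSE]
    kin$values <- kin$values[, seq_len(n_fr), drop = FALSE]
    al <- align_lag(fe, kin, max_lag_s = max_lag_s)
    lags[i] <- al$lag_frames
    days[i] <- s$day_index
    ann <- al$kin$annotations
    ann$frame_start <- pmin(ann$frame_start + off, off + n_fr)
    ann$frame_end <- pmin(ann$frame_end + off, off + n_fr)
    ann$session <- i
    ann$day_index <- s$day_index
    feats[[i]] <- fe$values
    kins[[i]] <- al$kin$values
    anns[[i]] <- ann
    seq_start <- c(seq_start, rep(off + 1L, n_fr))
    off <- off + n_fr
  }
  n_feat <- unique(vapply(feats, nrow, 1L))
  if (length(n_feat) != 1) stopf("sessions have differing feature counts")
  annotations <- do.call(rbind, anns)
  fe1 <- if (!is.null(x[[1]]$features)) x[[1]]$features else NULL
  fm <- feature_matrix(do.call(cbind, feats), x[[1]]$kin$frame_rate,
                       if (!is.null(fe1)) fe1$channel_labels else
                         channel_labels(x[[1]]$n_contacts))
  structure(list(features = fm,
                 kin = kin_trace(do.call(cbind, kins),
                                 x[[1]]$kin$frame_rate, annotations),
                 annotations = annotations, seq_start = seq_start,
                 session_days = days, lags = lags, n_sessions = length(x)),
            class = "emg_aggregate")
}

#' @export
print.emg_aggregate <- function(x, ...) {
  cat(sprintf(
    "Aggregated training data: %d sessions (days %s), %d frames, %d trials\n",
    x$n_sessions, paste(x$session_days, collapse = ", "),
    ncol(x$features$values), nrow(x$annotations)))
  invisible(x)
}

# Frame segments owned by each trial: the trial span plus the rest that
# follows it (up to the next trial or the session end); the session's
# leading rest is attached to its first trial.
trial_segments <- function(agg) {
  ann <- agg$annotations
  n <- nrow(ann)
  from <- integer(n); to <- integer(n)
  for (s in unique(ann$session)) {
    rows <- which(ann$session == s)
    rows <- rows[order(ann$frame_start[rows])]
    s_start <- agg$seq_start[ann$frame_start[rows[1]]]
    s_end <- max(which(agg$seq_start == s_start))
    for (j in seq_along(rows)) {
      i <- rows[j]
      from[i] <- if (j == 1) s_start else ann$frame_start[i]
      to[i] <- if (j < length(rows)) ann$frame_start[rows[j + 1]] - 1L else
        s_end
    }
  }
  list(from = from, to = to)
}

#' Configuration for an aggregated-training comparison
#'
#' @param aggregation_sizes Numbers of prior sessions to aggregate.
#' @param decoders Character subset of `c("mkf", "cnn")`, or a named list of
#'   custom decoders (each a list with functions `fit(aggregate)` and
#'   `predict(model, features)` returning a `decoded_trace`).
#' @param train_days,test_days Day indices of training and testing sessions.
#' @param mkf_args,cnn_args Extra arguments passed to [fit_mkf()] /
#'   [fit_cnn()].
#' @param seed Seed forwarded to decoder training.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(aggregation_sizes = c(1, 5, 10),
                              decoders = c("mkf", "cnn"),
                              train_days, test_days,
                              mkf_args = list(), cnn_args = list(),
                              seed = 1) {
  if (max(aggregation_sizes) > length(train_days))
    stopf("max aggregation size (%d) exceeds training sessions (%d)",
          max(aggregation_sizes), length(train_days))
  if (max(train_days) >= min(test_days))
    stopf("training days must precede testing days")
  structure(list(aggregation_sizes = as.integer(aggregation_sizes),
                 decoders = decoders, train_days = train_days,
                 test_days = test_days, mkf_args = mkf_args,
                 cnn_args = cnn_args, seed = as.integer(seed)),
            class = "experiment_config")
}

decoder_table <- function(config) {
  dec <- config$decoders
  if (is.character(dec)) {
    cnn_args <- config$cnn_args
    if (is.null(cnn_args$seed)) cnn_args$seed <- config$seed
    out <- list()
    for (d in dec) {
      out[[d]] <- switch(
        d,
        mkf = list(
          fit = function(agg) do.call(fit_mkf, c(list(agg),
                                                 config$mkf_args)),
          predict = function(model, fe) predict(model, fe)),
        cnn = list(
          fit = function(agg) do.call(fit_cnn, c(list(agg), cnn_args)),
          predict = function(model, fe) predict(model, fe)),
        stopf("unknown decoder '%s'", d))
    }
    out
  } else dec
}

#' Run the aggregated-training offline comparison
#'
#' For each decoder and each aggregation size `K`, trains on the `K` most
#' recent training sessions and decodes every test session; per-trial
#' intended/unintended RMSE and days-since-training are emitted. Test
#' kinematics are reaction-lag aligned (one shift per session, applied
#' identically across conditions) before scoring.
#'
#' @param config An [experiment_config()].
#' @param study List of `emg_session` covering the configured days.
#' @return Data frame, one row per decoder x K x test session x trial, with
#'   columns `decoder`, `K`, `test_day`, `days_since_training`,
#'   `movement_id`, `dof`, `trial`, `intended`, `unintended`.
#' @export
run_offline_experiment <- function(config, study) {
  stopifnot(inherits(config, "experiment_config"))
  days <- vapply(study, function(s) s$day_index, 1L)
  train_sessions <- study[days %in% config$train_days]
  test_sessions <- study[days %in% config$test_days]
  if (length(train_sessions) < max(config$aggregation_sizes))
    stopf("study does not cover the configured training days")
  if (length(test_sessions) == 0) stopf("study has no test sessions")

  # align each test session once, decode against the shifted kinematics
  test_prepped <- lapply(test_sessions, function(s) {
    fe <- session_features(s)
    n_fr <- min(ncol(fe$values), ncol(s$kin$values))
    fe$values <- fe$values[, seq_len(n_fr), drop = FALSE]
    kin <- s$kin
    kin$values <- kin$values[, seq_len(n_fr), drop = FALSE]
    al <- align_lag(fe, kin)
    list(day = s$day_index, features = fe, kin = al$kin,
         annotations = al$kin$annotations)
  })

  rows <- list()
  decs <- decoder_table(config)
  for (K in config$aggregation_sizes) {
    agg <- build_aggregated_training(train_sessions, K)
    newest_train_day <- max(agg$session_days)
    for (dn in names(decs)) {
      model <- decs[[dn]]$fit(agg)
      for (tp in test_prepped) {
        dec <- decs[[dn]]$predict(model, tp$features)
        ann <- tp$annotations
        for (i in seq_len(nrow(ann))) {
          r <- intended_unintended_rmse(dec, tp$kin, ann[i, ])
          rows[[length(rows) + 1L]] <- data.frame(
            decoder = dn, K = K, test_day = tp$day,
            days_since_training = tp$day - newest_train_day,
            movement_id = ann$movement_id[i],
            dof = unlist(ann$dofs[i])[1], trial = i,
            intended = r[["intended"]], unintended = r[["unintended"]])
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Principal-component view of the pooled feature space
#'
#' Pools the feature frames of all sessions into one matrix, mean-centers
#' it, and takes the singular value decomposition; scores on the first two
#' components are returned per frame, labelled by session day and by the
#' movement active at that frame (rest frames are dropped), so that
#' between-day drift of a movement's feature cluster can be inspected.
#'
#' @param sessions List of `emg_session` (>= 2).
#' @return An object of class `pca_projection`: `components` (features x 2,
#'   orthonormal), `explained_variance` (fractions, nonincreasing), and
#'   `scores` (data frame: `day`, `movement_id`, `pc1`, `pc2`).
#' @export
pca_feature_space <- function(sessions) {
  if (length(sessions) < 2) stopf("need at least 2 sessions")
  mats <- list(); day <- list(); mov <- list()
  for (s in sessions) {
    fe <- session_features(s)
    lab <- rep(NA_character_, ncol(fe$values))
    ann <- s$annotations
    for (i in seq_len(nrow(ann)))
      lab[ann$frame_start[i]:min(ann$frame_end[i], length(lab))] <-
        ann$movement_id[i]
    mats[[length(mats) + 1L]] <- t(fe$values)
    day[[length(day) + 1L]] <- rep(s$day_index, ncol(fe$values))
    mov[[length(mov) + 1L]] <- lab
  }
  X <- do.call(rbind, mats)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 2)
  if (sum(sv$d > sv$d[1] * 1e-12) < 2) stopf("feature space has rank < 2")
  var_frac <- sv$d^2 / sum(sv$d^2)
  scores <- Xc %*% sv$v
  keep <- !is.na(unlist(mov))
  structure(list(components = sv$v, explained_variance = var_frac[1:2],
                 singular_values = sv$d,
                 scores = data.frame(day = unlist(day)[keep],
                                     movement_id = unlist(mov)[keep],
                                     pc1 = scores[keep, 1],
                                     pc2 = scores[keep, 2])),
            class = "pca_projection")
}

#' @export
print.pca_projection <- function(x, ...) {
  cat(sprintf(
    "Feature-space PCA: first two components explain %.1f%% + %.1f%% of variance\n",
    100 * x$explained_variance[1], 100 * x$explained_variance[2]))
  invisible(x)
}

#' Offline replay of the target-touching task
#'
#' Synthesizes target-holding trials (a simulated user driving one DOF to a
#' target and holding it, with reaction lag and noise), decodes them, and
#' scores every trial with the task's metric set: windowed intended and
#' unintended RMSE (errors within the +/-15% window count as zero), percent
#' time in target, longest hold, and log mean absolute jerk of the active
#' DOF.
#'
#' @param decoder A fitted `mkf_decoder` or `emg_cnn` (or a custom list with
#'   a `predict(model, features)` function in `$predict` and the model in
#'   `$model`).
#' @param subject The [subject_model()] to synthesize with (drift it first
#'   via [apply_day_drift()] for a specific day).
#' @param protocol A [ttt_protocol()].
#' @param seed Session noise seed.
#' @param window Tolerance half-width.
#' @return Data frame, one row per trial: `movement_id`, `dof`, `amplitude`,
#'   `intended_wrmse`, `unintended_wrmse`, `pct_time_in_target`,
#'   `max_hold_s`, `log_mean_abs_jerk`.
#' @export
run_ttt_replay <- function(decoder, subject, protocol = ttt_protocol(),
                           seed = 1, window = 0.15) {
  kin <- make_kinematic_trace(protocol)
  fe <- synthesize_features(kin, subject, seed = seed)
  dec <- if (is.list(decoder) && !is.null(decoder$predict))
    decoder$predict(decoder$model, fe) else predict(decoder, fe)
  al <- align_lag(fe, kin)
  kin_al <- al$kin
  ann <- kin_al$annotations
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    span <- ann$frame_start[i]:ann$frame_end[i]
    dofs <- unlist(ann$dofs[i])
    restd <- setdiff(seq_len(N_DOF), dofs)
    D <- dec$values[, span, drop = FALSE]
    Tg <- kin_al$values[, span, drop = FALSE]
    occ <- ttt_occupancy(D, Tg, window = window,
                         frame_rate = kin_al$frame_rate)
    data.frame(
      movement_id = ann$movement_id[i], dof = dofs[1],
      amplitude = ann$amplitude[i],
      intended_wrmse = windowed_rmse(D[dofs, , drop = FALSE],
                                     Tg[dofs, , drop = FALSE], window),
      unintended_wrmse = windowed_rmse(D[restd, , drop = FALSE],
                                       Tg[restd, , drop = FALSE], window),
      pct_time_in_target = occ[["pct_time_in_target"]],
      max_hold_s = occ[["max_hold_s"]],
      log_mean_abs_jerk = suppressWarnings(
        log_mean_abs_jerk(D[dofs, , drop = FALSE], kin_al$frame_rate)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full multi-subject aggregation study on synthetic data
#'
#' The package's end-to-end experiment: for each seed a synthetic subject is
#' drawn, a multi-session study with day-indexed drift is generated
#' (feature-level, for tractable run times), and the aggregated-training
#' comparison is run for both decoders. Per-seed condition summaries (mean
#' intended/unintended RMSE and the median per-DOF robustness slope) are
#' returned alongside the per-trial table.
#'
#' @param n_seeds Number of synthetic subjects.
#' @param n_contacts Contacts per subject (feature count is
#'   `n + choose(n, 2)`).
#' @param protocol Calibration protocol for every session.
#' @param train_days,test_days Session day indices.
#' @param aggregation_sizes Aggregation sizes compared.
#' @param decoders Decoders compared.
#' @param drift Drift model template (its seed is re-derived per subject).
#' @param base_seed Base seed; subject s uses seeds derived from
#'   `base_seed + s`.
#' @param cnn_args,mkf_args Passed through to the experiment config.
#' @return List with `trials` (all per-trial rows, with a `seed` column) and
#'   `summary` (per seed x decoder x K: `intended`, `unintended`, `slope`).
#' @export
run_aggregation_study <- function(n_seeds = 10, n_contacts = 11,
                                  protocol = default_protocol(
                                    n_dofs = 4, trials_per_movement = 6),
                                  train_days = seq(0, 27, by = 3),
                                  test_days = c(31, 59),
                                  aggregation_sizes = c(1, 5, 10),
                                  decoders = c("mkf", "cnn"),
                                  drift = drift_model(),
                                  base_seed = 1,
                                  cnn_args = list(), mkf_args = list()) {
  all_rows <- list(); summ <- list()
  for (s in seq_len(n_seeds)) {
    subj_seed <- mix_seed(base_seed, 301, s)
    subject <- subject_model(n_contacts = n_contacts, seed = subj_seed)
    drift_s <- drift
    drift_s$seed <- mix_seed(base_seed, 303, s)
    study <- generate_study(subject, protocol, drift_s,
                            c(train_days, test_days), level = "features",
                            seed = mix_seed(base_seed, 305, s))
    config <- experiment_config(aggregation_sizes = aggregation_sizes,
                                decoders = decoders,
                                train_days = train_days,
                                test_days = test_days,
                                cnn_args = cnn_args, mkf_args = mkf_args,
                                seed = mix_seed(base_seed, 307, s))
    res <- run_offline_experiment(config, study)
    res$seed <- s
    all_rows[[s]] <- res
    for (dn in unique(res$decoder)) {
      for (K in unique(res$K)) {
        sub <- res[res$decoder == dn & res$K == K, ]
        per_dof <- stats::aggregate(intended ~ dof + test_day +
                                      days_since_training, sub, mean)
        sl <- robustness_slopes(data.frame(dof = per_dof$dof,
                                           day = per_dof$days_since_training,
                                           rmse = per_dof$intended))
        summ[[length(summ) + 1L]] <- data.frame(
          seed = s, decoder = dn, K = K,
          intended = mean(sub$intended), unintended = mean(sub$unintended),
          slope = stats::median(sl$slope))
      }
    }
  }
  list(trials = do.call(rbind, all_rows), summary = do.call(rbind, summ))
}
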