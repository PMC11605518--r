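small_study <- function(seed = 30, days = c(0, 1, 2, 5, 6), n_dofs = 2,
                        trials = 2, drift = drift_model(seed = seed)) {
  generate_study(tiny_subject(seed = seed), tiny_protocol(n_dofs, trials),
                 drift, days, level = "features", seed = seed)
}

test_that("aggregation bookkeeping: counts, identity, frame sums", {
  st <- small_study()
  agg <- build_aggregated_training(st[1:3], K = 3)
  expect_equal(agg$n_sessions, 3)
  # trial counts sum across sessions
  expect_equal(nrow(agg$annotations), 3 * nrow(st[[1]]$annotations))
  # frame count is the sum of individual frame counts
  expect_equal(ncol(agg$features$values),
               sum(vapply(st[1:3], function(s) ncol(s$features$values), 1)))
  # K = 1 aggregates exactly the last session
  a1 <- build_aggregated_training(st[1:3], K = 1)
  expect_equal(a1$session_days, st[[3]]$day_index)
  expect_equal(ncol(a1$features$values), ncol(st[[3]]$features$values))
  expect_error(build_aggregated_training(st, K = 0), "positive")
  expect_error(build_aggregated_training(st, K = 9), "exceeds")
  # per-frame sequence starts mark session boundaries
  expect_equal(unique(agg$seq_start),
               cumsum(c(1, vapply(st[1:2], function(s)
                 ncol(s$features$values), 1))))
})

test_that("offline experiment enumerates conditions and scores trials", {
  st <- small_study(seed = 31)
  cfg <- experiment_config(aggregation_sizes = c(1, 2, 3),
                           decoders = c("mkf"),
                           train_days = c(0, 1, 2), test_days = c(5, 6),
                           mkf_args = list(k = 10))
  res <- run_offline_experiment(cfg, st)
  # rows = conditions x test sessions x trials
  expect_equal(nrow(res), 3 * 2 * nrow(st[[1]]$annotations))
  expect_setequal(unique(res$K), c(1, 2, 3))
  expect_true(all(res$days_since_training == res$test_day - 2))
  expect_true(all(res$intended >= 0 & res$unintended >= 0))
})

test_that("config validation enforces the design invariants", {
  expect_error(experiment_config(aggregation_sizes = c(1, 5),
                                 train_days = 0:2, test_days = 4:5),
               "exceeds")
  expect_error(experiment_config(aggregation_sizes = 1,
                                 train_days = 0:3, test_days = c(2, 9)),
               "precede")
})

test_that("six conditions arise from two decoders and three sizes", {
  st <- small_study(seed = 32, days = c(0:2, 4, 5), trials = 2)
  # oracle decoder stub standing in for both algorithms: returns the
  # lag-aligned target kinematics, so every condition scores RMSE 0
  kin0 <- st[[1]]$kin  # identical prompted kinematics on every day
  stub_predict <- function(model, fe) {
    structure(list(values = align_lag(fe, kin0)$kin$values),
              class = "decoded_trace")
  }
  cfg <- experiment_config(aggregation_sizes = c(1, 2, 3),
                           decoders = list(mkf_stub = list(
                             fit = function(agg) NULL,
                             predict = stub_predict),
                             cnn_stub = list(
                               fit = function(agg) NULL,
                               predict = stub_predict)),
                           train_days = 0:2, test_days = c(4, 5))
  res <- run_offline_experiment(cfg, st)
  conds <- unique(res[, c("decoder", "K")])
  expect_equal(nrow(conds), 6)
  expect_lt(max(res$intended), 1e-10)
  expect_lt(max(res$unintended), 1e-10)
})

test_that("feature-space PCA matches a covariance eigendecomposition", {
  set.seed(40)
  st <- small_study(seed = 40, days = c(0, 3))
  pr <- pca_feature_space(st)
  X <- cbind(st[[1]]$features$values, st[[2]]$features$values)
  or <- oracle_pca_eig(t(X))
  # components match up to sign
  for (j in 1:2) {
    v <- pr$components[, j]; w <- or$vectors[, j]
    expect_lt(min(sum((v - w)^2), sum((v + w)^2)), 1e-8)
  }
  expect_equal(pr$explained_variance, or$var_frac, tolerance = 1e-8)
  expect_true(all(diff(pr$explained_variance) <= 0))
  # orthonormality
  expect_equal(crossprod(pr$components), diag(2), tolerance = 1e-10)
  expect_error(pca_feature_space(st[1]), "at least 2")
})

test_that("PCA is invariant to frame duplication and detects planar data", {
  # rank-2 toy embedded in 5 channels
  set.seed(41)
  basis <- matrix(rnorm(10), 5, 2)
  scores <- matrix(rnorm(2 * 200), 2)
  vals <- basis %*% scores
  mk_ses <- function(v) {
    ann <- data.frame(movement_id = "m", direction = 1, amplitude = 1,
                      frame_start = 1, frame_end = ncol(v))
    ann$dofs <- list(1L)
    kin <- structure(list(values = matrix(0, 12, ncol(v)), frame_rate = 30,
                          annotations = ann), class = "kin_trace")
    structure(list(day_index = 0L, kin = kin, annotations = ann,
                   features = feature_matrix(v + 2), n_contacts = 5L),
              class = "emg_session")
  }
  pr <- pca_feature_space(list(mk_ses(vals[, 1:100]), mk_ses(vals[, 101:200])))
  expect_equal(sum(pr$explained_variance), 1, tolerance = 1e-10)
  dup <- pca_feature_space(list(mk_ses(vals), mk_ses(vals)))
  for (j in 1:2)
    expect_lt(min(sum((pr$components[, j] - dup$components[, j])^2),
                  sum((pr$components[, j] + dup$components[, j])^2)), 1e-8)
})

test_that("the TTT replay enumerates 120 five-second trials and scores stubs", {
  proto <- ttt_protocol()
  kin <- make_kinematic_trace(proto)
  expect_equal(nrow(kin$annotations), 120)  # 12 movements x (5 + 5) trials
  spans <- kin$annotations$frame_end - kin$annotations$frame_start + 1L
  expect_true(all(spans == 150))            # 5 s at 30 Hz
  subj <- tiny_subject(seed = 50)
  # oracle stub returning the aligned targets scores perfectly
  stub <- list(model = NULL,
               predict = function(model, fe)
                 structure(list(values = align_lag(fe, kin)$kin$values),
                           class = "decoded_trace"))
  tab <- run_ttt_replay(stub, subj, proto, seed = 2)
  expect_equal(nrow(tab), 120)
  expect_true(all(tab$pct_time_in_target == 100))
  expect_true(all(tab$intended_wrmse == 0))
  expect_setequal(unique(tab$amplitude), c(0.5, 1))
})

test_that("a trained Kalman decoder performs the TTT replay credibly", {
  subj <- tiny_subject(seed = 51, n_contacts = 6)
  proto_cal <- tiny_protocol(2, 3)
  ses <- generate_study(subj, proto_cal, drift_model(0, 0, 0, 0, seed = 1), 0,
                        level = "features", seed = 7)[[1]]
  mkf <- fit_mkf(ses, k = 12)
  tab <- run_ttt_replay(mkf, subj, ttt_protocol(n_dofs = 2), seed = 3)
  expect_equal(nrow(tab), 40)  # 2 DOFs x 2 dirs x 2 amps x 5 trials
  # trained DOFs (1-2) are held in target most of the time
  expect_gt(median(tab$pct_time_in_target), 50)
  expect_true(all(is.finite(tab$log_mean_abs_jerk) |
                    tab$log_mean_abs_jerk == -Inf))
})
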