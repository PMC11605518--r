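test_that("kinematic trace follows the trapezoid protocol", {
  p <- movement_protocol(list(list(id = "m1", dofs = 3, direction = 1,
                                   amplitude = 1)),
                         trials_per_movement = 1)
  tr <- make_kinematic_trace(p, frame_rate = 30)
  ann <- tr$annotations
  expect_equal(nrow(ann), 1)
  # 3 + 1 + 3 s movement = 210 frames at 30 Hz
  expect_equal(ann$frame_end - ann$frame_start + 1L, 210L)
  span <- ann$frame_start:ann$frame_end
  # mid-hold: active DOF at +amplitude, every other DOF zero everywhere
  mid_hold <- ann$frame_start + 90 + 15
  expect_equal(tr$values[3, mid_hold], 1)
  expect_true(all(tr$values[-3, ] == 0))
  expect_true(all(tr$values[3, -span] == 0))
})

test_that("extension trials ramp negative and amplitudes scale", {
  p <- movement_protocol(list(list(id = "e", dofs = 1, direction = -1,
                                   amplitude = 0.5)),
                         trials_per_movement = 2)
  tr <- make_kinematic_trace(p)
  expect_equal(min(tr$values[1, ]), -0.5)
  expect_true(all(tr$values[1, ] <= 0))
  expect_equal(nrow(tr$annotations), 2)
})

test_that("time-dilated protocol reproduces the default trace under index mapping", {
  p1 <- movement_protocol(list(list(id = "m", dofs = 1, direction = 1,
                                    amplitude = 0.8)),
                          trials_per_movement = 1)
  p2 <- movement_protocol(list(list(id = "m", dofs = 1, direction = 1,
                                    amplitude = 0.8)),
                          trials_per_movement = 1,
                          rise_s = 6, hold_s = 2, return_s = 6)
  t1 <- make_kinematic_trace(p1)
  t2 <- make_kinematic_trace(p2)
  a1 <- t1$annotations; a2 <- t2$annotations
  off1 <- seq_len(a1$frame_end - a1$frame_start + 1L)
  # within-trial frame 2j of the dilated trace equals frame j of the default
  expect_equal(t2$values[1, a2$frame_start - 1L + 2L * off1],
               t1$values[1, a1$frame_start - 1L + off1])
})

test_that("protocol validation rejects bad movements", {
  expect_error(movement_protocol(list()), "at least one movement")
  expect_error(movement_protocol(list(list(dofs = 1, amplitude = 1.5))),
               "amplitude")
  expect_error(movement_protocol(list(list(dofs = 14, amplitude = 1))),
               "DOF indices")
})

test_that("EMG rest amplitude matches the closed-form rectified-Gaussian mean", {
  # long all-rest recording: per-contact MAV ~ sqrt(base^2+noise^2)*sqrt(2/pi)
  subj <- subject_model(n_contacts = 3, seed = 2,
                        mixing = matrix(0.5, 3, 24),
                        rest_baseline = c(0.4, 0.8, 1.2),
                        noise_sd = c(0, 0, 0), reaction_lag_s = 0)
  p <- movement_protocol(list(list(dofs = 1, amplitude = 1)),
                         trials_per_movement = 1, inter_trial_s = 40,
                         rise_s = 0.2, hold_s = 0.1, return_s = 0.2)
  kin <- make_kinematic_trace(p)
  kin$values[] <- 0  # force all-rest
  emg <- synthesize_emg(kin, subj, seed = 7)
  mav <- rowMeans(abs(emg$values))
  expect_equal(mav, c(0.4, 0.8, 1.2) * sqrt(2 / pi), tolerance = 0.1)
})

test_that("doubling a mixing row doubles the rest-subtracted driven MAV", {
  mk <- function(scale) {
    M <- matrix(0.05, 2, 24); M[1, 1] <- 0.8 * scale; M[2, 1] <- 0.8
    subject_model(n_contacts = 2, mixing = M, rest_baseline = c(0, 0),
                  noise_sd = c(0, 0), reaction_lag_s = 0)
  }
  p <- movement_protocol(list(list(dofs = 1, direction = 1, amplitude = 1)),
                         trials_per_movement = 2, inter_trial_s = 0.5)
  kin <- make_kinematic_trace(p)
  e1 <- synthesize_emg(kin, mk(1), seed = 5)
  e2 <- synthesize_emg(kin, mk(2), seed = 5)
  drive <- colSums(abs(e1$values)) > 0
  m1 <- mean(abs(e1$values[1, ]))
  m2 <- mean(abs(e2$values[1, ]))
  expect_equal(m2 / m1, 2, tolerance = 0.05)
})

test_that("zero noise, zero baseline, rest kinematics give an all-zero recording", {
  subj <- subject_model(n_contacts = 2, mixing = matrix(1, 2, 24),
                        rest_baseline = c(0, 0), noise_sd = c(0, 0))
  p <- movement_protocol(list(list(dofs = 1, amplitude = 1)),
                         trials_per_movement = 1)
  kin <- make_kinematic_trace(p)
  kin$values[] <- 0
  emg <- synthesize_emg(kin, subj, seed = 1)
  expect_true(all(emg$values == 0))
})

test_that("day drift honours identity and determinism contracts", {
  subj <- tiny_subject()
  dr <- drift_model(seed = 11)
  expect_identical(apply_day_drift(subj, dr, 0), subj)
  dr0 <- drift_model(0, 0, 0, 0, seed = 11)
  expect_identical(apply_day_drift(subj, dr0, 25), subj)
  d1 <- apply_day_drift(subj, dr, 7)
  d2 <- apply_day_drift(subj, dr, 7)
  expect_identical(d1, d2)
  expect_false(identical(d1$mixing, subj$mixing))
  expect_error(apply_day_drift(subj, dr, -1), "day_index")
  # invariants preserved under drift
  expect_true(all(d1$mixing >= 0))
  expect_true(all(d1$rest_baseline >= 0))
})

test_that("drifted sessions separate from day 0 increasingly with day gap", {
  # monotone (in expectation) growth of feature-centroid distance with days
  dists <- sapply(1:20, function(s) {
    subj <- subject_model(n_contacts = 5, seed = s)
    dr <- drift_model(seed = 100 + s)
    st <- generate_study(subj, tiny_protocol(1, 2), dr, c(0, 5, 40),
                         level = "features", seed = s)
    cents <- lapply(st, function(ss) rowMeans(ss$features$values))
    c(d5 = sqrt(sum((cents[[2]] - cents[[1]])^2)),
      d40 = sqrt(sum((cents[[3]] - cents[[1]])^2)))
  })
  expect_gt(mean(dists["d40", ]), mean(dists["d5", ]))
})

test_that("generate_study returns one session per day with matching indices", {
  subj <- tiny_subject()
  days <- c(0:9, 12, 15, 18, 21, 24, 27)  # 10 training + 6 testing days
  st <- generate_study(subj, tiny_protocol(1, 1), drift_model(seed = 2), days,
                       level = "features")
  expect_length(st, 16)
  expect_equal(vapply(st, function(s) s$day_index, 1L), as.integer(days))
  expect_identical(generate_study(subj, tiny_protocol(), drift_model(seed = 1),
                                  integer(0)), list())
  expect_error(generate_study(subj, tiny_protocol(), drift_model(seed = 1),
                              c(5, 3)), "nondecreasing")
})

test_that("zero drift keeps feature distributions indistinguishable across days", {
  subj <- tiny_subject(seed = 8)
  dr0 <- drift_model(0, 0, 0, 0, seed = 8)
  st <- generate_study(subj, tiny_protocol(2, 3), dr0, c(0, 100),
                       level = "features", seed = 21)
  m0 <- colMeans(st[[1]]$features$values)  # per-frame mean MAV
  m1 <- colMeans(st[[2]]$features$values)
  expect_gt(t.test(m0, m1)$p.value, 0.01)
  # and with drift on, the same comparison separates clearly
  dr <- drift_model(seed = 8)
  std <- generate_study(subj, tiny_protocol(2, 3), dr, c(0, 100),
                        level = "features", seed = 21)
  expect_lt(t.test(colMeans(std[[1]]$features$values),
                   colMeans(std[[2]]$features$values))$p.value, 0.01)
})

test_that("feature-level shortcut matches the raw-EMG chain at the envelope level", {
  subj <- subject_model(n_contacts = 4, seed = 5, reaction_lag_s = 0)
  p <- tiny_protocol(1, 2)
  kin <- make_kinematic_trace(p)
  fe_fast <- synthesize_features(kin, subj, seed = 3, mav_noise_frac = 0)
  ses <- generate_study(subj, p, drift_model(0, 0, 0, 0, seed = 1), 0,
                        level = "emg", seed = 3)[[1]]
  fe_full <- session_features(ses)
  n_fr <- min(ncol(fe_fast$values), ncol(fe_full$values))
  # compare per-channel means over frames (filters/windowing smear per-frame)
  r <- rowMeans(fe_full$values[, 31:n_fr]) / rowMeans(fe_fast$values[, 31:n_fr])
  expect_true(all(abs(r - 1) < 0.1))
})

test_that("sessions round-trip through the on-disk layout", {
  ses <- tiny_session(seed = 4)
  dir <- tempfile("ses")
  write_session(ses, dir)
  back <- read_session(dir)
  expect_equal(back$day_index, ses$day_index)
  expect_equal(back$features$values, ses$features$values, tolerance = 1e-12)
  expect_equal(back$kin$values, ses$kin$values, tolerance = 1e-12)
  expect_equal(back$annotations$frame_start, ses$annotations$frame_start)
  expect_equal(unlist(back$annotations$dofs), unlist(ses$annotations$dofs))
  unlink(dir, recursive = TRUE)
})
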