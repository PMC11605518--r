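test_that("filter cascade attenuates mains and DC but passes the EMG band", {
  fs <- 1000
  t <- seq_len(6 * fs) / fs
  steady <- (2 * fs):(6 * fs)  # skip causal transients
  run <- function(x) {
    out <- bandpass_notch(as_recording(matrix(x, 1), fs))
    out$values[1, steady]
  }
  # pure 60 Hz line noise: steady-state amplitude < 5% of input
  amp60 <- max(abs(run(sin(2 * pi * 60 * t))))
  expect_lt(amp60, 0.05)
  # DC is killed by the 15 Hz high-pass
  expect_lt(max(abs(run(rep(1, length(t))))), 1e-3)
  # 100 Hz rides through with pass-band gain in [0.7, 1.1]
  amp100 <- max(abs(run(sin(2 * pi * 100 * t))))
  expect_gt(amp100, 0.7)
  expect_lt(amp100, 1.1)
})

test_that("filter frequency response matches the designed cascade", {
  # oracle: product of the designed transfer functions evaluated on the grid
  spec <- filter_spec()
  filts <- emgagg:::filter_cascade(spec)
  gain_at <- function(f_hz) {
    w <- 2 * pi * f_hz / spec$fs
    z <- exp(1i * w)
    prod(vapply(filts, function(fl) {
      abs(sum(fl$b * z^(-(seq_along(fl$b) - 1))) /
            sum(fl$a * z^(-(seq_along(fl$a) - 1))))
    }, numeric(1)))
  }
  expect_lt(gain_at(60), 0.05)
  expect_lt(gain_at(120), 0.05)
  expect_lt(gain_at(180), 0.05)
  expect_gt(gain_at(100), 0.7)
  expect_lt(gain_at(100), 1.1)
  expect_lt(gain_at(5), 0.01)
})

test_that("bandpass_notch rejects too-short recordings and wrong rates", {
  expect_error(bandpass_notch(as_recording(matrix(rnorm(10), 1))), "too short")
  expect_error(bandpass_notch(as_recording(matrix(rnorm(2000), 1), fs = 2000),
                              filter_spec(fs = 1000)), "does not match")
})

test_that("differential pair counts match the channel-combinatorics identity", {
  expect_equal(nrow(differential_pairs(matrix(0, 32, 4))), 528)  # 32 + 496
  expect_equal(nrow(differential_pairs(matrix(0, 20, 4))), 210)  # 20 + 190
  x1 <- matrix(rnorm(8), 1)
  expect_identical(differential_pairs(x1), x1)     # no pairs for n = 1
  for (n in c(2, 5, 16, 33)) {
    out <- differential_pairs(matrix(rnorm(n * 3), n))
    expect_equal(nrow(out), n + choose(n, 2))
  }
  # lexicographic order and values: row after the n single-ended is 1-2
  x <- matrix(seq_len(3 * 2), 3)
  d <- differential_pairs(x)
  expect_equal(d[4, ], x[1, ] - x[2, ])
  expect_equal(d[5, ], x[1, ] - x[3, ])
  expect_equal(d[6, ], x[2, ] - x[3, ])
})

test_that("MAV features equal the brute-force windowed mean", {
  set.seed(42)
  x <- matrix(rnorm(2 * 1000), 2)
  fe <- mav_features(as_recording(x))
  for (ch in 1:2)
    expect_equal(fe$values[ch, ], oracle_mav(x[ch, ], 1000, 30, 300),
                 tolerance = 1e-12)
  # constant signal: every frame equals |c|
  fe_c <- mav_features(as_recording(matrix(-1.7, 1, 900)))
  expect_true(all(abs(fe_c$values + (-1.7) * sign(-1.7) * -1) < 1e-12))
  expect_equal(unname(fe_c$values[1, 1]), 1.7)
  # alternating +/-a square wave: MAV = a
  sq <- matrix(rep(c(0.3, -0.3), 500), 1)
  expect_true(all(abs(mav_features(as_recording(sq))$values - 0.3) < 1e-12))
  expect_error(mav_features(as_recording(matrix(0, 1, 0))), "empty")
})

test_that("MAV is invariant to sign flip of the raw EMG", {
  set.seed(7)
  x <- matrix(rnorm(1500), 1)
  expect_equal(mav_features(as_recording(x))$values,
               mav_features(as_recording(-x))$values)
})

test_that("align_lag recovers an injected reaction lag and is idempotent", {
  p <- tiny_protocol(2, 3)
  kin <- make_kinematic_trace(p)
  # 200 ms lag -> 6 frames at 30 Hz
  subj <- tiny_subject(seed = 5)
  fe <- synthesize_features(kin, subj, seed = 2)
  al <- align_lag(fe, kin)
  expect_true(abs(al$lag_frames - 6) <= 1)
  # exhaustive-correlation oracle agrees
  x <- colMeans(fe$values - rowMeans(fe$values))
  y <- colMeans(abs(kin$values))
  n <- length(x)
  cc <- sapply(0:30, function(l) cor(x[(1 + l):n], y[1:(n - l)]))
  expect_equal(al$lag_frames, which.max(cc) - 1L)
  # annotations shift with the kinematics
  expect_equal(al$kin$annotations$frame_start,
               kin$annotations$frame_start + al$lag_frames)
  # second pass recovers ~0
  al2 <- align_lag(fe, al$kin)
  expect_lte(abs(al2$lag_frames), 1)
  # zero injected lag
  subj0 <- tiny_subject(seed = 5, reaction_lag_s = 0)
  fe0 <- synthesize_features(kin, subj0, seed = 2)
  expect_lte(abs(align_lag(fe0, kin)$lag_frames), 1)
})

test_that("align_lag caps the shift, preserves values, and warns on zero kinematics", {
  p <- tiny_protocol(1, 2)
  kin <- make_kinematic_trace(p)
  fe <- synthesize_features(kin, tiny_subject(seed = 1), seed = 1)
  al <- align_lag(fe, kin, max_lag_s = 0.1)
  expect_lte(al$lag_frames, 3)
  l <- al$lag_frames
  if (l > 0) {
    n <- ncol(kin$values)
    expect_equal(al$kin$values[, (l + 1):n], kin$values[, 1:(n - l)])
    expect_true(all(al$kin$values[, 1:l] == 0))
  }
  kin0 <- kin
  kin0$values[] <- 0
  expect_warning(al0 <- align_lag(fe, kin0), "all-zero")
  expect_equal(al0$lag_frames, 0L)
})

test_that("baseline subtraction removes rest means exactly", {
  ses <- tiny_session(seed = 6)
  rest <- rest_frames(ses$annotations, ncol(ses$features$values))
  bs <- baseline_subtract(ses$features, rest)
  # oracle: naive per-channel mean over rest frames
  naive <- apply(ses$features$values[, rest, drop = FALSE], 1, mean)
  expect_equal(bs$baseline, naive, tolerance = 1e-12)
  # residual rest mean is ~0 (idempotence on the rest mean)
  expect_lt(max(abs(rowMeans(bs$features$values[, rest]))), 1e-12)
  # constant channels become all-zero
  fe_c <- feature_matrix(matrix(c(1, 2), 2, 10))
  expect_true(all(baseline_subtract(fe_c, 1:10)$features$values == 0))
  expect_error(baseline_subtract(fe_c, integer(0)), "empty")
})

test_that("feature count identity holds across the full chain", {
  for (n in c(1, 2, 5, 11)) {
    subj <- subject_model(n_contacts = max(n, 2), seed = 1)
    subj$n_contacts <- n
    subj$mixing <- matrix(0.5, n, 24)
    subj$rest_baseline <- rep(0.1, n)
    subj$noise_sd <- rep(0.05, n)
    kin <- make_kinematic_trace(tiny_protocol(1, 1))
    fe <- synthesize_features(kin, subj, seed = 1)
    expect_equal(nrow(fe$values), n + n * (n - 1) / 2)
  }
})
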