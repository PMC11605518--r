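#' Movement protocol for a calibration session
#'
#' Describes the prompted-movement structure of one training/testing session:
#' a set of single- or multi-DOF movements, each repeated a fixed number of
#' times as a trapezoidal excursion (linear rise to the target amplitude, a
#' hold, and a linear return to rest), separated by rest periods.
#'
#' @param movements List of movements; each element is a list with fields
#'   `id` (character), `dofs` (integer vector of active DOF indices, 1..12),
#'   `direction` (`+1` flexion, `-1` extension) and `amplitude` (target in
#'   (0, 1]).
#' @param trials_per_movement Number of consecutive repetitions per movement.
#' @param rise_s,hold_s,return_s Trapezoid segment durations in seconds.
#'   Defaults 3/1/3 give the standard 7 s mimicry movement.
#' @param inter_trial_s Rest duration between trials (and before the first),
#'   seconds.
#' @return An object of class `movement_protocol`.
#' @seealso [make_kinematic_trace()], [default_protocol()], [ttt_protocol()]
#' @export
movement_protocol <- function(movements, trials_per_movement = 6,
                              rise_s = 3, hold_s = 1, return_s = 3,
                              inter_trial_s = 2) {
  if (length(movements) == 0) stopf("protocol needs at least one movement")
  if (rise_s + hold_s + return_s <= 0) stopf("trial duration must be positive")
  if (any(c(rise_s, hold_s, return_s, inter_trial_s) < 0))
    stopf("segment durations must be nonnegative")
  if (!is_count(trials_per_movement) || trials_per_movement < 1)
    stopf("trials_per_movement must be a positive integer")
  movements <- lapply(seq_along(movements), function(i) {
    m <- movements[[i]]
    if (is.null(m$id)) m$id <- paste0("m", i)
    if (is.null(m$amplitude)) m$amplitude <- 1
    if (is.null(m$direction)) m$direction <- 1
    if (!all(m$dofs %in% 1:N_DOF))
      stopf("movement '%s': DOF indices must be in 1..%d", m$id, N_DOF)
    if (m$amplitude <= 0 || m$amplitude > 1)
      stopf("movement '%s': amplitude must be in (0, 1]", m$id)
    if (!m$direction %in% c(-1, 1))
      stopf("movement '%s': direction must be +1 or -1", m$id)
    m
  })
  structure(list(movements = movements,
                 trials_per_movement = as.integer(trials_per_movement),
                 rise_s = rise_s, hold_s = hold_s, return_s = return_s,
                 inter_trial_s = inter_trial_s),
            class = "movement_protocol")
}

#' @export
print.movement_protocol <- function(x, ...) {
  cat(sprintf(
    "Movement protocol: %d movements x %d trials, %.3g-%.3g-%.3g s trapezoid, %.3g s rest\n",
    length(x$movements), x$trials_per_movement,
    x$rise_s, x$hold_s, x$return_s, x$inter_trial_s))
  invisible(x)
}

#' Standard single-DOF mimicry protocol
#'
#' Flexion and extension movements for the first `n_dofs` degrees of freedom
#' (so `2 * n_dofs` movements), full amplitude, with the standard 3-1-3 s
#' trapezoid.
#'
#' @param n_dofs Number of DOFs actuated (movements = 2 per DOF).
#' @param trials_per_movement Repetitions per movement.
#' @param amplitude Target amplitude in (0, 1].
#' @inheritParams movement_protocol
#' @return A `movement_protocol`.
#' @export
default_protocol <- function(n_dofs = 4, trials_per_movement = 6,
                             amplitude = 1, inter_trial_s = 2) {
  movs <- list()
  for (d in seq_len(n_dofs)) {
    movs[[length(movs) + 1L]] <-
      list(id = sprintf("d%02d_flex", d), dofs = d, direction = 1,
           amplitude = amplitude)
    movs[[length(movs) + 1L]] <-
      list(id = sprintf("d%02d_ext", d), dofs = d, direction = -1,
           amplitude = amplitude)
  }
  movement_protocol(movs, trials_per_movement = trials_per_movement,
                    inter_trial_s = inter_trial_s)
}

#' Target-touching protocol
#'
#' The target-holding task layout: both directions of `n_dofs` DOFs (12
#' movements for 6 DOFs), with trials at 50% and 100% of full range. Each
#' trial ramps to the target and holds it for the rest of the 5 s trial;
#' there is no return segment (the trial ends at the target), and trials are
#' separated by 2 s of rest.
#'
#' @param n_dofs Number of DOFs (movements = 2 per DOF).
#' @param trials_per_amplitude Trials at each of the two amplitudes.
#' @param trial_s Trial duration, seconds.
#' @param rise_s Ramp-to-target duration within the trial, seconds.
#' @return A `movement_protocol` whose movements enumerate DOF x direction x
#'   amplitude; `trials_per_movement` is `trials_per_amplitude`.
#' @export
ttt_protocol <- function(n_dofs = 6, trials_per_amplitude = 5,
                         trial_s = 5, rise_s = 0.7) {
  movs <- list()
  for (d in seq_len(n_dofs)) {
    for (dir in c(1, -1)) {
      for (amp in c(0.5, 1)) {
        movs[[length(movs) + 1L]] <- list(
          id = sprintf("d%02d_%s_%d", d, if (dir > 0) "flex" else "ext",
                       round(100 * amp)),
          dofs = d, direction = dir, amplitude = amp)
      }
    }
  }
  movement_protocol(movs, trials_per_movement = trials_per_amplitude,
                    rise_s = rise_s, hold_s = trial_s - rise_s, return_s = 0,
                    inter_trial_s = 2)
}

#' Kinematic trace container
#' @noRd
kin_trace <- function(values, frame_rate, annotations) {
  stopifnot(is.matrix(values), nrow(values) == N_DOF)
  if (any(values < -1 | values > 1)) stopf("kinematics must lie in [-1, 1]")
  structure(list(values = values, frame_rate = frame_rate,
                 annotations = annotations),
            class = "kin_trace")
}

#' @export
print.kin_trace <- function(x, ...) {
  cat(sprintf("Kinematic trace: %d DOFs x %d frames at %g Hz, %d trials\n",
              nrow(x$values), ncol(x$values), x$frame_rate,
              nrow(x$annotations)))
  invisible(x)
}

#' Generate the prompted kinematics for a protocol
#'
#' Builds the 12-DOF target trace a session prompts the user to mimic: for
#' each trial, the active DOF(s) ramp linearly from rest to
#' `direction * amplitude` over the rise, hold, and ramp back over the
#' return; all other DOFs are exactly zero, and trials are separated by
#' rest. Trials of a movement are consecutive.
#'
#' @param protocol A [movement_protocol()].
#' @param frame_rate Output frame rate, Hz.
#' @return A `kin_trace`: list with `values` (12 x frames matrix in
#'   \eqn{[-1, 1]}), `frame_rate`, and `annotations`, a data frame with one
#'   row per trial (`movement_id`, `dofs` list-column, `direction`,
#'   `amplitude`, `frame_start`, `frame_end`; spans are 1-based inclusive).
#' @examples
#' tr <- make_kinematic_trace(default_protocol(n_dofs = 1,
#'                                             trials_per_movement = 1))
#' diff(unlist(tr$annotations[1, c("frame_start", "frame_end")])) + 1  # 210
#' @export
make_kinematic_trace <- function(protocol, frame_rate = 30) {
  stopifnot(inherits(protocol, "movement_protocol"))
  if (frame_rate <= 0) stopf("frame_rate must be positive")
  n_rise <- frames_of(protocol$rise_s, frame_rate)
  n_hold <- frames_of(protocol$hold_s, frame_rate)
  n_ret  <- frames_of(protocol$return_s, frame_rate)
  n_rest <- frames_of(protocol$inter_trial_s, frame_rate)
  n_trial <- n_rise + n_hold + n_ret
  if (n_trial < 1) stopf("trial shorter than one frame at %g Hz", frame_rate)
  profile <- c(if (n_rise > 0) seq_len(n_rise) / n_rise,
               rep(1, n_hold),
               if (n_ret > 0) 1 - seq_len(n_ret) / n_ret)

  n_trials <- length(protocol$movements) * protocol$trials_per_movement
  total <- n_rest + n_trials * (n_trial + n_rest)
  values <- matrix(0, N_DOF, total)
  ann <- vector("list", n_trials)
  pos <- n_rest  # leading rest
  k <- 0L
  for (m in protocol$movements) {
    for (tr in seq_len(protocol$trials_per_movement)) {
      k <- k + 1L
      span <- (pos + 1L):(pos + n_trial)
      for (d in m$dofs)
        values[d, span] <- m$direction * m$amplitude * profile
      ann[[k]] <- data.frame(movement_id = m$id, direction = m$direction,
                             amplitude = m$amplitude,
                             frame_start = span[1], frame_end = span[n_trial])
      ann[[k]]$dofs <- list(as.integer(m$dofs))
      pos <- pos + n_trial + n_rest
    }
  }
  annotations <- do.call(rbind, ann)
  kin_trace(values, frame_rate, annotations)
}

#' Frames outside every annotated trial span
#'
#' @param annotations Annotation data frame (as in `kin_trace`).
#' @param n_frames Total frame count of the trace.
#' @return Integer vector of rest-frame indices.
#' @export
rest_frames <- function(annotations, n_frames) {
  active <- rep(FALSE, n_frames)
  for (i in seq_len(nrow(annotations)))
    active[annotations$frame_start[i]:annotations$frame_end[i]] <- TRUE
  which(!active)
}

#' Synthetic subject: contact-to-muscle structure of an implanted recording
#'
#' Encodes how each DOF's flexion and extension drive the EMG amplitude seen
#' at each contact: a nonnegative `n_contacts x 24` mixing matrix (columns
#' are 12 DOFs x {flexion, extension} rectified drives), per-contact rest
#' baselines, measurement-noise levels, and the user's visuomotor reaction
#' lag. When `mixing` is not supplied it is generated at random: each
#' DOF-direction drives 2-4 contacts with weights in a physiological-looking
#' range, so every drive column has at least one contact.
#'
#' @param n_contacts Number of recording contacts (32 or 20 in typical
#'   implants; smaller values keep simulations light).
#' @param seed Integer seed for the generated structure.
#' @param mixing Optional nonnegative `n_contacts x 24` matrix.
#' @param rest_baseline Optional nonnegative baseline vector, amplitude units.
#' @param noise_sd Optional per-contact additive noise SD.
#' @param reaction_lag_s Reaction lag, seconds (>= 0).
#' @return An object of class `subject_model`.
#' @export
subject_model <- function(n_contacts = 32, seed = 1, mixing = NULL,
                          rest_baseline = NULL, noise_sd = NULL,
                          reaction_lag_s = 0.2) {
  if (reaction_lag_s < 0) stopf("reaction_lag_s must be nonnegative")
  n_drive <- 2L * N_DOF
  if (is.null(mixing) || is.null(rest_baseline) || is.null(noise_sd)) {
    gen <- with_seed(mix_seed(seed, 11), {
      M <- matrix(0, n_contacts, n_drive)
      for (j in seq_len(n_drive)) {
        k <- sample(2:min(4, n_contacts), 1)
        rows <- sample.int(n_contacts, k)
        M[rows, j] <- runif(k, 0.4, 1.2)
      }
      list(M = M,
           base = runif(n_contacts, 0.03, 0.10),
           nsd = runif(n_contacts, 0.03, 0.08))
    })
    if (is.null(mixing)) mixing <- gen$M
    if (is.null(rest_baseline)) rest_baseline <- gen$base
    if (is.null(noise_sd)) noise_sd <- gen$nsd
  }
  mixing <- as.matrix(mixing)
  if (!all(dim(mixing) == c(n_contacts, n_drive)))
    stopf("mixing must be %d x %d", n_contacts, n_drive)
  if (any(mixing < 0)) stopf("mixing entries must be nonnegative")
  if (any(colSums(mixing) <= 0))
    stopf("every DOF-direction must drive at least one contact")
  if (any(rest_baseline < 0) || any(noise_sd < 0))
    stopf("baseline and noise_sd must be nonnegative")
  structure(list(n_contacts = as.integer(n_contacts), mixing = mixing,
                 rest_baseline = as.numeric(rest_baseline),
                 noise_sd = as.numeric(noise_sd),
                 reaction_lag_s = reaction_lag_s),
            class = "subject_model")
}

#' @export
print.subject_model <- function(x, ...) {
  cat(sprintf(
    "Synthetic subject: %d contacts, reaction lag %.0f ms, mean baseline %.3f\n",
    x$n_contacts, 1000 * x$reaction_lag_s, mean(x$rest_baseline)))
  invisible(x)
}

#' Day-to-day drift process
#'
#' A seeded random walk applied to a subject's recording structure, one step
#' per calendar day: small Givens rotations of the mixing matrix in random
#' two-contact subspaces (electrode/tissue geometry change), a multiplicative
#' per-contact log-gain walk, and an additive rest-baseline walk. On top of
#' the accumulating walk, each recorded session carries a non-accumulating
#' day-specific log-gain fluctuation (`session_gain_sd`) modelling
#' day-of-recording state (impedance, user effort) that does not persist;
#' it is applied by [generate_study()], not by [apply_day_drift()]. All
#' rates zero reproduces statistically identical sessions on every day.
#'
#' @param rotation_rate SD of the per-day rotation angle, radians/day.
#' @param gain_sd_per_day SD of the per-day log-gain step.
#' @param baseline_sd_per_day SD of the per-day additive baseline step,
#'   amplitude units.
#' @param session_gain_sd SD of the per-session (non-accumulating) log-gain
#'   fluctuation.
#' @param seed Integer seed; the walk is deterministic given (seed, day).
#' @return An object of class `drift_model`.
#' @export
drift_model <- function(rotation_rate = 0.06, gain_sd_per_day = 0.10,
                        baseline_sd_per_day = 0.004, session_gain_sd = 0.25,
                        seed = 1) {
  if (any(c(rotation_rate, gain_sd_per_day, baseline_sd_per_day,
            session_gain_sd) < 0))
    stopf("drift rates must be nonnegative")
  structure(list(rotation_rate = rotation_rate,
                 gain_sd_per_day = gain_sd_per_day,
                 baseline_sd_per_day = baseline_sd_per_day,
                 session_gain_sd = session_gain_sd,
                 seed = as.integer(seed)),
            class = "drift_model")
}

# Day-specific non-accumulating fluctuation around the drifted state.
apply_session_state <- function(subject, drift, day_index) {
  if (is.null(drift$session_gain_sd) || drift$session_gain_sd == 0)
    return(subject)
  g <- with_seed(mix_seed(drift$seed, 211, day_index),
                 exp(rnorm(subject$n_contacts, 0, drift$session_gain_sd)))
  subject$mixing <- subject$mixing * g
  subject$rest_baseline <- subject$rest_baseline * g
  subject
}

#' @export
print.drift_model <- function(x, ...) {
  cat(sprintf(
    "Drift model: rotation %.3g rad/day, log-gain SD %.3g/day, baseline SD %.3g/day, session SD %.3g (seed %d)\n",
    x$rotation_rate, x$gain_sd_per_day, x$baseline_sd_per_day,
    x$session_gain_sd, x$seed))
  invisible(x)
}

#' Advance a subject's recording structure by accumulated drift
#'
#' Applies `day_index` daily random-walk steps to the subject. Day 0 returns
#' the subject unchanged; results are deterministic given `(drift$seed,
#' day_index)`, and day `d` shares its first `d` steps with any later day,
#' so the process is a genuine random walk across the study.
#'
#' @param subject A [subject_model()].
#' @param drift A [drift_model()].
#' @param day_index Nonnegative integer day.
#' @return A drifted `subject_model`.
#' @export
apply_day_drift <- function(subject, drift, day_index) {
  stopifnot(inherits(subject, "subject_model"), inherits(drift, "drift_model"))
  if (!is_count(day_index)) stopf("day_index must be a nonnegative integer")
  if (day_index == 0) return(subject)
  M <- subject$mixing
  base <- subject$rest_baseline
  n <- subject$n_contacts
  for (d in seq_len(day_index)) {
    step <- with_seed(mix_seed(drift$seed, 101, d), {
      list(pairs = replicate(2, sample.int(n, 2), simplify = FALSE),
           angles = rnorm(2, 0, drift$rotation_rate),
           gains = rnorm(n, 0, drift$gain_sd_per_day),
           dbase = rnorm(n, 0, drift$baseline_sd_per_day))
    })
    for (r in 1:2) {
      i <- step$pairs[[r]][1]; j <- step$pairs[[r]][2]
      co <- cos(step$angles[r]); si <- sin(step$angles[r])
      ri <- M[i, ]; rj <- M[j, ]
      M[i, ] <- co * ri + si * rj
      M[j, ] <- -si * ri + co * rj
    }
    g <- exp(step$gains)
    M <- pmax(M * g, 0)          # rotations can graze below zero; re-clip
    base <- pmax(base * g + step$dbase, 0)
  }
  subject$mixing <- M
  subject$rest_baseline <- base
  subject
}

# Rectified flexion/extension drive (24 x frames) from kinematics (12 x frames).
drive_matrix <- function(kin_values) {
  rbind(pmax(kin_values, 0), pmax(-kin_values, 0))
}

# Contact envelopes at the kinematic frame rate, with the subject's reaction
# lag applied (kinematics delayed; pre-start frames are rest).
contact_envelope <- function(kin, subject) {
  lag_fr <- frames_of(subject$reaction_lag_s, kin$frame_rate)
  v <- kin$values
  if (lag_fr > 0) {
    f <- ncol(v)
    v <- cbind(matrix(0, N_DOF, min(lag_fr, f)),
               v[, seq_len(max(f - lag_fr, 0)), drop = FALSE])
  }
  subject$rest_baseline + subject$mixing %*% drive_matrix(v)
}

#' Synthesize raw multi-channel EMG for a kinematic trace
#'
#' Amplitude-modulation model: each contact's signal is its nonnegative
#' envelope (rest baseline plus mixing-weighted rectified flexion/extension
#' drives of the kinematics, delayed by the subject's reaction lag) times a
#' unit-variance band-limited (15-375 Hz) Gaussian carrier, plus white
#' measurement noise. Carriers and noise are independent across contacts.
#'
#' @param kin A `kin_trace` (30 Hz).
#' @param subject A [subject_model()].
#' @param seed Integer seed.
#' @param fs Output sampling rate, Hz.
#' @return An `emg_recording`: list with `values` (contacts x samples) and
#'   `fs`.
#' @export
synthesize_emg <- function(kin, subject, seed = 1, fs = 1000) {
  stopifnot(inherits(kin, "kin_trace"), inherits(subject, "subject_model"))
  n_frames <- ncol(kin$values)
  n_samp <- as.integer(round(n_frames * fs / kin$frame_rate))
  # upsample kinematics to fs by linear interpolation, then delay by the lag
  t_frame <- seq_len(n_frames) / kin$frame_rate
  t_samp <- seq_len(n_samp) / fs - subject$reaction_lag_s
  kin_up <- matrix(0, N_DOF, n_samp)
  for (d in seq_len(N_DOF)) {
    kin_up[d, ] <- approx(t_frame, kin$values[d, ], xout = t_samp,
                          yleft = 0, rule = 2)$y
  }
  env <- subject$rest_baseline + subject$mixing %*% drive_matrix(kin_up)
  stopifnot(all(env >= 0))  # internal: model invariants guarantee this
  bp <- signal::butter(4, c(15, 375) / (fs / 2), type = "pass")
  values <- with_seed(mix_seed(seed, 23), {
    out <- matrix(0, subject$n_contacts, n_samp)
    for (c_i in seq_len(subject$n_contacts)) {
      carrier <- signal::filter(bp, rnorm(n_samp))
      carrier <- carrier / stats::sd(carrier)
      out[c_i, ] <- env[c_i, ] * carrier +
        rnorm(n_samp, 0, subject$noise_sd[c_i])
    }
    out
  })
  structure(list(values = values, fs = fs), class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("EMG recording: %d contacts x %d samples at %g Hz\n",
              nrow(x$values), ncol(x$values), x$fs))
  invisible(x)
}

#' Feature-level shortcut generator
#'
#' Produces the mean-absolute-value feature matrix a session would yield
#' after the full filtering/differencing/windowing chain, directly at the
#' frame rate, using the closed form for the expected rectified amplitude of
#' Gaussian carriers: a single-ended channel with envelope \eqn{e} and noise
#' SD \eqn{s} has expected MAV \eqn{\sqrt{e^2 + s^2}\sqrt{2/\pi}}, and a
#' differential pair adds the two channels' envelope powers (independent
#' carriers). Windowing scatter is emulated with multiplicative Gaussian
#' noise. Orders of magnitude faster than the raw-EMG path and statistically
#' matched at the envelope level; frame-to-frame correlation of the real
#' sliding window is not reproduced.
#'
#' @inheritParams synthesize_emg
#' @param mav_noise_frac Relative SD of the per-frame multiplicative scatter.
#' @return A `feature_matrix` (see [mav_features()]).
#' @export
synthesize_features <- function(kin, subject, seed = 1,
                                mav_noise_frac = 0.06) {
  stopifnot(inherits(kin, "kin_trace"), inherits(subject, "subject_model"))
  env <- contact_envelope(kin, subject)       # contacts x frames
  n <- subject$n_contacts
  pw <- env^2 + subject$noise_sd^2            # per-contact signal power
  pairs <- if (n >= 2) utils::combn(n, 2) else matrix(0, 2, 0)
  mu <- rbind(sqrt(pw),
              if (ncol(pairs) > 0)
                sqrt(pw[pairs[1, ], , drop = FALSE] +
                     pw[pairs[2, ], , drop = FALSE]))
  mu <- mu * sqrt(2 / pi)
  vals <- with_seed(mix_seed(seed, 31), {
    pmax(mu * (1 + matrix(rnorm(length(mu), 0, mav_noise_frac),
                          nrow(mu), ncol(mu))), 0)
  })
  feature_matrix(vals, kin$frame_rate, channel_labels(n))
}

#' Generate a multi-session synthetic study
#'
#' One session per requested day: the subject is advanced to that day's
#' drifted state and a session (prompted kinematics plus EMG or features) is
#' synthesized with a day-specific sub-seed. The same protocol is prompted
#' on every day, mirroring repeated calibration sessions.
#'
#' @param subject A [subject_model()] (day-0 state).
#' @param protocol A [movement_protocol()].
#' @param drift A [drift_model()].
#' @param day_indices Nondecreasing integer vector of session days.
#' @param level `"emg"` to synthesize raw 1 kHz EMG (full preprocessing chain
#'   then applies), `"features"` for the fast feature-level shortcut.
#' @param seed Base seed for session noise (defaults to the drift seed).
#' @param frame_rate Kinematic frame rate, Hz.
#' @return List of `emg_session` objects: each has `day_index`, `kin`,
#'   `annotations`, and either `emg` or `features`.
#' @export
generate_study <- function(subject, protocol, drift, day_indices,
                           level = c("emg", "features"), seed = drift$seed,
                           frame_rate = 30) {
  level <- match.arg(level)
  if (length(day_indices) == 0) return(list())
  if (is.unsorted(day_indices)) stopf("day_indices must be nondecreasing")
  kin <- make_kinematic_trace(protocol, frame_rate)
  lapply(seq_along(day_indices), function(i) {
    day <- day_indices[i]
    subj_d <- apply_session_state(apply_day_drift(subject, drift, day),
                                  drift, day)
    s_seed <- mix_seed(seed, 57, day, i)
    ses <- list(day_index = as.integer(day), kin = kin,
                annotations = kin$annotations,
                n_contacts = subject$n_contacts,
                reaction_lag_s = subject$reaction_lag_s)
    if (level == "emg") {
      ses$emg <- synthesize_emg(kin, subj_d, seed = s_seed)
    } else {
      ses$features <- synthesize_features(kin, subj_d, seed = s_seed)
    }
    structure(ses, class = "emg_session")
  })
}

#' @export
print.emg_session <- function(x, ...) {
  cat(sprintf("Session (day %d): %s, %d trials\n", x$day_index,
              if (!is.null(x$emg)) sprintf("raw EMG %d x %d @ %g Hz",
                                           nrow(x$emg$values),
                                           ncol(x$emg$values), x$emg$fs)
              else sprintf("features %d x %d @ %g Hz",
                           nrow(x$features$values), ncol(x$features$values),
                           x$features$frame_rate),
              nrow(x$annotations)))
  invisible(x)
}

#' Write / read a session directory
#'
#' On-disk layout: `emg.csv` (samples x contacts, header row of contact ids)
#' or `features.csv` (frames x features, header of channel labels),
#' `kinematics.csv` (frames x 12 DOFs), `annotations.json` (trial records)
#' and `meta.json` (day index, rates).
#'
#' @param session An `emg_session`.
#' @param dir Directory to create/fill.
#' @return `write_session` returns `dir` invisibly; `read_session` returns an
#'   `emg_session`.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "emg_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kin <- t(session$kin$values)
  colnames(kin) <- sprintf("dof%02d", seq_len(N_DOF))
  utils::write.csv(kin, file.path(dir, "kinematics.csv"), row.names = FALSE)
  if (!is.null(session$emg)) {
    emg <- t(session$emg$values)
    colnames(emg) <- sprintf("c%02d", seq_len(ncol(emg)))
    utils::write.csv(emg, file.path(dir, "emg.csv"), row.names = FALSE)
  }
  if (!is.null(session$features)) {
    fe <- t(session$features$values)
    colnames(fe) <- session$features$channel_labels
    utils::write.csv(fe, file.path(dir, "features.csv"), row.names = FALSE)
  }
  ann <- session$annotations
  ann$dofs <- lapply(ann$dofs, as.integer)
  jsonlite::write_json(ann, file.path(dir, "annotations.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  meta <- list(day_index = session$day_index,
               n_contacts = session$n_contacts,
               reaction_lag_s = session$reaction_lag_s,
               frame_rate = session$kin$frame_rate,
               fs = if (!is.null(session$emg)) session$emg$fs)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  kin_v <- t(as.matrix(utils::read.csv(file.path(dir, "kinematics.csv"))))
  dimnames(kin_v) <- NULL
  ann <- jsonlite::read_json(file.path(dir, "annotations.json"),
                             simplifyVector = TRUE)
  ann$dofs <- lapply(ann$dofs, as.integer)
  kin <- kin_trace(kin_v, meta$frame_rate, ann)
  ses <- list(day_index = as.integer(meta$day_index), kin = kin,
              annotations = ann, n_contacts = meta$n_contacts,
              reaction_lag_s = meta$reaction_lag_s)
  if (file.exists(file.path(dir, "emg.csv"))) {
    emg_v <- t(as.matrix(utils::read.csv(file.path(dir, "emg.csv"))))
    dimnames(emg_v) <- NULL
    ses$emg <- structure(list(values = emg_v, fs = meta$fs),
                         class = "emg_recording")
  }
  if (file.exists(file.path(dir, "features.csv"))) {
    fe <- utils::read.csv(file.path(dir, "features.csv"), check.names = FALSE)
    labs <- colnames(fe)
    fe <- t(as.matrix(fe))
    dimnames(fe) <- NULL
    ses$features <- feature_matrix(fe, meta$frame_rate, labs)
  }
  structure(ses, class = "emg_session")
}
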