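# Small fixture builders shared across test files.

tiny_protocol <- function(n_dofs = 2, trials = 2, ...) {
  default_protocol(n_dofs = n_dofs, trials_per_movement = trials, ...)
}

tiny_subject <- function(n_contacts = 6, seed = 3, ...) {
  subject_model(n_contacts = n_contacts, seed = seed, ...)
}

# One feature-level session, fast.
tiny_session <- function(seed = 1, n_dofs = 2, trials = 2, n_contacts = 6,
                         drift = drift_model(0, 0, 0, 0, seed = seed),
                         day = 0) {
  generate_study(tiny_subject(n_contacts, seed = seed),
                 tiny_protocol(n_dofs, trials), drift, day,
                 level = "features", seed = seed)[[1]]
}

# Wrap a plain matrix as an emg_recording.
as_recording <- function(values, fs = 1000) {
  structure(list(values = values, fs = fs), class = "emg_recording")
}

# A decoder stub that returns the (lag-aligned) target kinematics.
oracle_decoder <- function(kin_provider) {
  list(model = NULL,
       predict = function(model, fe) {
         kin <- kin_provider(fe)
         structure(list(values = kin, raw = kin), class = "decoded_trace")
       })
}
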