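# Small seeded sessions shared across test files.

quiet_noise <- function() {
  noise_settings(cardiac_amp = 0.01, respiration_amp = 0.01,
                 drift_amp = 0.01, white_sd = 0.002, global_amp = 0.02,
                 trial_gain_sd = 0.02)
}

silent_noise <- function() {
  noise_settings(cardiac_amp = 0, respiration_amp = 0, drift_amp = 0,
                 white_sd = 0, global_amp = 0, trial_gain_sd = 0)
}

tiny_config <- function(seed = 1, effects = effect_preset("null"),
                        noise = noise_settings(), n_reps = 3,
                        locations = c(-90L, 0L), intensities = 58L, ...) {
  simulation_config(seed = seed, n_reps = n_reps, locations = locations,
                    intensities = intensities, effects = effects,
                    noise = noise, ...)
}

# a deterministic recording built directly, no simulation
toy_recording <- function(n_channels = 20, n_samples = 800, fs = 13.3,
                          seed = 42, events = NULL) {
  set.seed(seed)
  data <- matrix(rnorm(n_channels * n_samples), n_channels, n_samples)
  channels <- nirs_probe_map()[seq_len(n_channels), , drop = FALSE]
  if (is.null(events)) {
    events <- data.frame(onset_s = c(15, (n_samples - 150) / fs),
                         location_deg = c(-90L, 0L),
                         intensity_db = 58L, duration_s = 10)
  }
  nirs_recording(data, fs_hz = fs, channels = channels, events = events,
                 subject_id = "toy")
}

# behavioral session with a prescribed number of 30-degree errors
session_with_errors <- function(n_trials, n_errors,
                                intensity_split = c(48, 58)) {
  target <- rep(c(1L, 3L, 4L, 5L, 7L), length.out = n_trials)
  response <- target
  if (n_errors > 0) {
    idx <- which(target == 4L)[seq_len(n_errors)]
    response[idx] <- 3L   # 0 deg reported as -30 deg
  }
  behavioral_session(data.frame(
    target_speaker = target, response_speaker = response,
    intensity_db = rep(intensity_split, length.out = n_trials)))
}
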