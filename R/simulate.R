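#' Default physiological noise settings for simulated sessions
#'
#' Amplitudes are peak values in mM·mm on the scale of typical
#' pathlength-scaled oxy-Hb fluctuations.  Component frequencies are drawn
#' once per session within their physiological bands (rhythms are
#' quasi-stationary within a session); phases and small amplitude jitters
#' vary per channel.  The global component is identical across channels
#' (coefficient 1) and therefore removed exactly by the common average
#' reference.
#'
#' @param cardiac_amp cardiac (1-1.5 Hz) amplitude.
#' @param respiration_amp respiration (0.2-0.5 Hz) amplitude.
#' @param drift_amp slow drift (< 0.03 Hz) amplitude.
#' @param white_sd white measurement-noise standard deviation.
#' @param global_amp shared systemic component amplitude.
#' @param trial_gain_sd standard deviation of the multiplicative
#'   trial-to-trial response gain (mean 1); models arousal/attention
#'   variability in evoked amplitude.
#' @return Named list of noise settings.
#' @export
noise_settings <- function(cardiac_amp = 0.08, respiration_amp = 0.05,
                           drift_amp = 0.10, white_sd = 0.03,
                           global_amp = 0.10, trial_gain_sd = 0.25) {
  list(cardiac_amp = cardiac_amp, respiration_amp = respiration_amp,
       drift_amp = drift_amp, white_sd = white_sd, global_amp = global_amp,
       trial_gain_sd = trial_gain_sd)
}

#' Condition-effect presets for the session generator
#'
#' An effect table assigns each (ROI, location, intensity) combination a
#' peak oxy-Hb response amplitude (mM·mm) and an onset latency (s).  A
#' missing `intensity_db` (NA) applies to both levels, mirroring the
#' default of no sound-level effect.
#'
#' Presets:
#' \describe{
#'   \item{`"null"`}{no condition effects (chance-level decoding).}
#'   \item{`"lateral"`}{the committed study-condition preset: lateral
#'     sources drive the contralateral auditory regions (supramarginal
#'     BA40, STG BA22, auditory association BA42) harder than the
#'     ipsilateral ones, with an earlier ipsilateral peak for -90 than for
#'     +90; the front source evokes moderate bilateral dlPFC/temporal
#'     activity; +/-30 deg sources are nearly indistinguishable from the
#'     front; no intensity effect.}
#'   \item{`"high_snr"`}{large lateral-vs-front amplitudes for near-perfect
#'     separability (pair with low noise).}
#'   \item{`"intensity"`}{sound-level effect confined to ROI 4 (left STG):
#'     58 dB responds, 48 dB does not.}
#' }
#'
#' @param preset one of `"null"`, `"lateral"`, `"high_snr"`, `"intensity"`.
#' @param scale multiplier applied to all amplitudes (used for
#'   amplitude-recovery checks).
#' @return Data frame with columns `roi_id`, `location_deg`,
#'   `intensity_db`, `amplitude`, `latency_s`.
#' @export
effect_preset <- function(preset = c("null", "lateral", "high_snr",
                                     "intensity"),
                          scale = 1) {
  preset <- match.arg(preset)
  eff <- switch(preset,
    null = empty_effects(),
    lateral = {
      contra <- 0.033   # peak amplitude, contralateral AC, lateral source
      ipsi <- 0.022
      front <- 0.015
      dlpfc <- 0.026
      rbind(
        # -90 deg: right (contralateral) AC strong, early response
        effects_for(c(7, 9, 10), -90, contra, 0.5),
        effects_for(c(2, 4, 5), -90, ipsi, 0.5),
        effects_for(c(3, 8), -90, dlpfc, 0.5),
        # +90 deg: mirror image, peaking ~1.2 s later than for -90
        effects_for(c(2, 4, 5), 90, contra, 1.7),
        effects_for(c(7, 9, 10), 90, ipsi, 1.7),
        effects_for(c(3, 8), 90, dlpfc, 1.7),
        # front: moderate bilateral temporal + dlPFC
        effects_for(c(2, 4, 5, 7, 9, 10), 0, front, 1.0),
        effects_for(c(3, 8), 0, dlpfc, 1.0),
        # +/-30 deg: front-like with a whisper of contralateral tilt
        effects_for(c(2, 4, 5, 7, 9, 10), -30, front, 1.0),
        effects_for(c(3, 8), -30, dlpfc, 1.0),
        effects_for(c(7, 9, 10), -30, 0.0015, 1.0),
        effects_for(c(2, 4, 5, 7, 9, 10), 30, front, 1.0),
        effects_for(c(3, 8), 30, dlpfc, 1.0),
        effects_for(c(2, 4, 5), 30, 0.0015, 1.0)
      )
    },
    high_snr = rbind(
      effects_for(c(7, 9, 10), -90, 1.0, 0),
      effects_for(c(2, 4, 5), 90, 1.0, 0),
      effects_for(c(3, 8), 0, 1.0, 0)
    ),
    intensity = data.frame(roi_id = 4L, location_deg = NA_integer_,
                           intensity_db = 58L, amplitude = 0.05,
                           latency_s = 0)
  )
  eff$amplitude <- eff$amplitude * scale
  eff
}

empty_effects <- function() {
  data.frame(roi_id = integer(0), location_deg = integer(0),
             intensity_db = integer(0), amplitude = numeric(0),
             latency_s = numeric(0))
}

effects_for <- function(rois, location, amplitude, latency) {
  data.frame(roi_id = as.integer(rois), location_deg = as.integer(location),
             intensity_db = NA_integer_, amplitude = amplitude,
             latency_s = latency)
}

#' Behavioral confusion model
#'
#' Row-stochastic response probabilities over the seven speakers for each
#' of the five active targets.  The `"lateral_confusion"` preset reproduces
#' the characteristic error pattern of normal-hearing listeners: the only
#' confusions are -90 deg reported as -60 deg and +90 deg as +60 deg.
#'
#' @param preset `"perfect"` or `"lateral_confusion"`.
#' @param p_confusion probability of the lateral confusion (default 0.2).
#' @return 5 x 7 probability matrix (rows: targets 1,3,4,5,7).
#' @export
behavior_model <- function(preset = c("perfect", "lateral_confusion"),
                           p_confusion = 0.2) {
  preset <- match.arg(preset)
  active <- c(1L, 3L, 4L, 5L, 7L)
  m <- matrix(0, 5, 7, dimnames = list(target = as.character(active),
                                       response = as.character(1:7)))
  m[cbind(1:5, active)] <- 1
  if (preset == "lateral_confusion") {
    stopifnot(p_confusion >= 0, p_confusion <= 1)
    m["1", "1"] <- 1 - p_confusion
    m["1", "2"] <- p_confusion
    m["7", "7"] <- 1 - p_confusion
    m["7", "6"] <- p_confusion
  }
  m
}

#' Configuration for a simulated fNIRS localization session
#'
#' Defines the block design (10 s preparation, then stimulus/rest blocks
#' of 10 s each), the condition schedule (`locations` x `intensities` x
#' `n_reps` in seeded random order), the HRF shape, the per-ROI condition
#' effects and the noise model.
#'
#' @param seed integer RNG seed; a session is bit-reproducible from its
#'   config.
#' @param n_reps repetitions per (location, intensity) cell (default 10;
#'   with the default 5 locations x 2 intensities this gives the standard
#'   100-trial session).
#' @param locations subset of c(-90, -30, 0, 30, 90).
#' @param intensities subset of c(48, 58).
#' @param fs_hz sampling rate (default 13.3 Hz).
#' @param stim_s,rest_s,prep_s block timing in seconds.
#' @param hrf an [hrf_kernel()].
#' @param effects effect table ([effect_preset()]).
#' @param noise noise settings ([noise_settings()]).
#' @param behavior confusion matrix ([behavior_model()]).
#' @param subject_id character label.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_reps = 10L,
                              locations = c(-90L, -30L, 0L, 30L, 90L),
                              intensities = c(48L, 58L),
                              fs_hz = 13.3, stim_s = 10, rest_s = 10,
                              prep_s = 10,
                              hrf = hrf_kernel(),
                              effects = effect_preset("null"),
                              noise = noise_settings(),
                              behavior = behavior_model("perfect"),
                              subject_id = "sim") {
  stopifnot(n_reps >= 1, fs_hz > 0, stim_s > 0, rest_s >= 0, prep_s >= 0,
            all(locations %in% c(-90L, -30L, 0L, 30L, 90L)),
            all(intensities %in% c(48L, 58L)))
  if (any(effects$amplitude < 0)) stop("effect amplitudes must be >= 0")
  if (any(behavior < 0) || any(abs(rowSums(behavior) - 1) > 1e-12)) {
    stop("behavior confusion probabilities must be >= 0 and rows must sum to 1")
  }
  structure(list(seed = as.integer(seed), n_reps = as.integer(n_reps),
                 locations = as.integer(locations),
                 intensities = as.integer(intensities),
                 fs_hz = fs_hz, stim_s = stim_s, rest_s = rest_s,
                 prep_s = prep_s, hrf = hrf, effects = effects,
                 noise = noise, behavior = behavior,
                 subject_id = subject_id),
            class = "simulation_config")
}

location_to_speaker <- function(location_deg) {
  map <- c(`-90` = 1L, `-30` = 3L, `0` = 4L, `30` = 5L, `90` = 7L)
  map[as.character(location_deg)]
}

#' Simulate a complete fNIRS + behavioral session
#'
#' Builds the seeded random condition schedule, synthesizes each channel's
#' oxy-Hb series as the sum of condition-dependent HRF-shaped block
#' responses (per the channel's ROI, with multiplicative trial-to-trial
#' gain) plus cardiac, respiratory, drift, white and shared global noise,
#' and draws behavioral responses from the confusion model.
#'
#' @param cfg a [simulation_config()].
#' @return List with elements `recording` ([nirs_recording()], chromophore
#'   `"oxy"`), `behavior` ([behavioral_session()]) and `truth` (the trial
#'   schedule: trial, onset_s, location_deg, intensity_db).
#' @examples
#' sess <- simulate_session(simulation_config(seed = 1, n_reps = 2,
#'   locations = c(-90, 0), intensities = 58))
#' sess$recording
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  fs <- cfg$fs_hz
  cells <- expand.grid(location_deg = cfg$locations,
                       intensity_db = cfg$intensities,
                       rep = seq_len(cfg$n_reps))
  n_trials <- nrow(cells)
  ord <- sample.int(n_trials)
  sched <- cells[ord, c("location_deg", "intensity_db"), drop = FALSE]
  sched$trial <- seq_len(n_trials)
  sched$onset_s <- cfg$prep_s +
    (sched$trial - 1) * (cfg$stim_s + cfg$rest_s)
  rownames(sched) <- NULL
  total_s <- cfg$prep_s + n_trials * (cfg$stim_s + cfg$rest_s)
  n <- sample_index(total_s, fs)
  t <- (seq_len(n) - 1) / fs
  map <- nirs_probe_map()
  rois <- roi_channels(map)

  # evoked responses
  template <- block_response(cfg$hrf, cfg$stim_s, fs)
  gains <- pmax(0, rnorm(n_trials, 1, cfg$noise$trial_gain_sd))
  data <- matrix(0, nrow = 20L, ncol = n)
  eff <- cfg$effects
  if (nrow(eff)) {
    for (k in seq_len(n_trials)) {
      rows <- which((is.na(eff$location_deg) |
                       eff$location_deg == sched$location_deg[k]) &
                    (is.na(eff$intensity_db) |
                       eff$intensity_db == sched$intensity_db[k]))
      for (r in rows) {
        i0 <- sample_index(sched$onset_s[k] + eff$latency_s[r], fs)
        idx <- seq.int(i0 + 1L, min(i0 + length(template), n))
        if (!length(idx) || idx[1] > n) next
        chs <- rois[[as.character(eff$roi_id[r])]]
        add <- eff$amplitude[r] * gains[k] * template[seq_along(idx)]
        data[chs, idx] <- data[chs, idx] +
          matrix(add, nrow = length(chs), ncol = length(idx), byrow = TRUE)
      }
    }
  }

  # physiological + instrumental noise; component frequencies fixed
  # within the session, phases/jitters per channel
  nz <- cfg$noise
  f_card <- runif(1, 1.0, 1.5)
  f_resp <- runif(1, 0.2, 0.5)
  f_drift <- runif(1, 0.005, 0.03)
  global <- if (nz$global_amp > 0) {
    g <- cumsum(rnorm(n))
    nz$global_amp * (g - mean(g)) / max(sd(g), .Machine$double.eps)
  } else {
    numeric(n)
  }
  for (ch in 1:20) {
    j <- runif(3, 0.8, 1.2)
    ph <- runif(3, 0, 2 * pi)
    wn <- rnorm(n, 0, nz$white_sd)
    data[ch, ] <- data[ch, ] +
      nz$cardiac_amp * j[1] * sin(2 * pi * f_card * t + ph[1]) +
      nz$respiration_amp * j[2] * sin(2 * pi * f_resp * t + ph[2]) +
      nz$drift_amp * j[3] * sin(2 * pi * f_drift * t + ph[3]) +
      wn + global
  }

  events <- data.frame(onset_s = sched$onset_s,
                       location_deg = sched$location_deg,
                       intensity_db = sched$intensity_db,
                       duration_s = cfg$stim_s)
  rec <- nirs_recording(data, fs_hz = fs, chromophore = "oxy",
                        channels = map, events = events,
                        subject_id = cfg$subject_id)

  # behavioral responses from the confusion model
  targets <- location_to_speaker(sched$location_deg)
  responses <- vapply(targets, function(tg) {
    sample(1:7, 1L, prob = cfg$behavior[as.character(tg), ])
  }, integer(1))
  beh <- behavioral_session(data.frame(target_speaker = as.integer(targets),
                                       response_speaker = responses,
                                       intensity_db = sched$intensity_db))

  list(recording = rec, behavior = beh,
       truth = sched[, c("trial", "onset_s", "location_deg", "intensity_db")])
}

#' Write the standard battery of synthetic fixture sessions
#'
#' Emits three seeded sessions used by tests and documentation — a
#' null-effect session, a low-noise high-SNR lateral-vs-front session and
#' an intensity-effect-only session — in the native text layout, plus a
#' `manifest.json` with file checksums.
#'
#' @param out_dir writable directory.
#' @param seed integer seed; regenerating with the same seed reproduces
#'   identical files.
#' @return Character vector of written paths (invisibly the manifest is
#'   included last).
#' @export
make_fixture_suite <- function(out_dir, seed = 7L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  quiet_noise <- noise_settings(cardiac_amp = 0.01, respiration_amp = 0.01,
                                drift_amp = 0.01, white_sd = 0.002,
                                global_amp = 0.02, trial_gain_sd = 0.02)
  cfgs <- list(
    null_effect = simulation_config(seed = seed, n_reps = 10,
                                    locations = c(-90L, 0L),
                                    intensities = 58L,
                                    effects = effect_preset("null"),
                                    subject_id = "fixture-null"),
    high_snr_lateral = simulation_config(seed = seed + 1L, n_reps = 10,
                                         locations = c(-90L, 0L),
                                         intensities = 58L,
                                         effects = effect_preset("high_snr"),
                                         noise = quiet_noise,
                                         subject_id = "fixture-high-snr"),
    intensity_only = simulation_config(seed = seed + 2L, n_reps = 10,
                                       locations = -90L,
                                       intensities = c(48L, 58L),
                                       effects = effect_preset("intensity"),
                                       noise = quiet_noise,
                                       subject_id = "fixture-intensity")
  )
  paths <- character(0)
  for (nm in names(cfgs)) {
    sess <- simulate_session(cfgs[[nm]])
    p <- file.path(out_dir, nm)
    write_recording(sess$recording, p)
    write_behavior(sess$behavior, file.path(p, "behavior.tsv"))
    write.table(sess$truth, file.path(p, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  files <- list.files(paths, full.names = TRUE, recursive = TRUE)
  manifest <- list(seed = seed,
                   sessions = names(cfgs),
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(files)),
                     substring(files, nchar(out_dir) + 2L))))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  c(paths, mpath)
}
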