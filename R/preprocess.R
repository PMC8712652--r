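#' Default extinction coefficients for the three-wavelength instrument
#'
#' Molar extinction coefficients of oxy- and deoxy-hemoglobin at 780, 805
#' and 830 nm, in 1/(mM·mm), from the standard compiled in-vitro spectra
#' (805 nm sits near the isosbestic point).  Shipped as an editable
#' constant: continuous-wave instruments bundle their own table, and only
#' the inversion, not the specific values, is load-bearing here.
#'
#' @return 3 x 2 matrix, rows named by wavelength, columns
#'   `eps_oxy`, `eps_deoxy`.
#' @export
extinction_defaults <- function() {
  matrix(c(0.0710, 0.1075,
           0.0830, 0.0793,
           0.0974, 0.0693),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("780", "805", "830"),
                         c("eps_oxy", "eps_deoxy")))
}

#' Modified Beer-Lambert conversion of optical density to hemoglobin
#'
#' Solves, sample by sample, the linear model `delta_OD = E %*% delta_c * L`
#' in the least-squares sense for the concentration changes of oxy- and
#' deoxy-hemoglobin, where `E` is the wavelengths x chromophores extinction
#' matrix and `L` the effective pathlength.  With three wavelengths and two
#' chromophores the system is overdetermined; total hemoglobin is the sum
#' of the two solutions.
#'
#' @param delta_od numeric matrix, 3 wavelengths x samples, of
#'   optical-density changes for one channel.
#' @param extinction 3 x 2 extinction matrix ([extinction_defaults()]),
#'   1/(mM·mm).
#' @param pathlength_mm effective optical pathlength (mm).
#' @return List of numeric vectors `oxy`, `deoxy`, `total` (mM·mm when
#'   `pathlength_mm = 1`, mM otherwise).
#' @export
mbll_convert <- function(delta_od, extinction = extinction_defaults(),
                         pathlength_mm = 1) {
  if (!is.matrix(delta_od) || nrow(delta_od) != 3L) {
    stop("delta_od must be a 3 wavelengths x samples matrix")
  }
  E <- unname(as.matrix(extinction))
  if (qr(E)$rank < 2L) stop("extinction matrix is rank deficient")
  # least squares: delta_c = (E'E)^-1 E' delta_OD / L
  sol <- solve(crossprod(E), crossprod(E, delta_od)) / pathlength_mm
  list(oxy = as.numeric(sol[1L, ]), deoxy = as.numeric(sol[2L, ]),
       total = as.numeric(sol[1L, ] + sol[2L, ]))
}

#' Common average reference spatial filter
#'
#' Subtracts the across-channel mean from every channel at each time
#' point, removing global systemic influences and task-evoked
#' physiological noise shared by all channels.
#'
#' @param rec a [nirs_recording()] with at least two channels.
#' @return The filtered recording; column (time-point) means of the output
#'   are zero to numerical precision.
#' @export
car_filter <- function(rec) {
  stopifnot(inherits(rec, "nirs_recording"))
  if (nrow(rec$data) < 2L) {
    stop("common average reference is undefined for a single channel")
  }
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec
}

#' Band-pass filter specification
#'
#' Fourth-order Butterworth low-pass at 0.2 Hz (suppressing heartbeat at
#' 1-1.5 Hz and respiration at 0.2-0.5 Hz) followed by a fourth-order
#' 0.03 Hz Butterworth high-pass removing baseline drift.
#'
#' @param high_pass_hz high-pass cutoff (default 0.03).
#' @param low_pass_hz low-pass cutoff (default 0.2).
#' @param order filter order (default 4).
#' @param application `"zero_phase"` (forward-backward, no phase delay;
#'   effective attenuation doubled) or `"causal"` (single pass).
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(high_pass_hz = 0.03, low_pass_hz = 0.2,
                        order = 4L,
                        application = c("zero_phase", "causal")) {
  application <- match.arg(application)
  if (!(high_pass_hz > 0 && high_pass_hz < low_pass_hz)) {
    stop("need 0 < high_pass_hz < low_pass_hz")
  }
  structure(list(high_pass_hz = high_pass_hz, low_pass_hz = low_pass_hz,
                 order = as.integer(order), application = application),
            class = "filter_spec")
}

apply_butter <- function(x, flt, application) {
  if (application == "zero_phase") {
    signal::filtfilt(flt, x)
  } else {
    as.numeric(signal::filter(flt, x))
  }
}

#' Butterworth band-pass filtering of a continuous recording
#'
#' Applies the low-pass, then the high-pass of `spec` to every channel of
#' the continuous data (never per epoch).  Defaults are zero-phase so the
#' discriminative 5-8 s response window is not shifted by phase delay.
#'
#' @param rec a [nirs_recording()].
#' @param spec a [filter_spec()].
#' @return Filtered recording of identical shape.
#' @export
bandpass <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "nirs_recording"), inherits(spec, "filter_spec"))
  nyq <- rec$fs_hz / 2
  if (spec$low_pass_hz >= nyq || spec$high_pass_hz >= nyq) {
    stop("filter cutoff must be below the Nyquist frequency ", nyq, " Hz")
  }
  lp <- signal::butter(spec$order, spec$low_pass_hz / nyq, type = "low")
  hp <- signal::butter(spec$order, spec$high_pass_hz / nyq, type = "high")
  for (ch in seq_len(nrow(rec$data))) {
    y <- apply_butter(rec$data[ch, ], lp, spec$application)
    rec$data[ch, ] <- apply_butter(y, hp, spec$application)
  }
  rec
}

#' Segment a continuous recording into stimulus-locked trials
#'
#' Cuts a 10-s (133-sample at 13.3 Hz) window from each stimulus onset.
#' Sample mapping is half-open `[round(onset*fs), round((onset+10)*fs))`.
#' With `baseline = "pre_stim_mean"` the per-channel mean over the second
#' preceding the onset (`[-1, 0)` s) is subtracted from each trial.
#'
#' @param rec a [nirs_recording()] with events.
#' @param baseline `"pre_stim_mean"` (default) or `"none"`.
#' @param window_s epoch length in seconds (default 10).
#' @return Object of class `nirs_epochs`: `data` (array trials x units x
#'   samples), `labels` (location_deg, intensity_db per trial), `fs_hz`,
#'   `unit_kind = "channel"`, `unit_ids`, `window_s`.
#' @export
segment <- function(rec, baseline = c("pre_stim_mean", "none"),
                    window_s = 10) {
  stopifnot(inherits(rec, "nirs_recording"))
  baseline <- match.arg(baseline)
  ev <- rec$events
  if (!nrow(ev)) stop("recording has no events to segment")
  fs <- rec$fs_hz
  n <- ncol(rec$data)
  len <- sample_index(window_s, fs)
  i0 <- sample_index(ev$onset_s, fs)
  too_late <- i0 + len > n
  if (any(too_late)) {
    stop("event(s) too close to the recording end for a ", window_s,
         "-s window: onsets ",
         paste(ev$onset_s[too_late], collapse = ", "), " s")
  }
  nb <- sample_index(1, fs)
  if (baseline == "pre_stim_mean" && any(i0 - nb < 0)) {
    stop("pre-stimulus baseline needs 1 s of data before every onset")
  }
  nu <- nrow(rec$data)
  arr <- array(NA_real_, dim = c(nrow(ev), nu, len))
  for (k in seq_len(nrow(ev))) {
    seg <- rec$data[, (i0[k] + 1L):(i0[k] + len), drop = FALSE]
    if (baseline == "pre_stim_mean") {
      base <- rowMeans(rec$data[, (i0[k] - nb + 1L):i0[k], drop = FALSE])
      seg <- seg - base
    }
    arr[k, , ] <- seg
  }
  structure(list(data = arr,
                 labels = data.frame(location_deg = ev$location_deg,
                                     intensity_db = ev$intensity_db),
                 fs_hz = fs, unit_kind = "channel",
                 unit_ids = rec$channels$channel_id,
                 window_s = window_s),
            class = "nirs_epochs")
}

#' @export
print.nirs_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<nirs_epochs> %d trials x %d %ss x %d samples (%.3g Hz)\n",
              d[1], d[2], x$unit_kind, d[3], x$fs_hz))
  invisible(x)
}

#' Average channels into regions of interest
#'
#' Reduces a channel-level trial tensor to the 10-ROI level by arithmetic
#' averaging of each ROI's member channels (single-channel ROIs pass
#' through unchanged).
#'
#' @param epochs channel-level `nirs_epochs` ([segment()]).
#' @param map probe map ([nirs_probe_map()]).
#' @return ROI-level `nirs_epochs` with `unit_kind = "roi"` and 10 units.
#' @export
roi_average <- function(epochs, map = nirs_probe_map()) {
  stopifnot(inherits(epochs, "nirs_epochs"))
  if (epochs$unit_kind != "channel") {
    stop("roi_average expects a channel-level trial tensor")
  }
  validate_probe_map(map)
  if (!setequal(epochs$unit_ids, map$channel_id)) {
    stop("probe map channels do not match the trial tensor units")
  }
  rois <- roi_channels(map)
  d <- dim(epochs$data)
  out <- array(NA_real_, dim = c(d[1], length(rois), d[3]))
  for (j in seq_along(rois)) {
    pos <- match(rois[[j]], epochs$unit_ids)
    sub <- epochs$data[, pos, , drop = FALSE]
    out[, j, ] <- apply(sub, c(1, 3), mean)
  }
  epochs$data <- out
  epochs$unit_kind <- "roi"
  epochs$unit_ids <- as.integer(names(rois))
  epochs
}

#' Grand-average response curves per condition
#'
#' Mean and standard-error curves across trials for each condition cell
#' (within a subject), or across per-subject mean curves when given a list
#' of epoch objects (group level).  SEM = sd/sqrt(n).
#'
#' @param epochs a `nirs_epochs`, or a list of them (one per subject).
#' @param group_by label columns defining conditions (default location and
#'   intensity).
#' @return Named list per condition with elements `mean` and `sem` (units
#'   x samples matrices) and `n` (trials or subjects averaged).
#' @export
grand_average <- function(epochs,
                          group_by = c("location_deg", "intensity_db")) {
  if (inherits(epochs, "nirs_epochs")) {
    return(grand_average_one(epochs, group_by))
  }
  stopifnot(is.list(epochs), length(epochs) >= 2)
  per_subj <- lapply(epochs, grand_average_one, group_by = group_by)
  conds <- names(per_subj[[1]])
  out <- lapply(conds, function(cn) {
    curves <- lapply(per_subj, function(g) g[[cn]]$mean)
    arr <- simplify2array(curves)  # units x samples x subjects
    n <- dim(arr)[3]
    list(mean = apply(arr, c(1, 2), mean),
         sem = apply(arr, c(1, 2), sd) / sqrt(n),
         n = n)
  })
  stats::setNames(out, conds)
}

grand_average_one <- function(epochs, group_by) {
  lab <- epochs$labels[, group_by, drop = FALSE]
  key <- interaction(lab, drop = TRUE, sep = "/")
  groups <- split(seq_len(nrow(lab)), key)
  if (any(lengths(groups) < 2)) {
    stop("every condition needs at least 2 trials for a grand average")
  }
  lapply(groups, function(idx) {
    sub <- epochs$data[idx, , , drop = FALSE]
    list(mean = apply(sub, c(2, 3), mean),
         sem = apply(sub, c(2, 3), sd) / sqrt(length(idx)),
         n = length(idx))
  })
}

#' Standard preprocessing chain for one session
#'
#' Runs the full continuous-domain chain in the canonical order — common
#' average reference, low-pass, high-pass — then epochs and (optionally)
#' reduces to ROI level.  Filters are always applied to the continuous
#' recording, never per epoch.
#'
#' @param rec a [nirs_recording()].
#' @param spec a [filter_spec()].
#' @param baseline epoch baseline mode, see [segment()].
#' @param granularity `"roi"` (default) or `"channel"`.
#' @return A `nirs_epochs` object.
#' @export
preprocess_recording <- function(rec, spec = filter_spec(),
                                 baseline = "pre_stim_mean",
                                 granularity = c("roi", "channel")) {
  granularity <- match.arg(granularity)
  epochs <- segment(bandpass(car_filter(rec), spec), baseline = baseline)
  if (granularity == "roi") epochs <- roi_average(epochs, rec$channels)
  epochs
}
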