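#' Canonical double-gamma hemodynamic response kernel
#'
#' Impulse response of the oxy-Hb concentration to a neural event: a
#' positive gamma peaking at `peak_s` minus a scaled gamma undershoot.
#' Convolved with the 10-s stimulus boxcar this yields block responses
#' whose discriminative portion falls in the 5-8 s window, consistent with
#' task-evoked responses appearing with 3-8 s delay.
#'
#' @param peak_s time-to-peak in seconds (default 6).
#' @param undershoot_s time-to-undershoot-minimum in seconds (default 16).
#' @param ratio undershoot-to-peak amplitude ratio (default 1/6).
#' @param duration_s kernel support in seconds (default 32).
#' @return Object of class `hrf_kernel`.
#' @export
hrf_kernel <- function(peak_s = 6, undershoot_s = 16, ratio = 1 / 6,
                       duration_s = 32) {
  stopifnot(peak_s > 0, undershoot_s > peak_s, ratio >= 0, duration_s > 0)
  structure(list(peak_s = peak_s, undershoot_s = undershoot_s,
                 ratio = ratio, duration_s = duration_s),
            class = "hrf_kernel")
}

#' Sample an HRF kernel at a given rate
#'
#' @param kernel an [hrf_kernel()].
#' @param fs_hz sampling rate.
#' @return Numeric vector, unit peak amplitude, positive integral.
#' @export
hrf_sample <- function(kernel, fs_hz) {
  stopifnot(inherits(kernel, "hrf_kernel"), fs_hz > 0)
  t <- seq(0, kernel$duration_s, by = 1 / fs_hz)
  # gamma density with scale 1 has its mode at shape - 1
  g1 <- stats::dgamma(t, shape = kernel$peak_s + 1, scale = 1)
  g2 <- stats::dgamma(t, shape = kernel$undershoot_s + 1, scale = 1)
  h <- g1 / max(g1) - kernel$ratio * g2 / max(g2)
  h <- h / max(h)
  if (sum(h) / fs_hz <= 0) stop("HRF kernel must integrate to a positive value")
  h
}

#' Block-design response template
#'
#' HRF convolved with a stimulus boxcar of the given duration, normalized
#' to unit peak so condition amplitudes are interpretable as peak
#' concentration changes (mM·mm).
#'
#' @param kernel an [hrf_kernel()].
#' @param stim_s stimulus duration in seconds (default 10).
#' @param fs_hz sampling rate.
#' @return Numeric vector (length covers stimulus + kernel support).
#' @export
block_response <- function(kernel, stim_s = 10, fs_hz = 13.3) {
  h <- hrf_sample(kernel, fs_hz)
  box <- rep(1, max(1L, sample_index(stim_s, fs_hz)))
  r <- stats::convolve(h, rev(box), type = "open") / fs_hz
  r / max(r)
}
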