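#' Construct a behavioral sound-localization session
#'
#' Responses from the seven-loudspeaker array spanning -90 deg (speaker 1)
#' to +90 deg (speaker 7) at 30 deg spacing.  Only five speakers (1, 3, 4,
#' 5, 7) present stimuli, but listeners are unaware of that, so valid
#' responses range over all seven.
#'
#' @param trials data frame with columns `target_speaker` (1-7, active
#'   speakers only), `response_speaker` (1-7) and `intensity_db` (48/58).
#' @return Object of class `behavioral_session` with the trial table and a
#'   `speaker_angles_deg` map.
#' @export
behavioral_session <- function(trials) {
  need <- c("target_speaker", "response_speaker", "intensity_db")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("behavioral trials missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(trials$response_speaker %in% 1:7)) {
    stop("invalid response: valid responses range from speaker 1 to 7")
  }
  if (!all(trials$target_speaker %in% c(1L, 3L, 4L, 5L, 7L))) {
    stop("targets must be active speakers 1, 3, 4, 5 or 7")
  }
  structure(list(trials = trials,
                 speaker_angles_deg = speaker_angles()),
            class = "behavioral_session")
}

#' Loudspeaker angles of the seven-speaker arc
#'
#' @return Named numeric vector: speaker 1 -> -90 deg through speaker
#'   7 -> +90 deg in 30 deg steps.
#' @export
speaker_angles <- function() {
  stats::setNames((1:7 - 4) * 30, as.character(1:7))
}

#' Root-mean-square localization error in degrees
#'
#' Each response is converted to an angular error (reported minus target
#' speaker angle); the RMS over the selected trials is
#' `sqrt(mean(error^2))`, with correct responses contributing zero.
#'
#' @param session a [behavioral_session()].
#' @param intensity_db optional: restrict to 48 or 58 dB trials
#'   (default `NULL`, all trials).
#' @return RMS error in degrees (full precision; see [round_half_up()] for
#'   2-decimal report formatting).
#' @export
rms_error <- function(session, intensity_db = NULL) {
  stopifnot(inherits(session, "behavioral_session"))
  tr <- session$trials
  if (!is.null(intensity_db)) {
    tr <- tr[tr$intensity_db %in% intensity_db, , drop = FALSE]
  }
  if (!nrow(tr)) stop("no trials in the requested subset")
  ang <- session$speaker_angles_deg
  err <- ang[as.character(tr$response_speaker)] -
    ang[as.character(tr$target_speaker)]
  sqrt(mean(err^2))
}

#' Per-level RMS report for a behavioral session
#'
#' Summarizes localization performance at both stimulus levels plus pooled,
#' with the angular-error histogram.  RMS values satisfy the pooling
#' identity `rms_all^2 * n_all = rms_low^2 * n_low + rms_high^2 * n_high`.
#'
#' @param session a [behavioral_session()].
#' @return List of class `rms_report`: `rms_low_deg`, `rms_high_deg`,
#'   `rms_all_deg`, `n_low`, `n_high`, `error_histogram` (table of signed
#'   errors in degrees).
#' @export
rms_report <- function(session) {
  stopifnot(inherits(session, "behavioral_session"))
  ang <- session$speaker_angles_deg
  tr <- session$trials
  err <- ang[as.character(tr$response_speaker)] -
    ang[as.character(tr$target_speaker)]
  structure(list(
    rms_low_deg = rms_error(session, 48),
    rms_high_deg = rms_error(session, 58),
    rms_all_deg = rms_error(session),
    n_low = sum(tr$intensity_db == 48),
    n_high = sum(tr$intensity_db == 58),
    error_histogram = table(error_deg = err)
  ), class = "rms_report")
}

#' @export
print.rms_report <- function(x, ...) {
  cat(sprintf("RMS localization error: low %.2f deg (n=%d), high %.2f deg (n=%d), all %.2f deg\n",
              round_half_up(x$rms_low_deg), x$n_low,
              round_half_up(x$rms_high_deg), x$n_high,
              round_half_up(x$rms_all_deg)))
  invisible(x)
}

#' Target-by-response count matrix
#'
#' Counts responses for each of the five active target speakers over all
#' seven possible responses; the basis of the bubble-plot summary of
#' localization confusions (e.g. -90 deg reported as -60 deg).
#'
#' @param session a [behavioral_session()].
#' @param intensity_db optional level restriction (48/58).
#' @return 5 x 7 integer matrix, rows named by the active target speakers,
#'   columns by response speaker; row sums equal trials per target.
#' @export
response_matrix <- function(session, intensity_db = NULL) {
  stopifnot(inherits(session, "behavioral_session"))
  tr <- session$trials
  if (!is.null(intensity_db)) {
    tr <- tr[tr$intensity_db %in% intensity_db, , drop = FALSE]
  }
  active <- c(1L, 3L, 4L, 5L, 7L)
  m <- table(factor(tr$target_speaker, levels = active),
             factor(tr$response_speaker, levels = 1:7))
  m <- matrix(as.integer(m), nrow = 5, dimnames = list(
    target = as.character(active), response = as.character(1:7)))
  m
}

#' Round half away from zero to a fixed number of decimals
#'
#' Report-formatting convention for RMS and accuracy tables (2 decimals,
#' halves rounded up), as opposed to R's banker's rounding.
#'
#' @param x numeric.
#' @param digits decimals (default 2).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Read a behavioral response log
#'
#' @param path TSV with columns `target_speaker`, `response_speaker`,
#'   `intensity_db` (one row per trial).
#' @return A [behavioral_session()].
#' @export
read_behavior <- function(path) {
  behavioral_session(read.table(path, sep = "\t", header = TRUE))
}

#' Write a behavioral response log
#'
#' @param session a [behavioral_session()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_behavior <- function(session, path) {
  write.table(session$trials, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
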