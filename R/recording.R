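#' Construct a continuous fNIRS concentration recording
#'
#' A recording holds one subject's multichannel concentration time series
#' (pathlength-scaled units, mM·mm), the sampling rate, channel metadata
#' and the stimulus event table of a block-design session (10 s stimulus /
#' 10 s rest).
#'
#' @param data numeric matrix, channels x samples.
#' @param fs_hz sampling rate in Hz (default 13.3, the instrument rate).
#' @param chromophore one of `"oxy"`, `"deoxy"`, `"total"`.
#' @param channels probe map data frame ([nirs_probe_map()] layout); may
#'   have fewer rows than 20 for reduced montages, but row count must match
#'   `nrow(data)`.
#' @param events data frame with columns `onset_s`, `location_deg`
#'   (-90/-30/0/30/90), `intensity_db` (48/58) and `duration_s`; sorted by
#'   onset on construction.
#' @param subject_id character label.
#' @return An object of class `nirs_recording`.
#' @seealso [read_recording()], [write_recording()], [simulate_session()]
#' @export
nirs_recording <- function(data, fs_hz = 13.3, chromophore = "oxy",
                           channels = nirs_probe_map(),
                           events = empty_events(), subject_id = "sim") {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("data must be a numeric channels x samples matrix")
  }
  if (anyNA(data)) stop("recording contains missing samples")
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0) {
    stop("fs_hz must be a single positive number")
  }
  chromophore <- match.arg(chromophore, c("oxy", "deoxy", "total"))
  if (nrow(data) != nrow(channels)) {
    stop("row count of data (", nrow(data),
         ") must equal channel count (", nrow(channels), ")")
  }
  events <- validate_events(events, n_samples = ncol(data), fs_hz = fs_hz)
  rec <- structure(
    list(data = data, fs_hz = fs_hz, chromophore = chromophore,
         channels = channels, events = events,
         subject_id = as.character(subject_id)),
    class = "nirs_recording"
  )
  rec
}

empty_events <- function() {
  data.frame(onset_s = numeric(0), location_deg = integer(0),
             intensity_db = integer(0), duration_s = numeric(0))
}

validate_events <- function(events, n_samples, fs_hz) {
  need <- c("onset_s", "location_deg", "intensity_db", "duration_s")
  miss <- setdiff(need, names(events))
  if (length(miss)) {
    stop("event table is missing column(s): ", paste(miss, collapse = ", "))
  }
  events <- events[order(events$onset_s), need, drop = FALSE]
  rownames(events) <- NULL
  if (nrow(events)) {
    if (any(diff(events$onset_s) <= 0)) {
      stop("event onsets must be strictly increasing")
    }
    if (any(events$onset_s < 0)) stop("event onsets must be non-negative")
    last_idx <- sample_index(events$onset_s, fs_hz)
    bad <- last_idx >= n_samples
    if (any(bad)) {
      stop("event(s) at onset ", paste(events$onset_s[bad], collapse = ", "),
           " s lie beyond the recorded span")
    }
    if (!all(events$location_deg %in% c(-90L, -30L, 0L, 30L, 90L))) {
      stop("location_deg must be one of -90, -30, 0, 30, 90")
    }
    if (!all(events$intensity_db %in% c(48L, 58L))) {
      stop("intensity_db must be 48 or 58")
    }
  }
  events
}

# 0-based sample index of a time point: index = round(t * fs).
# Fixed once so that the non-integral samples-per-second rate (13.3 Hz)
# maps second-aligned boundaries deterministically.
sample_index <- function(t_s, fs_hz) {
  as.integer(round(t_s * fs_hz))
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat("<nirs_recording> subject", x$subject_id, "\n")
  cat(sprintf("  %d channels x %d samples (%.4g s at %.3g Hz), chromophore: %s\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$fs_hz,
              x$fs_hz, x$chromophore))
  cat(sprintf("  %d events\n", nrow(x$events)))
  invisible(x)
}

#' Write a recording to the native text layout
#'
#' The native on-disk form of a session is a directory of diffable text
#' files: `header.yaml` (sampling rate, chromophore, subject, dimensions),
#' `signals.tsv` (channels x samples matrix, one channel per row, first
#' column the channel id), `events.tsv` and `channels.tsv` (probe map).
#'
#' @param rec a [nirs_recording()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "nirs_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory ", path)
  header <- list(fs_hz = rec$fs_hz, chromophore = rec$chromophore,
                 subject_id = rec$subject_id,
                 n_channels = nrow(rec$data), n_samples = ncol(rec$data))
  yaml::write_yaml(header, file.path(path, "header.yaml"),
                   precision = 15L)
  sig <- data.frame(channel_id = rec$channels$channel_id,
                    format(rec$data, digits = 15L, trim = TRUE,
                           scientific = TRUE))
  write.table(sig, file.path(path, "signals.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(rec$events, file.path(path, "events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(rec$channels, file.path(path, "channels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a recording from the native text layout
#'
#' @param path directory written by [write_recording()].
#' @return A [nirs_recording()], with events sorted by onset and all
#'   recording invariants re-validated.
#' @export
read_recording <- function(path) {
  hfile <- file.path(path, "header.yaml")
  if (!file.exists(hfile)) stop("no header.yaml under ", path)
  header <- yaml::read_yaml(hfile)
  for (field in c("fs_hz", "chromophore", "n_channels")) {
    if (is.null(header[[field]])) {
      stop("malformed header: missing field '", field, "'")
    }
  }
  sig <- read.table(file.path(path, "signals.tsv"), sep = "\t",
                    header = FALSE, quote = "", comment.char = "")
  channels <- read.table(file.path(path, "channels.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE,
                         quote = "", comment.char = "")
  events <- read.table(file.path(path, "events.tsv"), sep = "\t",
                       header = TRUE, quote = "", comment.char = "")
  data <- as.matrix(sig[, -1L, drop = FALSE])
  dimnames(data) <- NULL
  if (nrow(data) != header$n_channels) {
    stop("signals.tsv has ", nrow(data), " channels, header declares ",
         header$n_channels)
  }
  # preserve on-disk channel order
  channels <- channels[match(sig[[1L]], channels$channel_id), , drop = FALSE]
  rownames(channels) <- NULL
  nirs_recording(data, fs_hz = header$fs_hz,
                 chromophore = header$chromophore, channels = channels,
                 events = events,
                 subject_id = header$subject_id %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
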