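#' Probe map for the 20-channel bilateral auditory/prefrontal montage
#'
#' The montage places eight sources and eight detectors over both
#' hemispheres (3 cm separation), yielding 20 measurement channels.
#' Channels 1-10 sit on the left hemisphere, 11-20 on the right.  Channels
#' are grouped into 10 regions of interest (ROIs) of one to four
#' neighbouring channels sharing the same anatomical assignment: premotor /
#' supplementary motor cortex (BA6), supramarginal gyrus (BA40),
#' dorsolateral prefrontal cortex (BA9), superior temporal gyrus (BA22) and
#' auditory association cortex (BA42), mirrored across hemispheres
#' (ROI 1-5 left, ROI 6-10 right).
#'
#' MNI coordinates are channel midpoints projected on the cortical surface;
#' `proportion` is the probability of the anatomical assignment.  The map
#' is shipped verbatim from the study montage; two entries look like
#' transcription artifacts and are deliberately retained as published:
#' channel 6's X coordinate (-6) is atypical for a lateral optode, and
#' channel 17 duplicates channel 18's coordinates.
#'
#' @return A data frame with one row per channel and columns `channel_id`,
#'   `hemisphere` (`"left"`/`"right"`), `roi_id` (1-10), `brodmann_area`,
#'   `mni_x`, `mni_y`, `mni_z` (mm), `proportion` and `area` (anatomical
#'   label).
#' @examples
#' pm <- nirs_probe_map()
#' table(pm$hemisphere)
#' split(pm$channel_id, pm$roi_id)
#' @export
nirs_probe_map <- function() {
  pm <- data.frame(
    channel_id = c(1L, 2L, 5L, 8L, 3L, 6L, 4L, 7L, 10L, 9L,
                   11L, 12L, 15L, 18L, 13L, 16L, 14L, 17L, 20L, 19L),
    hemisphere = rep(c("left", "right"), each = 10L),
    roi_id = c(1L, 1L, 1L, 1L, 2L, 2L, 3L, 4L, 4L, 5L,
               6L, 6L, 6L, 6L, 7L, 7L, 8L, 9L, 9L, 10L),
    brodmann_area = c(6L, 6L, 6L, 6L, 40L, 40L, 9L, 22L, 22L, 42L,
                      6L, 6L, 6L, 6L, 40L, 40L, 9L, 22L, 22L, 42L),
    mni_x = c(-60, -65, -66, -64, -68, -6, -69, -68, -71, -68,
              62, 67, 68, 67, 69, 71, 63, 69, 72, 71),
    mni_y = c(3, -18, -6, 6, -39, -29, -16, -50, -39, -16,
              2, -18, -5, 4, -40, -29, 14, 4, -41, -17),
    mni_z = c(39, 39, 29, 17, 30, 25, 27, 7, 2, 14,
              40, 41, 31, 18, 31, 27, 27, 18, 1, 14),
    proportion = c(0.7964, 0.3576, 0.6310, 0.5016, 0.9527, 0.6075,
                   0.5610, 0.5290, 0.5092, 0.4658,
                   0.8272, 0.3588, 0.7785, 0.5342, 0.9968, 0.7037,
                   0.6111, 0.4618, 0.5140, 0.4969),
    area = c(rep("Pre-motor and supplementary motor cortex", 4),
             rep("Supramarginal gyrus part of Wernicke's area", 2),
             "dlPFC", rep("Superior temporal gyrus", 2),
             "Auditory association cortex",
             rep("Pre-motor and supplementary motor cortex", 4),
             rep("Supramarginal gyrus part of Wernicke's area", 2),
             "dlPFC", rep("Superior temporal gyrus", 2),
             "Auditory association cortex"),
    stringsAsFactors = FALSE
  )
  pm <- pm[order(pm$channel_id), , drop = FALSE]
  rownames(pm) <- NULL
  pm
}

#' Channel membership of each region of interest
#'
#' @param map probe map as returned by [nirs_probe_map()].
#' @return Named list mapping ROI id (as `"1"`..`"10"`) to the sorted
#'   integer channel ids it averages.
#' @export
roi_channels <- function(map = nirs_probe_map()) {
  lapply(split(map$channel_id, map$roi_id), sort)
}

#' Mirror-symmetric ROI pairs across hemispheres
#'
#' The montage is left/right symmetric: ROI k on the left corresponds
#' anatomically to ROI k + 5 on the right (premotor 1/6, supramarginal 2/7,
#' dlPFC 3/8, STG 4/9, auditory association 5/10).  Used by the
#' interhemispheric (ipsi/contralateral) decoding contrasts.
#'
#' @return Data frame with columns `pair`, `left_roi`, `right_roi`.
#' @export
hemisphere_pairs <- function() {
  data.frame(pair = 1:5, left_roi = 1:5, right_roi = 6:10)
}

validate_probe_map <- function(map) {
  stopifnot(is.data.frame(map))
  need <- c("channel_id", "hemisphere", "roi_id", "brodmann_area",
            "mni_x", "mni_y", "mni_z", "proportion")
  miss <- setdiff(need, names(map))
  if (length(miss)) {
    stop("probe map is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!identical(sort(map$channel_id), 1:20)) {
    stop("probe map must contain channels 1-20 exactly once")
  }
  if (anyNA(match(map$hemisphere, c("left", "right")))) {
    stop("hemisphere must be 'left' or 'right'")
  }
  bad_side <- (map$channel_id <= 10 & map$hemisphere != "left") |
    (map$channel_id > 10 & map$hemisphere != "right")
  if (any(bad_side)) stop("channels 1-10 must be left, 11-20 right")
  if (!all(map$roi_id %in% 1:10)) stop("roi_id must be in 1..10")
  invisible(map)
}
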