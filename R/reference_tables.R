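#' Published per-subject classification accuracies
#'
#' Best LOOCV classification accuracies (percent) of the 25 normal-hearing
#' subjects of the original sound-localization study, for the six
#' lateral/front contrasts (-90/0, 0/+90, -90/+90 at 48 and 58 dB) and
#' the six 30-degree contrasts (-30/0, 0/+30, -30/+30 at both levels).
#' Shipped so summary statistics (means, counts above the 70% margin,
#' level comparisons) can be recomputed and cross-checked without the
#' undeposited recordings.
#'
#' @return Data frame: `contrast`, `intensity_db`, `s1`..`s25`.
#' @seealso [summarize_accuracies()], [compare_conditions()]
#' @export
reference_accuracy_table <- function() {
  read.csv(system.file("extdata", "localization_accuracy_by_subject.csv",
                       package = "nirsloc", mustWork = TRUE),
           check.names = FALSE)
}

#' Published per-subject RMS localization errors
#'
#' RMS localization errors in degrees at the two stimulus levels and
#' pooled, for the subjects of the original study with any localization
#' errors; the remaining 15 subjects performed perfectly (0/0/0).  Used to
#' validate the pooling identity
#' `rms_all^2 * n_all = rms_low^2 * n_low + rms_high^2 * n_high`.
#'
#' @return Data frame: `subject`, `rms_low`, `rms_high`, `rms_all`.
#' @export
reference_rms_table <- function() {
  read.csv(system.file("extdata", "rms_by_subject.csv",
                       package = "nirsloc", mustWork = TRUE))
}

accuracy_row <- function(tab, contrast, intensity_db) {
  r <- tab$contrast == contrast & tab$intensity_db == intensity_db
  if (sum(r) != 1L) stop("no unique row for ", contrast, " at ",
                         intensity_db, " dB")
  as.numeric(tab[r, paste0("s", 1:25)])
}
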