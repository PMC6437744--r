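# Packaged reference tables from a published nine-subject, ten-session
# forearm-array calibration study, transcribed cell-for-cell as printed.
# They let the summary operations be checked against published numbers
# without access to the raw amplitude curves (which were never
# deposited).

#' Reference per-subject, per-pad CV table
#'
#' The transcribed coefficient-of-variation matrix (percent) of selected
#' amplitudes over ten calibration sessions for nine subjects on a
#' 16-pad array, together with the printed per-subject mean +/- SD
#' columns. The printed row summaries follow the sample (n-1) SD
#' convention.
#'
#' @return A list with `cv` (9 x 16 numeric matrix, rownames the subject
#'   numbers) and `printed` (data.frame with `subject_id`, `mean`, `sd`
#'   as printed).
#' @export
study_cv_fixture <- function() {
  path <- system.file("extdata", "study_cv_percent.csv", package = "etcal",
                      mustWork = TRUE)
  df <- utils::read.csv(path)
  cv <- as.matrix(df[, paste0("pad_", 1:16)])
  rownames(cv) <- as.character(df$subject)
  colnames(cv) <- paste0("pad", 1:16)
  list(cv = cv,
       printed = data.frame(subject_id = as.character(df$subject),
                            mean = df$printed_mean, sd = df$printed_sd))
}

#' Reference per-subject correlation summaries
#'
#' The transcribed correlation table for the same study: per subject, the
#' mean +/- SD correlation of the ten session curves with the overall
#' mean curve and with the subject's individual mean curve, and the
#' correlations of the streamlined-session curve with the individual
#' mean and with the 25th-percentile baseline.
#'
#' @return A data.frame with one row per subject and columns
#'   `subject`, `r_overall_mean`, `r_overall_sd`, `r_individual_mean`,
#'   `r_individual_sd`, `r_streamlined_individual`,
#'   `r_streamlined_baseline`.
#' @export
study_correlation_fixture <- function() {
  path <- system.file("extdata", "study_correlations.csv", package = "etcal",
                      mustWork = TRUE)
  utils::read.csv(path)
}
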