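#' Vigilance stage alphabet
#'
#' The seven EEG-vigilance stages in wakefulness-to-drowsiness order:
#' `0` (desynchronized active wakefulness), `A1`--`A3` (alpha-dominant
#' relaxed wakefulness with a posterior-to-anterior alpha shift across the
#' substages), `B1` (low-voltage non-alpha drowsiness), `B2/3`
#' (delta/theta-dominant drowsiness) and `C` (sleep onset, marked by
#' spindles or K-complexes). Segments rejected during artifact screening
#' carry the extra symbol `"ARTIFACT"`.
#'
#' @param with_artifact if `TRUE`, append the `"ARTIFACT"` symbol.
#' @return character vector of stage symbols.
#' @export
#' @examples
#' vigilance_stages()
vigilance_stages <- function(with_artifact = FALSE) {
  s <- c("0", "A1", "A2", "A3", "B1", "B2/3", "C")
  if (with_artifact) c(s, "ARTIFACT") else s
}

#' Numeric vigilance values of the stages
#'
#' Maps each stage to the numeric value used for the mean vigilance level:
#' 0 -> 7, A1 -> 6, A2 -> 5, A3 -> 4, B1 -> 3, B2/3 -> 2, C -> 1. Higher
#' values mean higher arousal. `ARTIFACT` has no numeric value (`NA`).
#'
#' @return named numeric vector over the 7 stages.
#' @export
stage_values <- function() {
  c("0" = 7, "A1" = 6, "A2" = 5, "A3" = 4, "B1" = 3, "B2/3" = 2, "C" = 1)
}

#' Default 10/20 montage of the vigilance pipeline
#'
#' The 25 EEG electrodes plus one EOG and one ECG channel used for
#' vigilance staging of 20-min resting recordings.
#'
#' @return character vector of 27 channel labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "CP1", "CP2", "CP5", "CP6", "Fz", "Cz", "Pz",
    "FC5", "FC6", "T7", "T8", "FC1", "FC2", "EOG", "ECG")
}

#' Channel roles for a set of labels
#'
#' @param labels channel labels.
#' @return character vector in `{"EEG","EOG","ECG"}` per label.
#' @export
channel_roles <- function(labels) {
  ifelse(labels == "EOG", "EOG", ifelse(labels == "ECG", "ECG", "EEG"))
}

#' Scalp region of each EEG channel
#'
#' Coarse frontal/central/posterior grouping used both by the generator's
#' stage spectra and by the classifier's region-of-interest band powers.
#'
#' @param labels channel labels; non-EEG labels map to `NA`.
#' @return character vector in `{"frontal","central","posterior"}`.
#' @export
channel_regions <- function(labels) {
  frontal   <- c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz")
  posterior <- c("P3", "P4", "Pz", "O1", "O2", "CP1", "CP2", "CP5", "CP6")
  central   <- c("C3", "C4", "Cz", "FC1", "FC2", "FC5", "FC6", "T7", "T8")
  out <- rep(NA_character_, length(labels))
  out[labels %in% frontal]   <- "frontal"
  out[labels %in% central]   <- "central"
  out[labels %in% posterior] <- "posterior"
  out
}

# Region-of-interest channel sets used by the classifier (configurable
# through fit_thresholds/classify_recording arguments).
default_roi <- function() {
  list(alpha_posterior = c("P3", "P4", "Pz", "O1", "O2"),
       alpha_frontal   = c("Fp1", "Fp2", "F3", "F4", "Fz"))
}

#' Frequency bands used throughout the package
#'
#' Delta-theta 2--7 Hz, alpha 8--12 Hz, beta 13--30 Hz, and the broadband
#' 0.5--70 Hz range of the analysis filter.
#'
#' @return named list of `c(lo, hi)` Hz intervals.
#' @export
vigilance_bands <- function() {
  list(delta_theta = c(2, 7), alpha = c(8, 12), beta = c(13, 30),
       total = c(0.5, 70))
}
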