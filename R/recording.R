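#' Multichannel EEG recording container
#'
#' A `Recording` holds a channels-by-samples signal matrix in microvolts
#' together with its sampling rate, channel labels and channel roles
#' (EEG/EOG/ECG). All package operations take and return this container.
#'
#' @param signals numeric matrix, channels x samples, in uV.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_labels character vector, one label per row of `signals`.
#' @param roles optional roles per channel; derived from labels if omitted.
#' @return object of class `Recording`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(400), 2, 200), 200, c("Cz", "Pz"))
#' rec
recording <- function(signals, sampling_rate, channel_labels, roles = NULL) {
  signals <- as.matrix(signals)
  if (nrow(signals) != length(channel_labels))
    stop("channel_labels must have one entry per signal row")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a positive number")
  if (is.null(roles)) roles <- channel_roles(channel_labels)
  rownames(signals) <- channel_labels
  structure(
    list(signals = signals,
         sampling_rate = sampling_rate,
         channel_labels = channel_labels,
         channel_roles = roles),
    class = "Recording")
}

#' @export
print.Recording <- function(x, ...) {
  dur <- ncol(x$signals) / x$sampling_rate
  cat(sprintf("<Recording> %d channels x %d samples (%.1f s @ %g Hz)\n",
              nrow(x$signals), ncol(x$signals), dur, x$sampling_rate))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording a `Recording`.
#' @return duration in seconds.
#' @export
recording_duration <- function(recording) {
  ncol(recording$signals) / recording$sampling_rate
}

# signals for a role subset, as a matrix (possibly 1 x n)
role_signals <- function(recording, role) {
  idx <- which(recording$channel_roles == role)
  recording$signals[idx, , drop = FALSE]
}

eeg_channel_index <- function(recording) {
  which(recording$channel_roles == "EEG")
}
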