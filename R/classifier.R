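#' Band power of a 1-s segment
#'
#' Mean over channels of the Hann-tapered periodogram power integrated
#' over a frequency band. With a 1-s window the spectral resolution is
#' 1 Hz; the band is inclusive of both edges and the normalization is
#' chosen so that the summed power over all bands recovers the signal
#' variance (taper-corrected Parseval).
#'
#' @param x numeric vector (one channel) or channels x samples matrix.
#' @param band `c(lo, hi)` in Hz.
#' @param sampling_rate sampling rate in Hz.
#' @return band power in uV^2 (mean over channels).
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * (0:199) / 200)
#' compute_band_power(x, c(8, 12), 200)  # ~0.5
compute_band_power <- function(x, band, sampling_rate) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  N <- ncol(x)
  if (band[2] > sampling_rate / 2)
    stop("band extends beyond the Nyquist frequency")
  P <- periodogram_matrix(x, sampling_rate)
  f <- as.numeric(colnames(P))
  mean(rowSums(P[, f >= band[1] & f <= band[2], drop = FALSE]))
}

# one-sided power spectrum per channel, bins at fs/N Hz spacing, scaled so
# that rowSums over all bins equals the taper-corrected signal variance
periodogram_matrix <- function(x, sampling_rate) {
  N <- ncol(x)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(N) / N))  # periodic Hann
  xw <- sweep(x, 2, w, `*`)
  F <- t(stats::mvfft(t(xw)))
  nb <- N %/% 2 + 1
  P <- abs(F[, seq_len(nb), drop = FALSE])^2 / (N * sum(w^2))
  dbl <- rep(2, nb)
  dbl[1] <- 1
  if (N %% 2 == 0) dbl[nb] <- 1
  P <- sweep(P, 2, dbl, `*`)
  colnames(P) <- (seq_len(nb) - 1) * sampling_rate / N
  P
}

#' Detect slow eye movements around a segment
#'
#' A segment counts as SEM-positive when the 0.1--1 Hz filtered EOG,
#' within a 3-s window centred on the segment, exceeds `p2p_threshold`
#' peak-to-peak. Blink transients are too fast to survive the slow
#' band-pass and do not trigger the detector.
#'
#' @param eog EOG channel samples (uV).
#' @param sampling_rate Hz.
#' @param segment 1-based segment index.
#' @param p2p_threshold peak-to-peak bound in uV (default 100).
#' @param prefiltered set `TRUE` when `eog` is already 0.1--1 Hz filtered
#'   (lets callers filter once per recording).
#' @return logical.
#' @export
detect_sem <- function(eog, sampling_rate, segment, p2p_threshold = 100,
                       prefiltered = FALSE) {
  xf <- if (prefiltered) eog else sem_filter(eog, sampling_rate)
  fs <- sampling_rate
  i0 <- max(1, (segment - 2) * fs + 1)
  i1 <- min(length(xf), (segment + 1) * fs)
  w <- xf[i0:i1]
  (max(w) - min(w)) > p2p_threshold
}

sem_filter <- function(eog, sampling_rate) {
  ny <- sampling_rate / 2
  bf <- signal::butter(2, c(0.1, 1) / ny, type = "pass")
  signal::filtfilt(bf, eog)
}

#' Per-segment classifier features
#'
#' Computes, for every segment, the region-of-interest band powers the
#' classifier decides on: posterior alpha (8--12 Hz over P3, P4, Pz, O1,
#' O2), frontal alpha (over Fp1, Fp2, F3, F4, Fz), delta-theta (2--7 Hz
#' over all EEG channels), broadband total power, and the SEM flag from
#' the EOG channel.
#'
#' @param recording preprocessed [recording()].
#' @param segments `SegmentTable`.
#' @param roi list with `alpha_posterior` and `alpha_frontal` channel
#'   label sets (default [default_roi()]).
#' @param sem_p2p_threshold SEM peak-to-peak bound, uV.
#' @return data frame, one row per segment: `segment`, `alpha_posterior`,
#'   `alpha_frontal`, `delta_theta`, `total_power`, `sem_present`.
#' @export
segment_features <- function(recording, segments, roi = default_roi(),
                             sem_p2p_threshold = 100) {
  fs <- recording$sampling_rate
  n_seg <- nrow(segments)
  bands <- vigilance_bands()
  eeg <- eeg_channel_index(recording)
  labs <- recording$channel_labels
  i_post <- which(labs %in% roi$alpha_posterior & labs %in% labs[eeg])
  i_front <- which(labs %in% roi$alpha_frontal & labs %in% labs[eeg])
  if (!length(i_post) || !length(i_front))
    stop("region-of-interest channels not found in the montage")

  eog <- role_signals(recording, "EOG")
  have_eog <- nrow(eog) > 0
  if (!have_eog)
    warning("no EOG channel: slow eye movements cannot be detected and ",
            "stage B1 will collapse to 0")
  eogf <- if (have_eog) sem_filter(eog[1, ], fs) else NULL

  out <- data.frame(segment = segments$segment,
                    alpha_posterior = NA_real_, alpha_frontal = NA_real_,
                    delta_theta = NA_real_, total_power = NA_real_,
                    sem_present = FALSE)
  for (s in seq_len(n_seg)) {
    i0 <- segments$start_sample[s]
    blk <- recording$signals[, i0:(i0 + fs - 1), drop = FALSE]
    P <- periodogram_matrix(blk[eeg, , drop = FALSE], fs)
    f <- as.numeric(colnames(P))
    in_band <- function(b) f >= b[1] & f <= b[2]
    bp <- function(rows, b)
      mean(rowSums(P[rows, in_band(b), drop = FALSE]))
    rows_post <- match(i_post, eeg)
    rows_front <- match(i_front, eeg)
    out$alpha_posterior[s] <- bp(rows_post, bands$alpha)
    out$alpha_frontal[s] <- bp(rows_front, bands$alpha)
    out$delta_theta[s] <- bp(seq_along(eeg), bands$delta_theta)
    out$total_power[s] <- bp(seq_along(eeg), bands$total)
    if (have_eog)
      out$sem_present[s] <- detect_sem(eogf, fs, s, sem_p2p_threshold,
                                       prefiltered = TRUE)
  }
  out
}

#' Fit adaptive per-recording stage thresholds
#'
#' The alpha and delta-theta decision thresholds adapt to each recording:
#' by default twice the median posterior-alpha and delta-theta power over
#' all artifact-free segments. Because the median sits at the non-alpha
#' floor whenever alpha-dominant segments are a minority, the rule is
#' invariant under rescaling of all channels. The A-substage cut points
#' `r1 < r2` split the frontal/posterior alpha power ratio.
#'
#' @param features data frame from [segment_features()], restricted to
#'   artifact-free segments by the caller or via `artifact_free`.
#' @param alpha_multiplier,dt_multiplier threshold multipliers (default 2).
#' @param r1,r2 anterior/posterior alpha ratio cut points (default 1, 1.5).
#' @param sem_p2p_threshold SEM bound carried along for reporting, uV.
#' @param artifact_free optional logical mask selecting the artifact-free
#'   rows of `features`.
#' @return object of class `StageThresholds`.
#' @export
fit_thresholds <- function(features, alpha_multiplier = 2,
                           dt_multiplier = 2, r1 = 1, r2 = 1.5,
                           sem_p2p_threshold = 100, artifact_free = NULL) {
  if (!is.null(artifact_free)) features <- features[artifact_free, ]
  if (nrow(features) < 60)
    stop("need at least 60 artifact-free segments to fit thresholds")
  if (!(r1 < r2)) stop("substage cut points must satisfy r1 < r2")
  structure(
    list(alpha_threshold =
           alpha_multiplier * stats::median(features$alpha_posterior),
         delta_theta_threshold =
           dt_multiplier * stats::median(features$delta_theta),
         a_substage_ratios = c(r1 = r1, r2 = r2),
         sem_p2p_threshold = sem_p2p_threshold),
    class = "StageThresholds")
}

#' Classify one artifact-free segment
#'
#' Decision list, first match wins: (1) a graphoelement (spindle or
#' K-complex) makes the segment stage C; (2) delta-theta power above its
#' threshold and above the posterior alpha power gives B2/3; (3) posterior
#' alpha above its threshold gives an A substage by the frontal/posterior
#' alpha ratio rho (rho <= r1: A1, r1 < rho <= r2: A2, rho > r2: A3);
#' (4) otherwise a detected slow eye movement gives B1, else stage 0.
#'
#' @param features one row of [segment_features()] (list or data frame).
#' @param thresholds a `StageThresholds` from [fit_thresholds()].
#' @param graphoelement logical graphoelement flag for the segment.
#' @return a stage label.
#' @export
classify_segment <- function(features, thresholds, graphoelement = FALSE) {
  if (graphoelement) return("C")
  if (features$delta_theta > thresholds$delta_theta_threshold &&
      features$delta_theta > features$alpha_posterior) return("B2/3")
  if (features$alpha_posterior > thresholds$alpha_threshold) {
    rho <- features$alpha_frontal / features$alpha_posterior
    r <- thresholds$a_substage_ratios
    if (rho <= r[["r1"]]) return("A1")
    if (rho <= r[["r2"]]) return("A2")
    return("A3")
  }
  if (isTRUE(features$sem_present)) "B1" else "0"
}

#' Classify every segment of a recording
#'
#' Computes features, fits adaptive thresholds on the artifact-free
#' segments (unless supplied), and applies the decision list to each
#' segment; artifact flags propagate as `ARTIFACT` labels. Deterministic
#' given its inputs.
#'
#' @param recording preprocessed [recording()].
#' @param segments flagged `SegmentTable` from [preprocess_recording()].
#' @param thresholds optional pre-fitted `StageThresholds`.
#' @param roi region-of-interest channel sets.
#' @param ... passed to [fit_thresholds()].
#' @return a [stage_sequence()] with the per-segment features attached as
#'   attribute `"features"` and the thresholds as `"thresholds"`.
#' @export
classify_recording <- function(recording, segments, thresholds = NULL,
                               roi = default_roi(), ...) {
  feats <- segment_features(recording, segments, roi)
  free <- !segments$artifact
  if (is.null(thresholds))
    thresholds <- fit_thresholds(feats[free, ], ...)
  labels <- character(nrow(segments))
  for (s in seq_len(nrow(segments))) {
    labels[s] <- if (segments$artifact[s]) "ARTIFACT" else
      classify_segment(feats[s, ], thresholds, segments$graphoelement[s])
  }
  seq <- stage_sequence(labels)
  attr(seq, "features") <- feats
  attr(seq, "thresholds") <- thresholds
  seq
}

#' Write a stage sequence as TSV
#'
#' One row per segment: 1-based index, label, and (when available) the
#' classifier features and flags.
#'
#' @param seq a [stage_sequence()].
#' @param path output path.
#' @export
write_stage_sequence <- function(seq, path) {
  df <- data.frame(segment = seq_along(seq), label = as.character(seq))
  feats <- attr(seq, "features")
  if (!is.null(feats)) df <- cbind(df, feats[, -1, drop = FALSE])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a stage sequence TSV
#'
#' @param path TSV written by [write_stage_sequence()].
#' @return a [stage_sequence()].
#' @export
read_stage_sequence <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  stage_sequence(df$label)
}
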