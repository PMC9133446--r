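#' Zero-phase band-pass and notch filtering
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass of
#' 0.5--70 Hz plus a 50 Hz notch to every channel, the standard analysis
#' filter for vigilance staging. EEG, EOG and ECG channels are filtered
#' identically. Output length equals input length and the filter
#' introduces no phase shift.
#'
#' @param recording a [recording()].
#' @param low,high band-pass edges in Hz.
#' @param notch notch frequency in Hz (`NULL` disables).
#' @param order Butterworth band-pass order (default 4).
#' @param notch_q notch quality factor f0 / bandwidth (default 30).
#' @param eog_low lower edge for EOG channels (default 0.1 Hz): slow eye
#'   movements live at 0.1--1 Hz and must survive filtering for the
#'   0-vs-B1 distinction; EEG and ECG use `low`.
#' @return the filtered [recording()].
#' @export
bandpass_notch <- function(recording, low = 0.5, high = 70, notch = 50,
                           order = 4, notch_q = 30, eog_low = 0.1) {
  fs <- recording$sampling_rate
  if (fs < 2 * high)
    stop("sampling rate must exceed twice the upper band edge")
  n <- ncol(recording$signals)
  if (n < 3 * fs / low)
    stop("recording too short for a ", low, " Hz high-pass edge: need at ",
         "least ", 3 / low, " s")
  ny <- fs / 2
  bp <- signal::butter(order, c(low, high) / ny, type = "pass")
  bp_eog <- signal::butter(order, c(eog_low, high) / ny, type = "pass")
  nf <- NULL
  if (!is.null(notch)) {
    w0 <- 2 * pi * notch / fs
    alpha <- sin(w0) / (2 * notch_q)
    b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
    a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
    nf <- list(b = b, a = a)
  }
  out <- recording
  for (ch in seq_len(nrow(out$signals))) {
    f <- if (out$channel_roles[ch] == "EOG") bp_eog else bp
    x <- signal::filtfilt(f, out$signals[ch, ])
    if (!is.null(nf)) x <- signal::filtfilt(nf$b, nf$a, x)
    out$signals[ch, ] <- x
  }
  out
}

#' Cut a recording into consecutive 1-s segments
#'
#' Segments tile the recording without overlap; a trailing partial second
#' is discarded. Segments are numbered from 1 in all outputs.
#'
#' @param recording a [recording()] (normally filtered first).
#' @return a `SegmentTable` data frame: `segment`, `start_sample`,
#'   `artifact`, `reason`, `graphoelement`, `grapho_reason`.
#' @export
segment_recording <- function(recording) {
  fs <- recording$sampling_rate
  n_seg <- ncol(recording$signals) %/% fs
  if (n_seg == 0)
    warning("recording shorter than 1 s: zero segments")
  data.frame(
    segment = seq_len(n_seg),
    start_sample = (seq_len(n_seg) - 1L) * as.integer(fs) + 1L,
    artifact = rep(FALSE, n_seg),
    reason = rep("", n_seg),
    graphoelement = rep(FALSE, n_seg),
    grapho_reason = rep("", n_seg),
    stringsAsFactors = FALSE)
}

# per-second channel summaries as n_channels x n_segments matrices
per_second_stat <- function(x, fs, n_seg, fun) {
  m <- matrix(x[seq_len(n_seg * fs)], nrow = fs)
  apply(m, 2, fun)
}

#' Automated artifact screening of 1-s segments
#'
#' Deterministic surrogate for visual artifact marking: a segment is
#' flagged when any EEG channel shows an absolute amplitude above
#' `amp_threshold`, a sample-to-sample jump above `jump_threshold`, or a
#' flatline (within-second range below `flat_range`). Reasons are recorded
#' per segment in machine-readable form (`amplitude`, `gradient`,
#' `flatline`, semicolon-joined).
#'
#' @param recording filtered [recording()].
#' @param segments a `SegmentTable` from [segment_recording()].
#' @param amp_threshold absolute amplitude bound, uV (default 100).
#' @param jump_threshold sample-to-sample jump bound, uV (default 50).
#' @param flat_range flatline range bound, uV (default 0.5).
#' @return the `SegmentTable` with `artifact`/`reason` filled in.
#' @export
detect_artifacts <- function(recording, segments, amp_threshold = 100,
                             jump_threshold = 50, flat_range = 0.5) {
  fs <- recording$sampling_rate
  n_seg <- nrow(segments)
  if (n_seg == 0) return(segments)
  eeg <- eeg_channel_index(recording)
  amp <- jump <- rep(FALSE, n_seg)
  flat <- rep(FALSE, n_seg)
  for (ch in eeg) {
    x <- recording$signals[ch, ]
    amp <- amp |
      per_second_stat(abs(x), fs, n_seg, max) > amp_threshold
    m <- matrix(x[seq_len(n_seg * fs)], nrow = fs)
    jump <- jump | apply(abs(diff(m)), 2, max) > jump_threshold
    flat <- flat | apply(m, 2, function(v) diff(range(v))) < flat_range
  }
  reasons <- mapply(function(a, j, f)
    paste(c("amplitude"[a], "gradient"[j], "flatline"[f]), collapse = ";"),
    amp, jump, flat)
  segments$artifact <- amp | jump | flat
  segments$reason <- reasons
  segments
}

#' Screen for sleep-indicating graphoelements
#'
#' Flags segments containing sleep spindles (12--16 Hz RMS envelope above
#' `spindle_factor` times its recording-wide median for at least
#' `min_dur` seconds, concurrently on at least `min_channels` central
#' channels -- genuine spindles are synchronous across the vertex while
#' narrowband noise exceedances are not) or K-complexes (a biphasic
#' 0.5--4 Hz deflection above 100 uV peak-to-peak lasting 0.5--1.5 s).
#' Segments within `artifact_pad` seconds of an artifact-flagged segment
#' are not scored: gross artifacts bleed into the band-filtered envelope.
#' Flagged artifact-free segments become eligible for stage C during
#' classification.
#'
#' @param recording filtered [recording()].
#' @param segments a `SegmentTable` (artifact flags, when already filled
#'   in, mask the neighbourhood of gross artifacts).
#' @param central_channels channel labels examined (default C3, C4, Cz).
#' @param spindle_band spindle frequency band, Hz.
#' @param spindle_factor envelope threshold as a multiple of the median.
#' @param min_dur minimal spindle duration in seconds.
#' @param min_channels central channels that must show the spindle
#'   concurrently (default 2).
#' @param kc_p2p K-complex peak-to-peak bound, uV.
#' @param artifact_pad seconds around artifact segments excluded from
#'   graphoelement scoring.
#' @return the `SegmentTable` with `graphoelement` flags filled in.
#' @export
screen_graphoelements <- function(recording, segments,
                                  central_channels = c("C3", "C4", "Cz"),
                                  spindle_band = c(12, 16),
                                  spindle_factor = 2, min_dur = 0.5,
                                  min_channels = 2, kc_p2p = 100,
                                  artifact_pad = 2) {
  fs <- recording$sampling_rate
  n_seg <- nrow(segments)
  if (n_seg == 0) return(segments)
  chans <- which(recording$channel_labels %in% central_channels &
                   recording$channel_roles == "EEG")
  spindle_votes <- matrix(FALSE, n_seg, length(chans))
  kc <- rep(FALSE, n_seg)
  ny <- fs / 2
  # steep linear-phase FIR so alpha-band energy does not leak into the
  # spindle band; centred application makes it zero-phase
  fir_ord <- min(600, 2 * (floor(ncol(recording$signals) / 3) %/% 2))
  sp_f <- signal::fir1(fir_ord, spindle_band / ny, type = "pass")
  kc_f <- signal::butter(2, c(0.5, 4) / ny, type = "pass")
  wlen <- max(3, round(0.25 * fs))
  seg_of_sample <- function(i) pmin(((i - 1) %/% fs) + 1L, n_seg)
  for (ci in seq_along(chans)) {
    ch <- chans[ci]
    x <- recording$signals[ch, ]
    # spindles: sustained exceedance of the RMS envelope
    xb <- as.vector(stats::filter(x, sp_f, sides = 2))
    xb[is.na(xb)] <- 0
    env <- sqrt(stats::filter(xb^2, rep(1 / wlen, wlen), sides = 2))
    env[is.na(env)] <- 0
    thr <- spindle_factor * stats::median(env)
    r <- rle(as.vector(env > thr))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_dur * fs
    for (i in which(keep)) {
      segs <- unique(seg_of_sample(starts[i]:ends[i]))
      spindle_votes[segs, ci] <- TRUE
    }
    # K-complexes: large biphasic slow deflection
    xk <- signal::filtfilt(kc_f, x)
    for (s in seq_len(n_seg)) {
      i0 <- max(1, (s - 1) * fs - round(0.25 * fs) + 1)
      i1 <- min(length(xk), s * fs + round(0.25 * fs))
      w <- xk[i0:i1]
      if (max(w) - min(w) > kc_p2p) {
        dt <- abs(which.max(w) - which.min(w)) / fs
        if (dt >= 0.15 && dt <= 1.5) kc[s] <- TRUE
      }
    }
  }
  spindle <- rowSums(spindle_votes) >= min(min_channels, length(chans))
  if (any(segments$artifact)) {
    near <- which(segments$artifact)
    near <- unique(pmax(1, pmin(n_seg, outer(near, -artifact_pad:artifact_pad,
                                             `+`))))
    spindle[near] <- FALSE
    kc[near] <- FALSE
  }
  segments$graphoelement <- spindle | kc
  segments$grapho_reason <- mapply(function(a, b)
    paste(c("spindle"[a], "k_complex"[b]), collapse = ";"), spindle, kc)
  segments
}

#' Preprocess a recording end to end
#'
#' Runs the standard chain: zero-phase band-pass + notch filtering, 1-s
#' segmentation, artifact screening and graphoelement screening; the
#' ICA-based removal of stereotyped ocular/cardiac artifacts
#' ([remove_stereotyped_artifacts()]) is applied when `ica = TRUE`.
#'
#' @param recording a raw [recording()].
#' @param ica run the ICA cleanup (slower; useful when ocular leakage into
#'   frontal channels is expected).
#' @param ... passed on to [detect_artifacts()].
#' @return list with elements `recording` (filtered, optionally
#'   ICA-cleaned) and `segments` (fully flagged `SegmentTable`).
#' @export
preprocess_recording <- function(recording, ica = FALSE, ...) {
  rec <- bandpass_notch(recording)
  if (ica) rec <- remove_stereotyped_artifacts(rec)
  seg <- segment_recording(rec)
  seg <- detect_artifacts(rec, seg, ...)
  seg <- screen_graphoelements(rec, seg)
  list(recording = rec, segments = seg)
}
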