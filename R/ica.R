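# FastICA with symmetric orthogonalization and the logcosh contrast.
# Deterministic: the unmixing iteration starts from the identity in the
# whitened space, so no random initialization is involved.
fast_ica <- function(X, max_iter = 100, tol = 1e-4) {
  nc <- nrow(X)
  n <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / n
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < 1e-10 * max(e$values))
    stop("rank-deficient channel covariance; ICA cannot separate ",
         "components - try a channel subset")
  K <- diag(1 / sqrt(e$values)) %*% t(e$vectors)
  Z <- K %*% Xc
  W <- diag(nc)
  sym_decorrelate <- function(W) {
    s <- eigen(tcrossprod(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(s$values)) %*% t(s$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W1 <- G %*% t(Z) / n - diag(rowMeans(1 - G^2)) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% Z                      # independent components
  A <- solve(W %*% K)               # mixing matrix (components -> channels)
  list(S = S, A = A, mean = mu, n_iter = it)
}

#' Remove stereotyped ocular and cardiac artifacts with ICA
#'
#' Decomposes the EEG channels into statistically independent components
#' and automatically excludes every component whose time course has an
#' absolute Pearson correlation above `threshold` with the EOG or ECG
#' channel, replacing the analyst's visual selection of blink, eye
#' movement and cardioballistic components. EEG channels are reconstructed
#' from the retained components; EOG and ECG pass through unchanged.
#'
#' @param recording a filtered [recording()] with EOG and ECG channels and
#'   at least 60 s of data.
#' @param threshold absolute correlation above which a component is
#'   excluded (default 0.8).
#' @param refs_band band (Hz) to which the EOG/ECG reference channels are
#'   restricted before correlating: EOG keeps sub-0.5 Hz content that the
#'   EEG analysis band-pass removes, so correlations are computed on the
#'   band the channels share.
#' @param verbose log the number of excluded components.
#' @return the cleaned [recording()]; the indices of removed components
#'   are attached as attribute `"excluded_components"`.
#' @export
remove_stereotyped_artifacts <- function(recording, threshold = 0.8,
                                         refs_band = c(0.5, 70),
                                         verbose = TRUE) {
  if (recording_duration(recording) < 60)
    stop("need at least 60 s of data for a stable decomposition")
  eog <- role_signals(recording, "EOG")
  ecg <- role_signals(recording, "ECG")
  if (nrow(eog) == 0 || nrow(ecg) == 0)
    stop("EOG and ECG channels are required to identify stereotyped ",
         "artifact components")
  eeg_idx <- eeg_channel_index(recording)
  X <- recording$signals[eeg_idx, , drop = FALSE]
  dec <- fast_ica(X)
  refs <- rbind(eog, ecg)
  if (!is.null(refs_band)) {
    bf <- signal::butter(4, refs_band / (recording$sampling_rate / 2),
                         type = "pass")
    for (i in seq_len(nrow(refs)))
      refs[i, ] <- signal::filtfilt(bf, refs[i, ])
  }
  rmax <- apply(dec$S, 1, function(s)
    max(abs(stats::cor(s, t(refs)))))
  excl <- which(rmax > threshold)
  if (verbose)
    message(length(excl), " of ", nrow(dec$S),
            " ICA components excluded (|r| > ", threshold, ")")
  out <- recording
  if (length(excl)) {
    keep <- setdiff(seq_len(nrow(dec$S)), excl)
    out$signals[eeg_idx, ] <-
      dec$A[, keep, drop = FALSE] %*% dec$S[keep, , drop = FALSE] + dec$mean
  }
  attr(out, "excluded_components") <- excl
  out
}
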