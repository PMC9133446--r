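#' Sample a latent vigilance trajectory
#'
#' Draws the per-second stage sequence of a simulated resting recording
#' from the first-order Markov chain in the configuration. The trajectory
#' is the ground truth against which staging is later scored.
#'
#' @param config a [simulation_config()].
#' @return character vector of stage labels, one per second.
#' @export
#' @examples
#' traj <- sample_stage_trajectory(simulation_config(duration = 120, seed = 1))
#' table(traj)
sample_stage_trajectory <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  P <- config$transition_matrix
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12))
    stop("transition matrix is not row-stochastic")
  n <- as.integer(round(config$duration))
  if (!is.null(config$seed)) set.seed(config$seed)
  stages <- vigilance_stages()
  idx <- integer(n)
  idx[1] <- sample.int(7, 1, prob = config$initial_distribution)
  if (n > 1)
    for (t in 2:n) idx[t] <- sample.int(7, 1, prob = P[idx[t - 1], ])
  stages[idx]
}

# unit-RMS band-limited Gaussian noise of length n, synthesized in the
# frequency domain (exact band support, no filter skirt leakage)
band_noise <- function(n, band, fs) {
  X <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                  # fold to [0, fs/2]
  X[f < band[1] | f > band[2]] <- 0i
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# per-sample envelope from per-second gains, 50 ms raised-cosine crossfade
gain_envelope <- function(gains, fs, fade = 0.05) {
  e <- rep(gains, each = fs)
  L <- max(3, round(fade * fs))
  if (L %% 2 == 0) L <- L + 1
  w <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))
  w <- w / sum(w)
  n <- length(e)
  ep <- c(rep(e[1], L), e, rep(e[n], L))
  sm <- stats::filter(ep, w, sides = 2)
  as.numeric(sm[(L + 1):(L + n)])
}

# raised-cosine pulse of given length
rc_pulse <- function(n) 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))

#' Synthesize a multichannel recording from a stage trajectory
#'
#' Renders each EEG channel as a sum of band-limited Gaussian noise
#' components (delta-theta 2--7 Hz, alpha 8--12 Hz, beta 13--30 Hz) whose
#' per-second RMS follows the stage-conditional spectra for the channel's
#' scalp region, cross-faded at second boundaries with a 50 ms
#' raised-cosine ramp, on top of a broadband noise floor. The EOG channel
#' carries slow-eye-movement oscillations (0.2--0.6 Hz, 120--200 uV
#' peak-to-peak) only during B-stage runs and blink transients (~200 uV,
#' 0.2--0.4 s) only during wake (0/A) seconds; the ECG channel carries a
#' periodic QRS-like impulse train. Gross high-amplitude artifact bursts
#' are injected at the configured rate and their seconds recorded. During
#' stage C seconds a brief 13.5 Hz spindle burst is added on the central
#' channels so that graphoelement screening can recognize them.
#'
#' @param trajectory per-second stage labels, as from
#'   [sample_stage_trajectory()].
#' @param config the [simulation_config()] used to draw the trajectory.
#' @return list with elements `recording` (a [recording()]) and
#'   `ground_truth` (stage labels, SEM event table, artifact seconds,
#'   blink times).
#' @export
synthesize_recording <- function(trajectory, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  stages <- vigilance_stages()
  bad <- which(!(trajectory %in% stages))
  if (length(bad))
    stop(sprintf("unknown stage label '%s' at second %d",
                 trajectory[bad[1]], bad[1]))
  fs <- config$sampling_rate
  n_sec <- length(trajectory)
  n <- n_sec * fs
  if (!is.null(config$seed)) set.seed(config$seed + 1L)

  labels <- config$montage
  roles <- channel_roles(labels)
  regions <- channel_regions(labels)
  bands <- vigilance_bands()
  band_names <- c("delta_theta", "alpha", "beta")

  # per-sample gain envelopes, one per band x region actually present
  env <- list()
  for (bd in band_names)
    for (rg in unique(stats::na.omit(regions)))
      env[[paste(bd, rg)]] <-
        gain_envelope(config$stage_spectra[trajectory, bd, rg], fs)

  sig <- matrix(0, nrow = length(labels), ncol = n)

  # ocular component shared between EOG and (optionally) frontal leakage
  ocular <- numeric(n)
  sec_of <- function(x) floor(x) + 1L     # time (s) -> 1-based second

  is_b <- trajectory %in% c("B1", "B2/3")
  is_wake <- trajectory %in% c("0", "A1", "A2", "A3")
  runs_of <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(start = starts[r$values], end = ends[r$values])
  }

  sem_events <- list()
  if (any(is_b) && config$sem_rate > 0) {
    br <- runs_of(is_b)
    for (i in seq_len(nrow(br))) {
      L <- br[i, "end"] - br[i, "start"] + 1L
      k <- stats::rpois(1, config$sem_rate * L / 60)
      if (k == 0) next
      for (j in seq_len(k)) {
        t0 <- (br[i, "start"] - 1) + stats::runif(1, 0, max(0.1, L - 2))
        dur <- stats::runif(1, 4, 7)
        t1 <- min(t0 + dur, br[i, "end"])     # stay inside the B run
        if (t1 - t0 < 1.5) next
        f <- stats::runif(1, 0.25, 0.6)
        amp <- stats::runif(1, 140, 200) / 2  # p2p -> amplitude
        i0 <- floor(t0 * fs) + 1L
        i1 <- min(floor(t1 * fs), n)
        tt <- (seq(i0, i1) - i0) / fs
        ramp_n <- min(length(tt) %/% 2, round(0.5 * fs))
        ramp <- rep(1, length(tt))
        ramp[seq_len(ramp_n)] <- rc_pulse(ramp_n)
        ramp[length(tt) - seq_len(ramp_n) + 1] <- rc_pulse(ramp_n)
        ocular[i0:i1] <- ocular[i0:i1] +
          amp * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi)) * ramp
        sem_events[[length(sem_events) + 1]] <- c(t0, t1)
      }
    }
  }
  sem_events <- if (length(sem_events))
    do.call(rbind, sem_events) else matrix(numeric(0), ncol = 2)
  colnames(sem_events) <- c("start", "end")

  blink_times <- numeric(0)
  if (any(is_wake) && config$blink_rate > 0) {
    wr <- runs_of(is_wake)
    for (i in seq_len(nrow(wr))) {
      L <- wr[i, "end"] - wr[i, "start"] + 1L
      k <- stats::rpois(1, config$blink_rate * L / 60)
      if (k == 0) next
      t0s <- (wr[i, "start"] - 1) + sort(stats::runif(k, 0, L - 0.5))
      for (t0 in t0s) {
        dur <- stats::runif(1, 0.2, 0.4)
        i0 <- floor(t0 * fs) + 1L
        i1 <- min(i0 + round(dur * fs) - 1L, n)
        ocular[i0:i1] <- ocular[i0:i1] +
          stats::runif(1, 180, 220) * rc_pulse(i1 - i0 + 1L)
        blink_times <- c(blink_times, t0)
      }
    }
  }

  for (ch in seq_along(labels)) {
    if (roles[ch] == "EEG") {
      x <- config$background_rms * band_noise(n, bands$total, fs)
      for (bd in band_names)
        x <- x + env[[paste(bd, regions[ch])]] * band_noise(n, bands[[bd]], fs)
      if (config$eog_leakage > 0 && regions[ch] == "frontal")
        x <- x + config$eog_leakage * ocular
      sig[ch, ] <- x
    } else if (roles[ch] == "EOG") {
      sig[ch, ] <- ocular + 4 * band_noise(n, bands$total, fs)
    } else {                                  # ECG
      x <- 5 * band_noise(n, bands$total, fs)
      period <- round(60 / config$heart_rate * fs)
      qrs <- c(-0.2, -0.1, 0.4, 1, 0.4, -0.25, -0.1) * 600
      beats <- seq(round(fs / 2), n - length(qrs), by = period)
      for (b in beats) x[b:(b + length(qrs) - 1)] <-
          x[b:(b + length(qrs) - 1)] + qrs
      sig[ch, ] <- x
    }
  }

  # spindle bursts marking stage C seconds (central channels)
  c_secs <- which(trajectory == "C")
  if (length(c_secs)) {
    cen <- which(labels %in% c("C3", "C4", "Cz"))
    for (s in c_secs) {
      i0 <- (s - 1) * fs + round(0.2 * fs)
      len <- round(0.6 * fs)
      burst <- 40 * sin(2 * pi * 13.5 * seq_len(len) / fs) * rc_pulse(len)
      for (ch in cen) sig[ch, i0:(i0 + len - 1)] <-
          sig[ch, i0:(i0 + len - 1)] + burst
    }
  }

  # gross artifacts: high-amplitude bursts confined to whole seconds
  artifact_seconds <- integer(0)
  n_art <- stats::rpois(1, config$artifact_rate * n_sec / 60)
  if (n_art > 0) {
    artifact_seconds <- sort(sample.int(n_sec, min(n_art, n_sec)))
    eeg_idx <- which(roles == "EEG")
    for (s in artifact_seconds) {
      dur <- stats::runif(1, 0.3, 0.9)
      t0 <- stats::runif(1, 0, 1 - dur)
      i0 <- (s - 1) * fs + floor(t0 * fs) + 1L
      i1 <- i0 + round(dur * fs) - 1L
      amp <- stats::runif(1, 600, 900)
      burst <- amp * sin(2 * pi * stats::runif(1, 2, 5) *
                           seq_len(i1 - i0 + 1L) / fs) *
        rc_pulse(i1 - i0 + 1L)
      hit <- sample(eeg_idx, max(5, length(eeg_idx) %/% 2))
      for (ch in hit) sig[ch, i0:i1] <- sig[ch, i0:i1] + burst
    }
  }

  rec <- recording(sig, fs, labels, roles)
  gt <- structure(
    list(stage_labels = trajectory,
         sem_events = sem_events,
         artifact_seconds = artifact_seconds,
         blink_times = blink_times),
    class = "GroundTruth")
  list(recording = rec, ground_truth = gt)
}

#' Simulate a full recording in one call
#'
#' Convenience wrapper: samples the trajectory and synthesizes signals.
#'
#' @inheritParams sample_stage_trajectory
#' @return as [synthesize_recording()].
#' @export
simulate_recording <- function(config) {
  synthesize_recording(sample_stage_trajectory(config), config)
}
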