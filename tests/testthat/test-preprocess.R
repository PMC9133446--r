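sine_recording <- function(freq, dur = 10, amp = 1, fs = 200) {
  t <- (0:(dur * fs - 1)) / fs
  vector_recording(amp * sin(2 * pi * freq * t), fs)
}

test_that("the 50 Hz notch suppresses mains interference", {
  rec <- sine_recording(50, amp = 30)
  out <- bandpass_notch(rec)
  mid <- 401:1600            # steady state, away from edge transients
  expect_lt(stats::sd(out$signals[1, mid]) /
              stats::sd(rec$signals[1, mid]), 0.05)
})

test_that("passband signals survive with zero phase shift", {
  rec <- sine_recording(10)
  out <- bandpass_notch(rec)
  mid <- 401:1600
  ratio <- stats::sd(out$signals[1, mid]) / stats::sd(rec$signals[1, mid])
  expect_gt(ratio, 0.95)
  expect_lt(ratio, 1.05)
  cc <- stats::ccf(out$signals[1, mid], rec$signals[1, mid],
                   lag.max = 3, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("white noise is attenuated at least 20 dB above 80 Hz", {
  set.seed(1)
  rec <- vector_recording(rnorm(30 * 200))
  out <- bandpass_notch(rec)
  P <- vigileeg:::periodogram_matrix(out$signals, 200)
  f <- as.numeric(colnames(P))
  atten <- 10 * log10(mean(P[1, f >= 10 & f <= 40]) /
                        mean(P[1, f >= 80]))
  expect_gte(atten, 20)
})

test_that("filtering is idempotent within tolerance", {
  set.seed(2)
  rec <- vector_recording(rnorm(30 * 200))
  f1 <- bandpass_notch(rec)
  f2 <- bandpass_notch(f1)
  rms <- function(r) sqrt(compute_band_power(r$signals[1, ], c(2, 40), 200))
  expect_lt(abs(rms(f2) - rms(f1)) / rms(f1), 0.01)
})

test_that("too-short recordings are rejected by the filter", {
  expect_error(bandpass_notch(vector_recording(rnorm(400))), "too short")
})

test_that("segmentation floors to whole seconds and warns when empty", {
  rec <- vector_recording(rnorm(round(12.7 * 200)))
  expect_equal(nrow(segment_recording(rec)), 12)
  expect_warning(seg0 <- segment_recording(vector_recording(rnorm(100))),
                 "zero segments")
  expect_equal(nrow(seg0), 0)
})

test_that("gross artifacts are recovered with few false flags", {
  fx <- default_recording_600()
  seg <- detect_artifacts(fx$pp$recording, segment_recording(fx$pp$recording))
  truth <- fx$ground_truth$artifact_seconds
  expect_gt(length(truth), 3)
  hit <- mean(truth %in% seg$segment[seg$artifact])
  false_flags <- setdiff(seg$segment[seg$artifact], truth)
  expect_gte(hit, 0.95)
  expect_lte(length(false_flags) / nrow(seg), 0.02)
})

test_that("flatline and clean signals flag as expected", {
  flat <- vector_recording(rep(0, 5 * 200))
  seg <- detect_artifacts(flat, segment_recording(flat))
  expect_true(all(seg$artifact))
  expect_true(all(grepl("flatline", seg$reason)))
  clean <- sine_recording(10, dur = 5, amp = 30)
  seg2 <- detect_artifacts(clean, segment_recording(clean))
  expect_false(any(seg2$artifact))
})

test_that("artifact flagging is monotone in the amplitude threshold", {
  fx <- default_recording_600()
  seg <- segment_recording(fx$pp$recording)
  hi <- detect_artifacts(fx$pp$recording, seg, amp_threshold = 100)
  lo <- detect_artifacts(fx$pp$recording, seg, amp_threshold = 50)
  expect_true(all(seg$segment[hi$artifact] %in% seg$segment[lo$artifact]))
})

test_that("an injected spindle burst flags its segment", {
  out <- constant_stage_recording("A1", duration = 90, seed = 4,
                                  artifact_rate = 0)
  rec <- bandpass_notch(out$recording)
  fs <- 200
  burst <- 40 * sin(2 * pi * 13 * seq_len(round(0.7 * fs)) / fs)
  i0 <- 44 * fs + 30          # inside segment 45
  for (ch in which(rec$channel_labels %in% c("C3", "C4")))
    rec$signals[ch, i0:(i0 + length(burst) - 1)] <-
      rec$signals[ch, i0:(i0 + length(burst) - 1)] + burst
  seg <- screen_graphoelements(rec, segment_recording(rec))
  expect_true(seg$graphoelement[45])
  expect_match(seg$grapho_reason[45], "spindle")
})

test_that("an injected K-complex flags its segment", {
  out <- constant_stage_recording("B1", duration = 90, seed = 5,
                                  artifact_rate = 0)
  rec <- bandpass_notch(out$recording)
  fs <- 200
  tt <- seq_len(round(0.8 * fs)) / fs
  kc <- 90 * sin(2 * pi * tt / 0.8)       # biphasic, ~180 uV p2p
  i0 <- 60 * fs + 20
  for (ch in which(rec$channel_labels %in% c("C3", "C4", "Cz")))
    rec$signals[ch, i0:(i0 + length(kc) - 1)] <-
      rec$signals[ch, i0:(i0 + length(kc) - 1)] + kc
  seg <- screen_graphoelements(rec, segment_recording(rec))
  expect_true(seg$graphoelement[61])
  expect_match(seg$grapho_reason[61], "k_complex")
})

test_that("clean wake EEG and constant signals carry no graphoelements", {
  out <- constant_stage_recording("A1", duration = 90, seed = 6,
                                  artifact_rate = 0)
  rec <- bandpass_notch(out$recording)
  seg <- screen_graphoelements(rec, segment_recording(rec))
  expect_false(any(seg$graphoelement))
  const <- vector_recording(rep(1, 90 * 200), label = "C3")
  seg2 <- screen_graphoelements(const, segment_recording(const))
  expect_false(any(seg2$graphoelement))
})

test_that("segment count is invariant under flagging", {
  fx <- default_recording_600()
  expect_equal(nrow(fx$pp$segments), 600)
})

test_that("ICA removes ocular leakage from frontal channels", {
  cfg <- simulation_config(duration = 120, seed = 5, eog_leakage = 0.3)
  out <- simulate_recording(cfg)
  rec <- bandpass_notch(out$recording)
  eog <- rec$signals[rec$channel_roles == "EOG", ]
  fr <- which(rec$channel_labels %in% c("Fp1", "Fp2"))
  pre_cor <- max(abs(stats::cor(t(rec$signals[fr, , drop = FALSE]), eog)))
  cln <- suppressMessages(remove_stereotyped_artifacts(rec))
  post_cor <- max(abs(stats::cor(t(cln$signals[fr, , drop = FALSE]), eog)))
  expect_gte(length(attr(cln, "excluded_components")), 1)
  expect_lt(post_cor, 0.5 * pre_cor)
})

test_that("ICA is a no-op when nothing correlates with EOG/ECG", {
  cfg <- simulation_config(duration = 90, seed = 6, artifact_rate = 0)
  out <- simulate_recording(cfg)
  rec <- bandpass_notch(out$recording)
  cln <- suppressMessages(remove_stereotyped_artifacts(rec))
  expect_length(attr(cln, "excluded_components"), 0)
  err <- sqrt(mean((cln$signals - rec$signals)^2)) /
    sqrt(mean(rec$signals^2))
  expect_lt(err, 0.05)
})

test_that("ICA demands EOG/ECG and enough data", {
  out <- constant_stage_recording("A1", duration = 90, seed = 7)
  rec <- bandpass_notch(out$recording)
  short <- rec
  short$signals <- short$signals[, 1:(30 * 200)]
  expect_error(remove_stereotyped_artifacts(short), "60 s")
  no_ref <- recording(rec$signals[1:25, ], 200, rec$channel_labels[1:25])
  expect_error(remove_stereotyped_artifacts(no_ref), "EOG and ECG")
})
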