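test_that("band power satisfies Parseval for a pure tone", {
  t <- (0:199) / 200
  x <- sin(2 * pi * 10 * t)
  expect_equal(compute_band_power(x, c(8, 12), 200), 0.5, tolerance = 0.05)
  # disjoint band sees essentially nothing
  expect_lt(compute_band_power(x, c(2, 7), 200),
            0.01 * compute_band_power(x, c(8, 12), 200))
  expect_error(compute_band_power(x, c(90, 120), 200), "Nyquist")
})

test_that("white-noise band power matches the flat-spectrum expectation", {
  set.seed(10)
  sigma2 <- 4
  powers <- replicate(1000,
    compute_band_power(rnorm(200, sd = 2), c(8, 12), 200))
  # 5 of 100 positive-frequency bins carry 2/200 of the variance each
  expected <- sigma2 * 5 * 2 / 200
  se <- stats::sd(powers) / sqrt(length(powers))
  expect_lt(abs(mean(powers) - expected), 3 * se)
})

test_that("SEM detection fires on slow oscillations, not blinks", {
  fs <- 200
  t <- (0:(20 * fs - 1)) / fs
  sem <- 75 * sin(2 * pi * 0.3 * t)          # 150 uV p2p at 0.3 Hz
  expect_true(detect_sem(sem, fs, 10))
  expect_false(detect_sem(rep(0, 20 * fs), fs, 10))
  blink <- rep(0, 20 * fs)
  i0 <- 10 * fs
  blink[i0:(i0 + 59)] <- 200 * 0.5 * (1 - cos(2 * pi * (1:60) / 61))
  expect_false(detect_sem(blink, fs, 10))    # 0.3 s transient: too fast
})

test_that("thresholds follow the 2x-median rule and scale with power", {
  feats <- data.frame(segment = 1:80, alpha_posterior = 7,
                      alpha_frontal = 3, delta_theta = 5,
                      total_power = 20, sem_present = FALSE)
  th <- fit_thresholds(feats)
  expect_equal(th$alpha_threshold, 14)
  expect_equal(th$delta_theta_threshold, 10)
  scaled <- feats
  scaled[, 2:5] <- scaled[, 2:5] * 4          # doubling amplitudes
  th2 <- fit_thresholds(scaled)
  expect_equal(th2$alpha_threshold, 4 * th$alpha_threshold)
  expect_error(fit_thresholds(feats[1:30, ]), "60")
  expect_error(fit_thresholds(feats, r1 = 2, r2 = 1), "r1 < r2")
})

test_that("the decision list classifies canonical feature vectors", {
  th <- structure(list(alpha_threshold = 10, delta_theta_threshold = 20,
                       a_substage_ratios = c(r1 = 1, r2 = 1.5),
                       sem_p2p_threshold = 100),
                  class = "StageThresholds")
  f <- function(ap, af, dt, sem = FALSE)
    list(alpha_posterior = ap, alpha_frontal = af, delta_theta = dt,
         sem_present = sem)
  expect_equal(classify_segment(f(50, 15, 5), th), "A1")    # rho 0.3
  expect_equal(classify_segment(f(50, 60, 5), th), "A2")    # rho 1.2
  expect_equal(classify_segment(f(50, 100, 5), th), "A3")   # rho 2.0
  expect_equal(classify_segment(f(5, 5, 60), th), "B2/3")   # dt 3x thr
  expect_equal(classify_segment(f(5, 5, 5, sem = TRUE), th), "B1")
  expect_equal(classify_segment(f(5, 5, 5, sem = FALSE), th), "0")
  expect_equal(classify_segment(f(50, 15, 5), th, graphoelement = TRUE),
               "C")
})

test_that("A-stage seconds exceed the fitted alpha threshold", {
  fx <- default_recording_600()
  seq <- with_cache("seq600", function()
    classify_recording(fx$pp$recording, fx$pp$segments))
  feats <- attr(seq, "features")
  th <- attr(seq, "thresholds")
  gt <- fx$ground_truth$stage_labels
  free <- !fx$pp$segments$artifact
  a_secs <- free & gt %in% c("A1", "A2", "A3")
  expect_gte(mean(feats$alpha_posterior[a_secs] > th$alpha_threshold), 0.9)
})

test_that("staging recovers the latent trajectory on default material", {
  fx <- default_recording_600()
  seq <- with_cache("seq600", function()
    classify_recording(fx$pp$recording, fx$pp$segments))
  agree <- stage_agreement(as.character(seq), fx$ground_truth$stage_labels)
  expect_gte(agree, 0.8)
  # stage C never appears under default simulation conditions
  expect_false("C" %in% as.character(seq))
  # artifacts propagate
  expect_true(all(which(fx$pp$segments$artifact) %in%
                    which(as.character(seq) == "ARTIFACT")))
})

test_that("staging is invariant under rescaling all channels", {
  cfg <- simulation_config(duration = 150, seed = 21,
                           sem_rate = 0, blink_rate = 0, artifact_rate = 0)
  out <- simulate_recording(cfg)
  pp <- preprocess_recording(out$recording)
  s1 <- classify_recording(pp$recording, pp$segments)
  scaled <- pp$recording
  scaled$signals <- scaled$signals * 3
  s2 <- classify_recording(scaled, pp$segments)
  expect_identical(as.character(s1), as.character(s2))
})

test_that("all-artifact segment tables yield all-ARTIFACT sequences", {
  out <- constant_stage_recording("A1", duration = 70, seed = 3)
  pp <- preprocess_recording(out$recording)
  seg <- pp$segments
  seg$artifact <- TRUE
  th <- structure(list(alpha_threshold = 10, delta_theta_threshold = 20,
                       a_substage_ratios = c(r1 = 1, r2 = 1.5),
                       sem_p2p_threshold = 100),
                  class = "StageThresholds")
  seq <- classify_recording(pp$recording, seg, thresholds = th)
  expect_true(all(as.character(seq) == "ARTIFACT"))
})

test_that("raising the drowsiness gain never lowers the B2/3 fraction", {
  fracs <- vapply(c(10, 14, 18), function(g) {
    spectra <- default_stage_spectra()
    spectra["B2/3", "delta_theta", ] <- g
    cfg <- simulation_config(duration = 240, seed = 31,
                             stage_spectra = spectra)
    out <- simulate_recording(cfg)
    pp <- preprocess_recording(out$recording)
    seq <- classify_recording(pp$recording, pp$segments)
    mean(as.character(seq) == "B2/3")
  }, 0)
  expect_true(all(diff(fracs) >= 0))
})

test_that("a missing EOG collapses B1 to 0 with a warning", {
  cfg <- simulation_config(duration = 90, seed = 12, artifact_rate = 0)
  out <- simulate_recording(cfg)
  pp <- preprocess_recording(out$recording)
  keep <- pp$recording$channel_roles != "EOG"
  rec <- recording(pp$recording$signals[keep, ], 200,
                   pp$recording$channel_labels[keep])
  expect_warning(seq <- classify_recording(rec, pp$segments), "EOG")
  expect_false("B1" %in% as.character(seq))
})

test_that("stage sequences round-trip through TSV", {
  fx <- default_recording_600()
  seq <- with_cache("seq600", function()
    classify_recording(fx$pp$recording, fx$pp$segments))
  path <- tempfile(fileext = ".tsv")
  write_stage_sequence(seq, path)
  back <- read_stage_sequence(path)
  expect_identical(as.character(back), as.character(seq))
})
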