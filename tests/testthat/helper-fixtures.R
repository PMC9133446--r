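# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# mid-sized default-condition recording with ground truth (600 s)
default_recording_600 <- function() {
  with_cache("rec600", function() {
    cfg <- simulation_config(duration = 600, seed = 3)
    out <- simulate_recording(cfg)
    pp <- preprocess_recording(out$recording)
    c(out, pp = list(pp))
  })
}

# a single-channel EEG recording from a vector
vector_recording <- function(x, fs = 200, label = "Cz") {
  recording(matrix(x, nrow = 1), fs, label)
}

# constant-stage trajectory recording
constant_stage_recording <- function(stage, duration = 120, seed = 1, ...) {
  cfg <- simulation_config(duration = duration, seed = seed, ...)
  synthesize_recording(rep(stage, duration), cfg)
}

# stage sequence built from counts, optionally shuffled
seq_of <- function(..., shuffle = FALSE, seed = NULL) {
  counts <- c(...)
  labs <- rep(names(counts), counts)
  if (shuffle) {
    if (!is.null(seed)) set.seed(seed)
    labs <- sample(labs)
  }
  stage_sequence(labs)
}

# Printed paired-test rows (difference mean, SD, t, dz), n = 9 pairs,
# from the pre/post vigilance study this package re-implements.
printed_paired_rows <- list(
  BLT_A1  = c(-0.069, 0.128, -1.621, -0.540),
  BLT_B23 = c(0.090, 0.079, 3.430, 1.143),
  BLT_mv  = c(-0.489, 0.498, -2.944, -0.981),
  TAU_A1  = c(-0.043, 0.212, -0.602, -0.201),
  TAU_B23 = c(0.046, 0.298, 0.460, 0.153),
  TAU_mv  = c(-0.237, 1.067, -0.667, -0.222))

# interval of t (and dz) values compatible with 3-decimal rounding of the
# printed difference mean and SD
rounding_intervals <- function(m, s, n) {
  corners <- expand.grid(m = m + c(-5e-4, 5e-4), s = s + c(-5e-4, 5e-4))
  list(t = range(corners$m / (corners$s / sqrt(n))),
       dz = range(corners$m / corners$s))
}

# a difference sample with exactly the given mean and SD
sample_with_moments <- function(m, s, n) {
  x <- scale(seq_len(n))[, 1]
  m + s * x / stats::sd(x)
}

# weighted half-agreement between predicted and true stages
# (A2/A3 confusions count half)
stage_agreement <- function(pred, truth) {
  free <- pred != "ARTIFACT"
  p <- pred[free]; g <- truth[free]
  w <- ifelse(p == g, 1,
              ifelse((p == "A2" & g == "A3") | (p == "A3" & g == "A2"),
                     0.5, 0))
  mean(w)
}
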