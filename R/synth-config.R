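#' Default stage transition matrix
#'
#' Row-stochastic 7x7 first-order Markov transition matrix over the stage
#' order 0, A1, A2, A3, B1, B2/3, C governing the per-second latent
#' vigilance trajectory. The default is persistent (long stage runs) and
#' its stationary distribution puts roughly 30% of the time in A1 and 34%
#' in B2/3 with an alpha-dominant (A) total below one half, resembling the
#' occurrence profile of depressed adolescents at rest. Stage C receives
#' no mass by default (sleep onset is not reached in 20 min of quiet rest);
#' its row escapes back to B2/3 so the chain has a unique stationary law.
#'
#' @return 7x7 matrix with stage dimnames.
#' @export
default_transition_matrix <- function() {
  s <- vigilance_stages()
  P <- matrix(c(
    .82,   .144,  .009,  0,     .027,  0,     0,
    .027,  .901,  .036,  .009,  .027,  0,     0,
    0,     .162,  .73,   .072,  .036,  0,     0,
    0,     .036,  .09,   .748,  .09,   .036,  0,
    0,     .054,  .009,  .045,  .766,  .126,  0,
    0,     0,     0,     .0072, .0648, .928,  0,
    0,     0,     0,     0,     0,     1,     0),
    nrow = 7, byrow = TRUE, dimnames = list(s, s))
  P
}

#' Default per-stage band spectra
#'
#' Stage x band x region table of root-mean-square amplitudes (uV) for the
#' band-limited noise components of the generator. The defaults encode the
#' staging signatures: posterior-dominant alpha in A1, anteriorized alpha
#' across A2/A3, a low-voltage floor in B1, delta-theta dominance in B2/3,
#' and low-amplitude beta-dominant activity in stage 0.
#'
#' @return numeric array `[stage, band, region]` with dimnames.
#' @export
default_stage_spectra <- function() {
  stages <- vigilance_stages()
  bands <- c("delta_theta", "alpha", "beta")
  regions <- c("frontal", "central", "posterior")
  a <- array(0, dim = c(7, 3, 3), dimnames = list(stages, bands, regions))
  # rows: delta_theta, alpha, beta per region                  f    c    p
  a["0",    "delta_theta", ] <- c(3, 3, 3)
  a["0",    "alpha", ]       <- c(2.5, 2.5, 2.5)
  a["0",    "beta", ]        <- c(5, 5, 5)
  a["A1",   "delta_theta", ] <- c(4, 4, 4)
  a["A1",   "alpha", ]       <- c(6, 12, 22)     # posterior >= 3x frontal
  a["A1",   "beta", ]        <- c(4, 4, 4)
  a["A2",   "delta_theta", ] <- c(4, 4, 4)
  a["A2",   "alpha", ]       <- c(14, 13, 13)    # frontal ~ posterior
  a["A2",   "beta", ]        <- c(4, 4, 4)
  a["A3",   "delta_theta", ] <- c(5, 5, 5)
  a["A3",   "alpha", ]       <- c(15, 12, 10)    # frontal >= 1.5x posterior
  a["A3",   "beta", ]        <- c(4, 4, 4)
  a["B1",   "delta_theta", ] <- c(5, 5, 5)
  a["B1",   "alpha", ]       <- c(2.5, 2.5, 2.5) # low voltage, alpha gone
  a["B1",   "beta", ]        <- c(4, 4, 4)
  a["B2/3", "delta_theta", ] <- c(14, 14, 14)    # delta-theta >= 2x alpha
  a["B2/3", "alpha", ]       <- c(4, 4, 4)
  a["B2/3", "beta", ]        <- c(4, 4, 4)
  a["C",    "delta_theta", ] <- c(16, 16, 16)
  a["C",    "alpha", ]       <- c(3, 3, 3)
  a["C",    "beta", ]        <- c(4, 4, 4)
  a
}

#' Configuration of the synthetic resting-EEG generator
#'
#' Collects every knob of the generator: recording geometry, the Markov
#' model of the latent vigilance trajectory, the stage-conditional band
#' spectra, and the rates of ocular, cardiac and gross-artifact events.
#'
#' @param duration recording length in seconds (default 1200, i.e. 20 min).
#' @param sampling_rate sampling rate in Hz (default 200).
#' @param montage ordered channel labels (default [default_montage()]).
#' @param transition_matrix 7x7 row-stochastic matrix over the stage order
#'   0, A1, A2, A3, B1, B2/3, C.
#' @param initial_distribution probability 7-vector for the first second.
#' @param stage_spectra stage x band x region RMS table (uV), as produced
#'   by [default_stage_spectra()].
#' @param sem_rate slow-eye-movement events per minute of B-stage time.
#' @param blink_rate blinks per minute of wake (0/A) time.
#' @param artifact_rate gross-artifact seconds per minute.
#' @param heart_rate ECG rate in beats per minute.
#' @param background_rms broadband (0.5--70 Hz) noise floor RMS in uV.
#' @param eog_leakage fraction of the EOG signal mixed into frontal EEG
#'   channels (0 disables; used to exercise the ICA cleanup).
#' @param seed integer seed making trajectory and signals reproducible.
#' @return object of class `SimulationConfig`.
#' @export
#' @examples
#' cfg <- simulation_config(duration = 60, seed = 1)
simulation_config <- function(duration = 1200,
                              sampling_rate = 200,
                              montage = default_montage(),
                              transition_matrix = default_transition_matrix(),
                              initial_distribution =
                                c(.15, .70, .08, .05, .02, 0, 0),
                              stage_spectra = default_stage_spectra(),
                              sem_rate = 12,
                              blink_rate = 8,
                              artifact_rate = 1,
                              heart_rate = 70,
                              background_rms = 2,
                              eog_leakage = 0,
                              seed = NULL) {
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == c(7, 7)))
    stop("transition_matrix must be 7x7 over the stage order ",
         paste(vigilance_stages(), collapse = ", "))
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-12))
    stop("transition_matrix rows must be non-negative and sum to 1")
  if (length(initial_distribution) != 7 || any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 1) > 1e-12)
    stop("initial_distribution must be a probability 7-vector")
  if (any(stage_spectra < 0)) stop("stage spectra gains must be >= 0")
  n_samp <- duration * sampling_rate
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("duration x sampling_rate must be an integer sample count")
  dimnames(transition_matrix) <-
    list(vigilance_stages(), vigilance_stages())
  structure(
    list(duration = duration, sampling_rate = sampling_rate,
         montage = montage,
         transition_matrix = transition_matrix,
         initial_distribution = initial_distribution,
         stage_spectra = stage_spectra,
         sem_rate = sem_rate, blink_rate = blink_rate,
         artifact_rate = artifact_rate, heart_rate = heart_rate,
         background_rms = background_rms, eog_leakage = eog_leakage,
         seed = seed),
    class = "SimulationConfig")
}

#' Read or write a generator configuration as YAML
#'
#' The scalar fields map directly; the transition matrix and spectra are
#' stored as nested lists. Fields absent from the file fall back to the
#' [simulation_config()] defaults.
#'
#' @param path file path.
#' @return for the reader, a `SimulationConfig`.
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (f in c("duration", "sampling_rate", "sem_rate", "blink_rate",
              "artifact_rate", "heart_rate", "background_rms",
              "eog_leakage", "seed"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  if (!is.null(y$montage)) args$montage <- unlist(y$montage)
  if (!is.null(y$transition_matrix))
    args$transition_matrix <-
      do.call(rbind, lapply(y$transition_matrix, unlist))
  if (!is.null(y$initial_distribution))
    args$initial_distribution <- unlist(y$initial_distribution)
  if (!is.null(y$stage_spectra)) {
    a <- default_stage_spectra()
    for (st in names(y$stage_spectra))
      for (bd in names(y$stage_spectra[[st]]))
        a[st, bd, ] <- unlist(y$stage_spectra[[st]][[bd]])
    args$stage_spectra <- a
  }
  do.call(simulation_config, args)
}

#' @rdname read_simulation_config
#' @param config a `SimulationConfig`.
#' @export
write_simulation_config <- function(config, path) {
  a <- config$stage_spectra
  spectra <- lapply(dimnames(a)[[1]], function(st) {
    l <- lapply(dimnames(a)[[2]], function(bd) as.list(a[st, bd, ]))
    names(l) <- dimnames(a)[[2]]
    l
  })
  names(spectra) <- dimnames(a)[[1]]
  y <- list(duration = config$duration,
            sampling_rate = config$sampling_rate,
            montage = as.list(config$montage),
            transition_matrix =
              lapply(seq_len(7), function(i)
                as.list(unname(config$transition_matrix[i, ]))),
            initial_distribution = as.list(config$initial_distribution),
            stage_spectra = spectra,
            sem_rate = config$sem_rate, blink_rate = config$blink_rate,
            artifact_rate = config$artifact_rate,
            heart_rate = config$heart_rate,
            background_rms = config$background_rms,
            eog_leakage = config$eog_leakage,
            seed = config$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Stationary distribution of a stage transition matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized
#' to a probability vector. Used as the analytic reference for trajectory
#' frequencies.
#'
#' @param transition_matrix row-stochastic matrix.
#' @return named probability vector over the stages.
#' @export
stationary_distribution <- function(transition_matrix) {
  e <- eigen(t(transition_matrix))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-9))
    stop("no non-negative stationary vector; is the matrix stochastic?")
  v[v < 0] <- 0
  stats::setNames(v / sum(v), rownames(transition_matrix))
}
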