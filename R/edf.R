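# Minimal EDF (European Data Format) writer/reader: fixed-layout ASCII
# header plus 16-bit little-endian samples, one data record per second.
# Physical range is fixed at +/-3276.8 uV so one digital step is 0.1 uV.

edf_phys_max <- 3276.8

pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

#' Write a recording (and its ground truth) to disk
#'
#' Writes an EDF file with physical units uV and, when a ground truth is
#' supplied, a sidecar TSV (`<base>_stages.tsv`) holding one row per second
#' with the true stage and an artifact flag. Signals are quantized to the
#' 16-bit EDF grid (+/-3276.8 uV physical range, 0.1 uV per step); a
#' trailing partial second, if any, is dropped.
#'
#' @param recording a [recording()].
#' @param ground_truth optional ground truth from [synthesize_recording()].
#' @param path output EDF file path.
#' @return invisibly, the paths written.
#' @export
write_recording <- function(recording, ground_truth = NULL, path) {
  fs <- recording$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) stop("sampling rate must be integer Hz")
  fs <- as.integer(round(fs))
  ns <- length(recording$channel_labels)
  if (nrow(recording$signals) != ns)
    stop("channel count mismatch between signals and labels")
  n_rec <- ncol(recording$signals) %/% fs

  con <- tryCatch(suppressWarnings(file(path, "wb")),
                  error = function(e)
                    stop("cannot open '", path, "' for writing"))
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("X", 80), pad("vigileeg synthetic", 80),
    pad("01.01.26", 8), pad("00.00.00", 8),
    pad(256 * (ns + 1), 8), pad("", 44),
    pad(n_rec, 8), pad(1, 8), pad(ns, 4),
    paste(pad(recording$channel_labels, 16), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(rep(pad(-edf_phys_max, 8), ns), collapse = ""),
    paste(rep(pad(edf_phys_max, 8), ns), collapse = ""),
    paste(rep(pad(-32768, 8), ns), collapse = ""),
    paste(rep(pad(32767, 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(fs, 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)

  scale <- 65535 / (2 * edf_phys_max)
  for (r in seq_len(n_rec)) {
    block <- recording$signals[, ((r - 1) * fs + 1):(r * fs), drop = FALSE]
    d <- round(block * scale)
    d[d > 32767] <- 32767
    d[d < -32768] <- -32768
    writeBin(as.integer(t(d)), con, size = 2, endian = "little")
  }

  paths <- path
  if (!is.null(ground_truth)) {
    side <- stage_sidecar_path(path)
    labs <- ground_truth$stage_labels
    if (length(labs) != n_rec)
      stop("ground truth has ", length(labs), " seconds but the recording ",
           "holds ", n_rec)
    utils::write.table(
      data.frame(second = seq_len(n_rec), stage = labs,
                 artifact = as.integer(seq_len(n_rec) %in%
                                         ground_truth$artifact_seconds)),
      side, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, side)
  }
  invisible(paths)
}

stage_sidecar_path <- function(path)
  paste0(sub("\\.edf$", "", path, ignore.case = TRUE), "_stages.tsv")

#' Read an EDF recording written by [write_recording()]
#'
#' @param path EDF file path.
#' @return a [recording()] in physical units (uV).
#' @export
read_recording <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchar) trimws(readChar(con, nchar))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)            # transducer
  for (i in seq_len(ns)) rd(8)             # physical dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)            # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  sig <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      phys <- pmin[i] + (d - dmin[i]) * (pmax[i] - pmin[i]) /
        (dmax[i] - dmin[i])
      sig[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  recording(sig, spr[1] / rec_dur, labels)
}

#' Read a stage sidecar file
#'
#' @param path either the TSV path or the EDF path it accompanies.
#' @return data frame with columns `second`, `stage`, `artifact`.
#' @export
read_stage_sidecar <- function(path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE))
    path <- stage_sidecar_path(path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("integer", "character", "integer"))
}
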