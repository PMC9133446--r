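#' Per-second vigilance stage sequence
#'
#' Validated container for one recording's per-segment stage labels,
#' drawn from the 7-stage alphabet plus `ARTIFACT`.
#'
#' @param labels character vector of stage symbols.
#' @return object of class `StageSequence` (a classed character vector).
#' @export
#' @examples
#' stage_sequence(c("A1", "A1", "B2/3", "ARTIFACT"))
stage_sequence <- function(labels) {
  labels <- as.character(labels)
  bad <- which(!(labels %in% vigilance_stages(with_artifact = TRUE)))
  if (length(bad))
    stop(sprintf("invalid stage symbol '%s' at segment %d",
                 labels[bad[1]], bad[1]))
  structure(labels, class = "StageSequence")
}

#' @export
print.StageSequence <- function(x, ...) {
  cat(sprintf("<StageSequence> %d segments\n", length(x)))
  print(table(factor(unclass(x),
                     levels = vigilance_stages(with_artifact = TRUE))))
  invisible(x)
}

artifact_free_labels <- function(seq) {
  labs <- unclass(seq)
  labs[labs != "ARTIFACT"]
}

#' Relative stage occurrence
#'
#' Fraction of artifact-free segments spent in each stage: the number of
#' segments of one stage divided by the number of all artifact-free
#' segments. `ARTIFACT` segments enter neither numerator nor denominator.
#'
#' @param seq a [stage_sequence()].
#' @return named numeric vector over the 7 stages, summing to 1.
#' @export
relative_occurrence <- function(seq) {
  labs <- artifact_free_labels(seq)
  if (!length(labs))
    stop("no artifact-free segments: occurrence undefined")
  tab <- table(factor(labs, levels = vigilance_stages()))
  stats::setNames(as.numeric(tab) / length(labs), vigilance_stages())
}

#' Mean vigilance level
#'
#' Arithmetic mean of the numeric stage values ([stage_values()]:
#' 0 -> 7 down to C -> 1) over all artifact-free segments. Higher values
#' mean higher arousal.
#'
#' @param seq a [stage_sequence()].
#' @return value in \[1, 7\].
#' @export
mean_vigilance <- function(seq) {
  labs <- artifact_free_labels(seq)
  if (!length(labs))
    stop("no artifact-free segments: mean vigilance undefined")
  mean(stage_values()[labs])
}

#' Sliding 1-min interval labels
#'
#' Labels every 60-s sliding interval (interval 1 covers segments 1--60,
#' interval 2 segments 2--61, and so on) with its modal stage among
#' artifact-free segments; ties break toward the drowsier stage (the lower
#' numeric value). Intervals with fewer than `min_scorable` artifact-free
#' segments are labelled `UNSCORABLE`.
#'
#' @param seq a [stage_sequence()] with at least 60 segments.
#' @param width interval width in segments (default 60).
#' @param min_scorable minimal artifact-free segments per interval.
#' @return character vector of length `length(seq) - width + 1`.
#' @export
interval_labels <- function(seq, width = 60, min_scorable = 30) {
  labs <- unclass(seq)
  N <- length(labs)
  if (N < width)
    stop("need at least ", width, " segments for interval labelling")
  # counts per stage via cumulative sums; stages ordered drowsiest-first
  # so that max.col's first-maximum rule implements the tie-break
  drowsy_first <- rev(vigilance_stages())
  ind <- outer(labs, drowsy_first, `==`) * 1L
  cs <- rbind(0L, apply(ind, 2, cumsum))
  n_int <- N - width + 1L
  counts <- cs[(width + 1L):(N + 1L), , drop = FALSE] -
    cs[1:n_int, , drop = FALSE]
  scorable <- rowSums(counts)
  win <- max.col(counts, ties.method = "first")
  out <- drowsy_first[win]
  out[scorable < min_scorable] <- "UNSCORABLE"
  out
}

#' Arousal stability index (1--8)
#'
#' Scores how early and how deeply vigilance declines over a recording,
#' after the standard scoring table: the timeline is split into three
#' equal-duration thirds ("first/second/last 10 min" of a 20-min + rest
#' recording; see Details), and the criteria are checked in ascending
#' score order with the first match returned --- 1/2/3 when at least one
#' third of the first/second/last part is B2/3, 4/5/6 the same for B1,
#' 7 when at least two thirds of the whole timeline is 0/A1/A2/A3, and 8
#' when more than two thirds is 0 or A1. Lower values mean earlier
#' arousal decline. When no criterion matches, rules 4--6 are retried
#' with B1 and B2/3 pooled; if still nothing matches the score is 7.
#'
#' @details By default the timeline unit is the sliding 1-min interval
#' label ([interval_labels()]); `unit = "segments"` evaluates the same
#' criteria on raw segment fractions. `windowing = "thirds"` (default)
#' splits the timeline into equal thirds; `windowing = "minutes"` uses
#' literal 10-min windows (for a 20-min recording the third window is
#' then empty and its criteria cannot fire). `order = "descending"`
#' checks the table from score 8 downwards instead.
#'
#' @param seq a [stage_sequence()] with >= 60 artifact-free segments.
#' @param order evaluation order of the scoring table.
#' @param windowing `"thirds"` or literal `"minutes"`.
#' @param unit `"intervals"` (1-min modal labels) or `"segments"`.
#' @param ... passed to [interval_labels()].
#' @return integer score in 1..8.
#' @export
arousal_stability_index <- function(seq,
                                    order = c("ascending", "descending"),
                                    windowing = c("thirds", "minutes"),
                                    unit = c("intervals", "segments"),
                                    ...) {
  order <- match.arg(order)
  windowing <- match.arg(windowing)
  unit <- match.arg(unit)
  labs <- unclass(seq)
  if (sum(labs != "ARTIFACT") < 60)
    stop("need at least 60 artifact-free segments for the stability index")

  if (unit == "intervals") {
    u <- interval_labels(seq, ...)
    pos_sec <- seq_along(u)            # interval start second
  } else {
    u <- labs
    u[u == "ARTIFACT"] <- "UNSCORABLE"
    pos_sec <- seq_along(u)
  }
  scorable <- u != "UNSCORABLE"
  if (!any(scorable))
    stop("all intervals are unscorable")

  if (windowing == "thirds") {
    third <- ceiling(3 * seq_along(u) / length(u))
  } else {
    third <- pmin(ceiling(pos_sec / 600), 3L)
  }
  frac_in <- function(set, window) {
    sel <- third == window & scorable
    if (!any(sel)) return(0)
    mean(u[sel] %in% set)
  }
  frac_all <- function(set) mean(u[scorable] %in% set)

  checks <- list(
    `1` = function() frac_in("B2/3", 1) >= 1 / 3,
    `2` = function() frac_in("B2/3", 2) >= 1 / 3,
    `3` = function() frac_in("B2/3", 3) >= 1 / 3,
    `4` = function() frac_in("B1", 1) >= 1 / 3,
    `5` = function() frac_in("B1", 2) >= 1 / 3,
    `6` = function() frac_in("B1", 3) >= 1 / 3,
    `7` = function() frac_all(c("0", "A1", "A2", "A3")) >= 2 / 3,
    `8` = function() frac_all(c("0", "A1")) > 2 / 3)
  ord <- if (order == "ascending") 1:8 else 8:1
  for (i in ord) if (checks[[as.character(i)]]()) return(i)
  # fallback: pooled B criteria in the same order direction
  pooled <- c("B1", "B2/3")
  pooled_scores <- if (order == "ascending") 4:6 else 6:4
  for (i in pooled_scores)
    if (frac_in(pooled, i - 3L) >= 1 / 3) return(i)
  7L
}

#' Summarize one recording's vigilance
#'
#' Bundles the three per-recording outcomes: relative stage occurrence,
#' mean vigilance level, and the arousal stability index, plus the
#' artifact-free segment count.
#'
#' @param seq a [stage_sequence()].
#' @param ... passed to [arousal_stability_index()].
#' @return object of class `VigilanceSummary`.
#' @export
vigilance_summary <- function(seq, ...) {
  occ <- relative_occurrence(seq)
  structure(
    list(occurrence = occ,
         mean_vigilance = mean_vigilance(seq),
         stability_index =
           tryCatch(arousal_stability_index(seq, ...),
                    error = function(e) NA_integer_),
         n_artifact_free = sum(unclass(seq) != "ARTIFACT")),
    class = "VigilanceSummary")
}

#' @export
print.VigilanceSummary <- function(x, ...) {
  cat("<VigilanceSummary>\n")
  cat("  occurrence:",
      paste(sprintf("%s=%.3f", names(x$occurrence), x$occurrence),
            collapse = " "), "\n")
  cat(sprintf("  mean vigilance: %.3f\n", x$mean_vigilance))
  cat(sprintf("  stability index: %s\n", x$stability_index))
  cat(sprintf("  artifact-free segments: %d\n", x$n_artifact_free))
  invisible(x)
}

#' Write per-recording summaries as CSV
#'
#' One row per recording: the seven occurrence fractions, mean vigilance,
#' stability index and artifact-free count.
#'
#' @param summaries named list of `VigilanceSummary` objects.
#' @param path output CSV path.
#' @export
write_summary_csv <- function(summaries, path) {
  rows <- lapply(names(summaries), function(id) {
    s <- summaries[[id]]
    df <- as.data.frame(as.list(s$occurrence), check.names = FALSE)
    names(df) <- paste0("occ_", c("0", "A1", "A2", "A3", "B1", "B23", "C"))
    cbind(data.frame(recording = id), df,
          data.frame(mean_vigilance = s$mean_vigilance,
                     stability_index = s$stability_index,
                     n_artifact_free = s$n_artifact_free))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
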