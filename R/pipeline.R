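# End-to-end study pipeline: simulate a 2-group (BLT vs TAU) pre/post
# cohort, stage every recording, summarize vigilance, and run the
# statistical battery into a Table-2-shaped report.

# blend the base transition matrix toward an "aroused" (more 0/A1) or
# "drowsy" (more B) target row profile; w in [-1, 1]
tilt_transition_matrix <- function(P, w) {
  w <- max(-0.95, min(0.95, w))
  if (w == 0) return(P)
  q_up <- c(.20, .65, .08, .04, .03, 0, 0)
  q_down <- c(0, .05, .05, .10, .25, .55, 0)
  q <- if (w > 0) q_up else q_down
  (1 - abs(w)) * P + abs(w) * matrix(q, nrow = 7, ncol = 7, byrow = TRUE)
}

#' Configuration of a simulated pre/post two-group study
#'
#' Describes the cohort (group sizes, recording length), the
#' between-participant heterogeneity of baseline arousal, the treatment
#' effects (expressed as a tilt of the stage transition matrix toward
#' wakeful stages), the depression-score model, and the fidelity level
#' at which recordings are produced.
#'
#' @param n_blt,n_tau analyzed group sizes (defaults 9 and 10).
#' @param duration recording length in seconds.
#' @param baseline_tilt_sd SD of the per-participant baseline arousal
#'   tilt (0 disables heterogeneity).
#' @param blt_effect,tau_effect mean post-pre arousal tilt added by each
#'   arm (positive = more aroused after treatment).
#' @param response_sd SD of the individual response around the arm mean.
#' @param bdi_mean,bdi_sd,bdi_change_mean,bdi_change_sd BDI-II score
#'   model: baseline truncated-normal mean/SD (bounds 0--63) and the
#'   pre-to-post change distribution.
#' @param bdi_b23_r target correlation between the post BDI-II score and
#'   post B2/3 occurrence (0 disables the coupling).
#' @param level `"stages"` scores the latent trajectories directly;
#'   `"eeg"` synthesizes signals and runs the full preprocessing and
#'   classification chain per recording.
#' @param sim a [simulation_config()] template for the generator.
#' @param seed master seed; all per-recording seeds derive from it.
#' @return object of class `StudyConfig`.
#' @export
study_config <- function(n_blt = 9, n_tau = 10, duration = 1200,
                         baseline_tilt_sd = 0.25,
                         blt_effect = 0.28, tau_effect = 0.08,
                         response_sd = 0.17,
                         bdi_mean = 31.53, bdi_sd = 10.98,
                         bdi_change_mean = -6, bdi_change_sd = 6,
                         bdi_b23_r = 0,
                         level = c("stages", "eeg"),
                         sim = simulation_config(duration = duration),
                         seed = 1) {
  level <- match.arg(level)
  if (n_blt < 2 || n_tau < 2)
    stop("each group needs at least 2 participants")
  structure(
    list(n_blt = n_blt, n_tau = n_tau, duration = duration,
         baseline_tilt_sd = baseline_tilt_sd,
         blt_effect = blt_effect, tau_effect = tau_effect,
         response_sd = response_sd,
         bdi_mean = bdi_mean, bdi_sd = bdi_sd,
         bdi_change_mean = bdi_change_mean,
         bdi_change_sd = bdi_change_sd, bdi_b23_r = bdi_b23_r,
         level = level, sim = sim, seed = seed),
    class = "StudyConfig")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# one recording at the configured fidelity level -> VigilanceSummary
simulate_summary <- function(config, tilt, seed) {
  sim <- config$sim
  sim$transition_matrix <-
    tilt_transition_matrix(sim$transition_matrix, tilt)
  sim$duration <- config$duration
  sim$seed <- seed
  if (config$level == "stages") {
    seq <- stage_sequence(sample_stage_trajectory(sim))
    vigilance_summary(seq)
  } else {
    out <- simulate_recording(sim)
    pp <- preprocess_recording(out$recording,
                               ica = sim$eog_leakage > 0)
    seq <- classify_recording(pp$recording, pp$segments)
    vigilance_summary(seq)
  }
}

#' Run one simulated study end to end
#'
#' Simulates pre and post recordings for every participant of both arms,
#' stages and summarizes each recording, draws BDI-II scores, and runs
#' the full statistical battery. Fully reproducible from the
#' configuration and its seed.
#'
#' @param config a [study_config()].
#' @return object of class `StudyResult`: `participants` (long data
#'   frame, one row per participant and timepoint), `stats` (the
#'   [analyze_study()] report) and the configuration.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "StudyConfig"))
  set.seed(config$seed)
  n <- config$n_blt + config$n_tau
  seeds <- sample.int(.Machine$integer.max - 1L, 2 * n)
  group <- c(rep("BLT", config$n_blt), rep("TAU", config$n_tau))
  base_tilt <- stats::rnorm(n, 0, config$baseline_tilt_sd)
  effect <- ifelse(group == "BLT", config$blt_effect, config$tau_effect)
  post_tilt <- base_tilt + effect + stats::rnorm(n, 0, config$response_sd)
  bdi_pre <- round(rtrunc_norm(n, config$bdi_mean, config$bdi_sd, 0, 63))
  bdi_post <- round(pmin(63, pmax(0, bdi_pre +
    stats::rnorm(n, config$bdi_change_mean, config$bdi_change_sd))))

  rows <- list()
  for (i in seq_len(n)) {
    for (tp in c("pre", "post")) {
      tilt <- if (tp == "pre") base_tilt[i] else post_tilt[i]
      seed_i <- seeds[2 * (i - 1) + (tp == "post") + 1L]
      s <- simulate_summary(config, tilt, seed_i)
      rows[[length(rows) + 1]] <- data.frame(
        id = sprintf("P%02d", i), group = group[i], time = tp,
        bdi = if (tp == "pre") bdi_pre[i] else bdi_post[i],
        A1 = s$occurrence[["A1"]], B23 = s$occurrence[["B2/3"]],
        occ_0 = s$occurrence[["0"]], occ_A2 = s$occurrence[["A2"]],
        occ_A3 = s$occurrence[["A3"]], occ_B1 = s$occurrence[["B1"]],
        occ_C = s$occurrence[["C"]],
        mean_vigilance = s$mean_vigilance,
        stability = s$stability_index,
        n_artifact_free = s$n_artifact_free)
    }
  }
  participants <- do.call(rbind, rows)

  # optional coupling of the post BDI score to post B2/3 occurrence
  if (config$bdi_b23_r != 0) {
    post <- participants$time == "post"
    b23 <- participants$B23[post]
    z <- scale(b23)[, 1]
    r <- config$bdi_b23_r
    eps <- stats::rnorm(sum(post))
    bdi <- config$bdi_mean + config$bdi_change_mean +
      config$bdi_sd * (r * z + sqrt(1 - r^2) * scale(eps)[, 1])
    participants$bdi[post] <- round(pmin(63, pmax(0, bdi)))
  }

  structure(list(participants = participants,
                 stats = analyze_study(participants),
                 config = config),
            class = "StudyResult")
}

#' Statistical battery on a participant table
#'
#' Reproduces the study's analysis plan on a long participant table (one
#' row per participant and timepoint, columns `id`, `group`, `time`,
#' `bdi`, `A1`, `B23`, `mean_vigilance`, `stability`): per-group paired
#' t-tests on the pre-post differences of A1, B2/3 and mean vigilance;
#' 2x2 mixed ANOVAs; baseline two-sample t-tests with equivalence
#' verdicts against the design's minimal detectable effect size;
#' Wilcoxon signed-rank tests on stability per group; a group-by-change
#' chi-square on binned stability differences; and Pearson correlations
#' of the BDI-II score with B2/3 occurrence and mean vigilance at each
#' timepoint.
#'
#' @param participants long participant data frame as in [run_study()].
#' @return object of class `StatsReport` (nested list of `vig_test`s
#'   plus descriptives).
#' @export
analyze_study <- function(participants) {
  p <- participants
  pre <- p[p$time == "pre", ]
  post <- p[p$time == "post", ]
  post <- post[match(pre$id, post$id), ]
  outcomes <- c(A1 = "A1", B23 = "B23",
                mean_vigilance = "mean_vigilance")

  paired <- list()
  for (g in c("BLT", "TAU")) {
    sel <- pre$group == g
    paired[[g]] <- lapply(outcomes, function(oc)
      paired_t(pre[[oc]][sel] - post[[oc]][sel]))
  }

  anova <- lapply(outcomes, function(oc) mixed_anova_2x2(p, oc))

  sesoi <- mde_t("two_sample", n1 = sum(pre$group == "BLT"),
                 n2 = sum(pre$group == "TAU"))
  baseline <- lapply(outcomes, function(oc)
    equivalence_check(pre[[oc]][pre$group == "BLT"],
                      pre[[oc]][pre$group == "TAU"], sesoi))

  stab_diff <- post$stability - pre$stability
  wilcoxon <- lapply(c(BLT = "BLT", TAU = "TAU"), function(g)
    tryCatch(wilcoxon_signed_rank(stab_diff[pre$group == g]),
             error = function(e) NULL))
  bins <- cut(stab_diff, breaks = c(-Inf, -2, -1, 0, 1, Inf))
  tab <- table(pre$group, bins)
  chisq <- if (all(dim(tab) >= 2)) chi_square_crosstab(tab) else NULL

  correlations <- list(
    bdi_b23_pre = pearson_r(pre$bdi, pre$B23),
    bdi_b23_post = pearson_r(post$bdi, post$B23),
    bdi_meanvig_post = pearson_r(post$bdi, post$mean_vigilance),
    dbdi_dmeanvig = pearson_r(post$bdi - pre$bdi,
                              post$mean_vigilance - pre$mean_vigilance))

  desc <- do.call(rbind, lapply(c("BLT", "TAU"), function(g)
    do.call(rbind, lapply(c("pre", "post"), function(tp) {
      sel <- p$group == g & p$time == tp
      data.frame(group = g, time = tp,
                 A1_mean = mean(p$A1[sel]), A1_sd = stats::sd(p$A1[sel]),
                 B23_mean = mean(p$B23[sel]),
                 B23_sd = stats::sd(p$B23[sel]),
                 mv_mean = mean(p$mean_vigilance[sel]),
                 mv_sd = stats::sd(p$mean_vigilance[sel]))
    }))))

  structure(list(paired = paired, anova = anova, baseline = baseline,
                 wilcoxon = wilcoxon, chisq = chisq,
                 correlations = correlations, descriptives = desc,
                 sesoi = sesoi),
            class = "StatsReport")
}

fmt3 <- function(x) formatC(x, format = "f", digits = 3)

#' Render a stats report as text
#'
#' Deterministic fixed-width rendering of the three report blocks
#' (paired tests, ANOVA, descriptives) plus baseline equivalence,
#' stability tests and correlations, all numbers at 3 decimals.
#'
#' @param report a `StatsReport` (or a `StudyResult`).
#' @param path optional file to write to.
#' @return the report lines, invisibly when writing to a file.
#' @export
report_text <- function(report, path = NULL) {
  if (inherits(report, "StudyResult")) report <- report$stats
  L <- character(0)
  add <- function(...) L <<- c(L, paste0(...))
  add("== Paired t-tests (pre - post) ==")
  if (length(report$paired)) {
    add(sprintf("%-5s %-15s %8s %8s %8s %8s %8s",
                "group", "measure", "mean", "sd", "t", "p", "dz"))
    for (g in names(report$paired))
      for (m in names(report$paired[[g]])) {
        r <- report$paired[[g]][[m]]
        add(sprintf("%-5s %-15s %8s %8s %8s %8s %8s", g, m,
                    fmt3(r$mean), fmt3(r$sd), fmt3(r$statistic),
                    fmt3(r$p.value), fmt3(r$effect_size)))
      }
  }
  add("", "== Mixed ANOVA (time, time x group) ==")
  for (m in names(report$anova)) {
    a <- report$anova[[m]]
    add(sprintf("%-15s time: F(%d,%d)=%s p=%s d=%s | time*group: F(%d,%d)=%s p=%s d=%s",
                m, a$time$df[1], a$time$df[2], fmt3(a$time$statistic),
                fmt3(a$time$p.value), fmt3(a$time$effect_size),
                a$time_group$df[1], a$time_group$df[2],
                fmt3(a$time_group$statistic),
                fmt3(a$time_group$p.value),
                fmt3(a$time_group$effect_size)))
  }
  if (!is.null(report$baseline)) {
    add("", sprintf("== Baseline equivalence (SESOI d = %s) ==",
                    fmt3(report$sesoi)))
    for (m in names(report$baseline)) {
      b <- report$baseline[[m]]
      add(sprintf("%-15s d=%s CI [%s, %s] -> %s", m, fmt3(b$d),
                  fmt3(b$ci[1]), fmt3(b$ci[2]),
                  if (b$equivalent) "EQUIVALENT" else "not equivalent"))
    }
  }
  if (length(report$wilcoxon)) {
    add("", "== Vigilance stability ==")
    for (g in names(report$wilcoxon)) {
      w <- report$wilcoxon[[g]]
      if (!is.null(w))
        add(sprintf("%-5s Wilcoxon Z=%s p=%s r=%s", g,
                    fmt3(w$statistic), fmt3(w$p.value),
                    fmt3(w$effect_size)))
    }
    if (!is.null(report$chisq))
      add(sprintf("group chi-square(%d)=%s p=%s w=%s",
                  report$chisq$df, fmt3(report$chisq$statistic),
                  fmt3(report$chisq$p.value),
                  fmt3(report$chisq$effect_size)))
  }
  if (length(report$correlations)) {
    add("", "== BDI-II correlations ==")
    for (m in names(report$correlations)) {
      r <- report$correlations[[m]]
      add(sprintf("%-18s r=%s p=%s", m, fmt3(r$effect_size),
                  fmt3(r$p.value)))
    }
  }
  add("", "== Descriptives ==")
  d <- report$descriptives
  add(sprintf("%-5s %-5s %8s %8s %8s %8s %8s %8s",
              "group", "time", "A1", "sd", "B23", "sd", "meanvig", "sd"))
  if (is.null(d)) d <- data.frame()
  for (i in seq_len(nrow(d)))
    add(sprintf("%-5s %-5s %8s %8s %8s %8s %8s %8s",
                d$group[i], d$time[i], fmt3(d$A1_mean[i]),
                fmt3(d$A1_sd[i]), fmt3(d$B23_mean[i]), fmt3(d$B23_sd[i]),
                fmt3(d$mv_mean[i]), fmt3(d$mv_sd[i])))
  if (!is.null(path)) {
    writeLines(L, path)
    return(invisible(L))
  }
  L
}

#' Write a stats report as CSV
#'
#' Flat CSV with one row per test: block, group/measure, statistic, df,
#' p, effect size.
#'
#' @param report a `StatsReport` or `StudyResult`.
#' @param path output CSV path.
#' @export
report_csv <- function(report, path) {
  if (inherits(report, "StudyResult")) report <- report$stats
  rows <- list()
  push <- function(block, label, r) {
    if (is.null(r)) return()
    rows[[length(rows) + 1]] <<- data.frame(
      block = block, label = label, statistic = r$statistic,
      df = paste(round(r$df, 2), collapse = ";"), p = r$p.value,
      effect = r$effect_size, effect_type = r$effect_type)
  }
  for (g in names(report$paired))
    for (m in names(report$paired[[g]]))
      push("paired_t", paste(g, m), report$paired[[g]][[m]])
  for (m in names(report$anova)) {
    push("anova_time", m, report$anova[[m]]$time)
    push("anova_time_group", m, report$anova[[m]]$time_group)
  }
  for (g in names(report$wilcoxon))
    push("wilcoxon", g, report$wilcoxon[[g]])
  push("chisq", "stability", report$chisq)
  for (m in names(report$correlations))
    push("correlation", m, report$correlations[[m]])
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.StudyResult <- function(x, ...) {
  writeLines(report_text(x$stats))
  invisible(x)
}
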