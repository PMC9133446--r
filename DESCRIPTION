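Package: vigileeg
Title: Resting-State EEG Vigilance Staging and Arousal Stability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying brain arousal regulation in resting-state
    EEG. Provides a synthetic multichannel EEG generator with a known latent
    vigilance trajectory, the standard preprocessing chain (zero-phase
    Butterworth band-pass and notch filtering, 1-s segmentation, automated
    artifact screening, ICA-based removal of stereotyped ocular and cardiac
    artifacts, sleep-graphoelement screening), a sensor-space vigilance
    classifier assigning stages 0, A1, A2, A3, B1, B2/3 and C to every
    artifact-free second, per-recording vigilance metrics (relative stage
    occurrence, mean vigilance level, the 1-8 arousal stability index), and
    the statistical battery of a pre/post two-group clinical design:
    paired and two-sample t-tests, exact noncentral-t minimal detectable
    effect sizes, equivalence tests against a smallest effect size of
    interest, 2x2 mixed ANOVA, Wilcoxon signed-rank, chi-square crosstabs
    and Pearson correlations, plus an end-to-end simulation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
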