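#!/usr/bin/env Rscript

# Stage 1 — simulate the study cohorts.
#
# Two products:
#  * a volumes-only cohort at the validation-study size (33 controls /
#    39 PD) used by the statistical analyses in 03_stats.R, and
#  * a small imaged cohort (4 + 4 subjects, full 7-measurement phantom
#    series with ground truth) that 02_segment.R pushes through the image
#    pipeline.
#
# Everything is seeded; re-running reproduces identical files (see the
# manifest_*.json checksums).

suppressPackageStartupMessages(library(nmvolumetry))

seed <- 20230101L
dir.create("results", showWarnings = FALSE)

cfg_stats <- pipeline_config(output_dir = "results/cohort_stats",
                             seed = seed, images = FALSE)
tab <- run_simulate(cfg_stats)
cat(sprintf("volumes-only cohort: %d controls, %d PD\n",
            sum(tab$group == "control"), sum(tab$group == "pd")))
cat(sprintf("  SNc true volumes: control %.0f +/- %.0f, PD %.0f +/- %.0f mm^3\n",
            mean(tab$snc_volume_true[tab$group == "control"]),
            sd(tab$snc_volume_true[tab$group == "control"]),
            mean(tab$snc_volume_true[tab$group == "pd"]),
            sd(tab$snc_volume_true[tab$group == "pd"])))

cfg_img <- pipeline_config(output_dir = "results/cohort_imaged",
                           seed = seed + 1L, images = TRUE,
                           cohort = list(n_control = 4, n_pd = 4))
tab2 <- run_simulate(cfg_img)
cat(sprintf("imaged cohort: %d subjects written under %s\n",
            nrow(tab2), cfg_img$output_dir))
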