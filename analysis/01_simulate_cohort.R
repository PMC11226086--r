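#!/usr/bin/env Rscript

# Stage 1: generate the default synthetic cohort (11 controls, 6 UWS, 12 MCS
# training subjects and 5 conscious-drawn holdout subjects) and store it
# under results/cohort so later stages and reruns share identical data.
#
# Usage: Rscript analysis/01_simulate_cohort.R [seed]

suppressPackageStartupMessages(library(specdcm))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

cfg <- cohort_config()
cohort <- make_cohort(cfg, seed = seed)
print(cohort)

dir.create("results", showWarnings = FALSE)
path <- file.path("results", "cohort")
write_cohort(cohort, path)
cat("cohort written to", path, "\n")
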