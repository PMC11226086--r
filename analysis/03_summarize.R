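#!/usr/bin/env Rscript

# Stage 3: condense the report tables into the headline summary tables —
# which connections survive the strict posterior-probability threshold per
# contrast, classification (balanced) accuracies per edge subset, and the
# holdout assignment table. Writes results/summary_*.csv.
#
# Usage: Rscript analysis/03_summarize.R

suppressPackageStartupMessages(library(specdcm))

report_dir <- file.path("results", "report")
if (!dir.exists(report_dir)) {
  stop("no report tables; run analysis/02_run_pipeline.R first")
}

bma_tab <- read.csv(file.path(report_dir, "bma_effects.csv"))
cv_tab <- read.csv(file.path(report_dir, "losocv_pp.csv"))
state_tab <- read.csv(file.path(report_dir, "state_pp.csv"),
                      check.names = FALSE)

# group differences surviving the strict > .99 probability threshold
labels <- paste0(default_dmn()$edges$source, "->", default_dmn()$edges$target)
diffs <- bma_tab[bma_tab$covariate == "group", ]
diffs$connection <- labels[diffs$edge_index]
effects <- diffs[order(diffs$contrast, -diffs$pp),
                 c("contrast", "connection", "effect", "pp", "retained")]
write.csv(effects, file.path("results", "summary_effects.csv"),
          row.names = FALSE)
cat("retained group differences (pp > .99):\n")
print(effects[effects$retained, ], row.names = FALSE, digits = 3)

# classification accuracy by contrast and edge subset
acc <- unique(cv_tab[, c("contrast", "subset", "balanced_accuracy")])
write.csv(acc, file.path("results", "summary_accuracy.csv"),
          row.names = FALSE)
cat("\nbalanced LOSOCV accuracy:\n")
print(acc, row.names = FALSE, digits = 3)

# holdout (leave-one-state-out) assignments
write.csv(state_tab, file.path("results", "summary_holdout.csv"),
          row.names = FALSE)
cat("\nholdout assignments:\n")
print(state_tab, row.names = FALSE, digits = 3)
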