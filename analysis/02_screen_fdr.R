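#!/usr/bin/env Rscript
# Step 2: harmonize every pair, run the primary random-effects IVW screen,
# and apply Benjamini-Hochberg FDR (q < 0.05) across the batch. Retained
# pairs also get MR-Egger, weighted median and weighted mode plus the
# sensitivity battery. Writes the forest table (per-study effect, 95% CI,
# p, q) that a forest plot would be drawn from.

library(mrweb)

studies <- "results/studies"
truth <- read.delim(file.path(studies, "truth.tsv"))
cand <- lapply(truth$pair, function(i) list(
  exposure = file.path(studies, sprintf("exposure_%02d.tsv", i)),
  outcome = file.path(studies, sprintf("outcome_%02d.tsv", i)),
  exposure_id = sprintf("chronotype_sim_%02d", i),
  outcome_id = sprintf("trait_%02d", i)
))

res <- screen_and_analyze(cand, pipeline_config(
  screen_p = 1,          # all pairs enter the FDR stage
  fdr_threshold = 0.05,
  methods = c("ivw_re", "egger", "median_weighted", "mode_weighted"),
  n_boot = 200, seed = 2021
))

write.table(res$forest, "results/forest_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sig <- res$forest[res$forest$significant, ]
cat(sprintf("%d/%d pairs FDR-significant at q < 0.05\n",
            nrow(sig), nrow(res$forest)))
flagged <- as.integer(sub(".*_", "", sig$exposure_id))
cat(sprintf("true-effect pairs recovered: %d/%d; false flags: %d\n",
            sum(flagged %in% truth$pair[truth$theta != 0]),
            sum(truth$theta != 0),
            sum(!flagged %in% truth$pair[truth$theta != 0])))
cat("forest table -> results/forest_table.tsv\n")
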