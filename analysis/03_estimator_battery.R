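#!/usr/bin/env Rscript
# Step 3: per-pair deep dive for the FDR-significant studies.
#
# For the first causal pair, rerun every estimator (fixed/random IVW,
# Egger, simple/weighted median, simple/weighted mode) with bootstrap SEs,
# and write a method-comparison table. Under no pleiotropy all methods
# should agree around theta = 0.3, with the robust estimators paying a
# power premium (wider intervals).

library(mrweb)

studies <- "results/studies"
h <- harmonize_studies(
  read_sumstats(file.path(studies, "exposure_01.tsv")),
  read_sumstats(file.path(studies, "outcome_01.tsv"))
)
cat(sprintf("pair 01: %d instruments kept, %d dropped\n",
            nrow(h$data), nrow(h$audit)))

ests <- mr_all(h, c("ivw_fe", "ivw_re", "egger", "median_simple",
                    "median_weighted", "mode_simple", "mode_weighted"),
               n_boot = 1000, seed = 2021)
tab <- do.call(rbind, lapply(ests, function(e) data.frame(
  method = e$method, n_snp = e$n_snp, theta = e$theta, se = e$se,
  ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
  egger_intercept = e$intercept, egger_intercept_pval = e$intercept_pval
)))
write.table(tab, "results/estimator_comparison.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(tab[c("method", "theta", "se", "pval")], row.names = FALSE, digits = 3)
cat("-> results/estimator_comparison.tsv\n")
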