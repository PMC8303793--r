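#!/usr/bin/env Rscript
# Step 1: generate the study battery.
#
# Emulates the situation the pipeline is built for: a set of candidate
# exposure/outcome study pairs of which a minority carry a real causal
# effect, each delivered as two-sample GWAS summary statistics with the
# usual allele-level mess (strand flips, palindromic SNPs). Five pairs get
# theta = 0.3, fifteen are null; J = 30 instruments, n = 100,000 per study.
# Writes the studies in the native TSV dialect plus a ground-truth table.

library(mrweb)

out_dir <- "results/studies"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

n_true <- 5; n_null <- 15
truth <- data.frame()
for (i in seq_len(n_true + n_null)) {
  theta <- if (i <= n_true) 0.3 else 0
  s <- simulate_two_sample(sim_config(
    n_snps = 30, theta = theta, n_exposure = 1e5, n_outcome = 1e5,
    frac_flipped = 0.2, frac_palindromic = 0.1, seed = 20210700 + i
  ))
  write_sumstats(s$exposure, file.path(out_dir, sprintf("exposure_%02d.tsv", i)))
  write_sumstats(s$outcome, file.path(out_dir, sprintf("outcome_%02d.tsv", i)))
  truth <- rbind(truth, data.frame(pair = i, theta = theta))
}
write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("wrote %d study pairs (%d causal at theta = 0.3, %d null) to %s\n",
            n_true + n_null, n_true, n_null, out_dir))
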