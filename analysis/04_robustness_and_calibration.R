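#!/usr/bin/env Rscript
# Robustness diagnostics for the permutation machinery: PERMANOVA type-I
# error under the null and the unequal-variance (equal centroid) simulation.
suppressMessages(library(tridomain))

dir.create("results", showWarnings = FALSE)

uv <- unequal_variance_simulation(dispersion_ratios = c(1, 2, 4),
                                  n_reps = 300, n_perm = 199, seed = 99)
write.table(uv, "results/unequal_variance_rejection.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("PERMANOVA rejection rate at alpha = 0.05, equal centroids:\n")
for (i in seq_len(nrow(uv)))
  cat(sprintf("  dispersion ratio %g: %.3f (n_reps = %d)\n",
              uv$ratio[i], uv$rejection_rate[i], uv$n_reps[i]))
cat("ratio 1 is the type-I calibration; ratios 2 and 4 probe whether\n")
cat("dispersion differences alone (no location shift) inflate rejections.\n")
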