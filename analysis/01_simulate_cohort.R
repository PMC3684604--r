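#!/usr/bin/env Rscript
# Generate the default synthetic three-domain cohort (96 stool samples:
# bacterial/archaeal/fungal genus counts + usual/recent nutrient panels)
# and write every table under results/cohort/ for the downstream stages.
suppressMessages(library(tridomain))

seed <- 20130617 %% 10000  # fixed study seed for the worked analysis
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

coh <- generate_cohort(cohort_config(seed = seed))

for (dom in names(coh$counts)) {
  write_count_table(coh$counts[[dom]], file.path(out, paste0(dom, "_counts.tsv")),
                    params = list(seed = seed))
  write_taxonomy(coh$taxonomy[[dom]], file.path(out, paste0(dom, "_taxonomy.tsv")))
}
write_nutrient_table(coh$nutrients$usual, file.path(out, "nutrients_usual.csv"))
write_nutrient_table(coh$nutrients$recent, file.path(out, "nutrients_recent.csv"))
write.table(data.frame(sample = names(coh$truth$archaeal_state),
                       archaeal_state = coh$truth$archaeal_state),
            file.path(out, "truth_archaeal_state.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(nutrient = names(coh$truth$nutrient_block),
                       block = coh$truth$nutrient_block),
            file.path(out, "truth_nutrient_blocks.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(coh$truth$diet_effects, file.path(out, "truth_diet_effects.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

st <- table(coh$truth$archaeal_state)
cat(sprintf("cohort of %d samples written to %s\n", ncol(coh$counts$fungi), out))
cat(sprintf("archaeal states: %s\n",
            paste(names(st), st, sep = "=", collapse = ", ")))
cat(sprintf("fungal genera: %d, bacterial: %d, archaeal: %d\n",
            nrow(coh$counts$fungi), nrow(coh$counts$bacteria),
            nrow(coh$counts$archaea)))
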