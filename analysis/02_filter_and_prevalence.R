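#!/usr/bin/env Rscript
# Apply the survey inclusion rules (>=200 ITS reads per sample; genus in
# >=9 samples with >=10 total reads), compute within-amplicon proportions,
# and report the cohort's prevalence structure.
suppressMessages(library(tridomain))

cdir <- "results/cohort"
out <- "results/filtered"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- list(bacteria = read_count_table(file.path(cdir, "bacteria_counts.tsv"), "bacteria"),
               archaea = read_count_table(file.path(cdir, "archaea_counts.tsv"), "archaea"),
               fungi = read_count_table(file.path(cdir, "fungi_counts.tsv"), "fungi"))
fungi_tax <- read_taxonomy(file.path(cdir, "fungi_taxonomy.tsv"))

ps <- prevalence_summary(counts$archaea, counts$fungi, fungi_tax)
cat(sprintf("archaea-positive samples: %d/%d (%s: %d, %s: %d, both: %d)\n",
            ps$archaea_positive, ps$n_samples,
            "Methanobrevibacter", ps$methanobrevibacter_positive,
            "Nitrososphaera", ps$nitrososphaera_positive, ps$both_archaea))
cat(sprintf("fungal prevalence: Saccharomyces %.0f%%, Candida %.0f%%, Cladosporium %.0f%%\n",
            ps$saccharomyces_prevalence_pct, ps$candida_prevalence_pct,
            ps$cladosporium_prevalence_pct))
cat(sprintf("fungal genera in >=9 samples: %d; |rho|(Asco, Basidio) = %.3f\n",
            ps$fungal_genera_prevalence_ge_min, ps$asco_basidio_spearman_rho_abs))

for (dom in names(counts)) {
  min_reads <- if (dom == "fungi") 200 else 0
  dep <- filter_samples_by_depth(counts[[dom]], min_reads)
  gen <- filter_genera(dep$counts)
  cat(sprintf("%s: dropped %d samples (depth), %d genera (rarity); %d genera remain\n",
              dom, nrow(dep$report$dropped_samples),
              nrow(gen$report$dropped_genera), nrow(gen$counts)))
  write_count_table(gen$counts, file.path(out, paste0(dom, "_filtered.tsv")))
  pr <- to_proportions(gen$counts)
  write.table(data.frame(genus_id = rownames(pr), unclass(pr), check.names = FALSE),
              file.path(out, paste0(dom, "_proportions.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
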