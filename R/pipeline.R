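#' Prevalence and summary statistics of a three-domain genus survey
#'
#' Recomputes the headline descriptive numbers of a cross-domain stool
#' survey from genus-by-sample read-count tables: archaeal detection counts
#' (any archaeal read; per focal genus; co-occurrence of the two focal
#' genera), fungal genus prevalence percentages, the number of fungal
#' genera present in at least `min_prevalence` samples, and the Spearman
#' correlation between per-sample Ascomycota and Basidiomycota proportions.
#'
#' @param arch_counts archaeal [count_table()].
#' @param fungi_counts fungal [count_table()].
#' @param fungi_taxonomy fungal [taxonomy_table()] (phylum = first rank).
#' @param focal_archaea the two focal archaeal genus ids.
#' @param fungal_genera fungal genera whose prevalence percentage is
#'   reported.
#' @param min_prevalence prevalence cutoff for the genus count (default 9).
#' @return named list of summary numbers.
#' @export
prevalence_summary <- function(arch_counts, fungi_counts, fungi_taxonomy,
                               focal_archaea = c("Methanobrevibacter", "Nitrososphaera"),
                               fungal_genera = c("Saccharomyces", "Candida", "Cladosporium"),
                               min_prevalence = 9) {
  n <- ncol(fungi_counts)
  a <- unclass(arch_counts)
  mbb <- if (focal_archaea[1] %in% rownames(a)) a[focal_archaea[1], ] > 0 else rep(FALSE, ncol(a))
  nit <- if (focal_archaea[2] %in% rownames(a)) a[focal_archaea[2], ] > 0 else rep(FALSE, ncol(a))
  fprev <- rowSums(unclass(fungi_counts) > 0)
  props <- to_proportions(fungi_counts)
  phylum <- fungi_taxonomy[rownames(fungi_counts), 1]
  phy_prop <- rowsum(unclass(props), group = phylum)
  rho <- if (all(c("Ascomycota", "Basidiomycota") %in% rownames(phy_prop)))
    suppressWarnings(stats::cor(phy_prop["Ascomycota", ], phy_prop["Basidiomycota", ],
                                method = "spearman")) else NA_real_
  out <- list(
    n_samples = n,
    archaea_positive = sum(colSums(a) > 0),
    methanobrevibacter_positive = sum(mbb),
    nitrososphaera_positive = sum(nit),
    both_archaea = sum(mbb & nit),
    fungal_genera_prevalence_ge_min = sum(fprev >= min_prevalence),
    asco_basidio_spearman_rho_abs = abs(rho))
  for (g in fungal_genera)
    out[[paste0(tolower(g), "_prevalence_pct")]] <-
      if (g %in% rownames(fungi_counts)) 100 * sum(unclass(fungi_counts)[g, ] > 0) / n else NA_real_
  out
}

#' Pipeline parameter defaults
#'
#' @param min_reads_fungi ITS depth threshold (200; bacteria/archaea 0).
#' @param min_prevalence,min_total genus inclusion rules (9 samples, 10
#'   reads).
#' @param presence_threshold Dice presence cutoff (proportion 0.01).
#' @param alphas generalized-UniFrac exponent grid for the omnibus tests.
#' @param n_clusters nutrient clusters per inventory (20).
#' @param n_perm permutations for all PERMANOVA stages.
#' @param q FDR level for selections (0.25).
#' @param alpha_screen stage-1 diet screen threshold.
#' @param seed integer seed for every stochastic stage.
#' @return named list of parameters.
#' @export
pipeline_params <- function(min_reads_fungi = 200, min_prevalence = 9, min_total = 10,
                            presence_threshold = 0.01, alphas = c(0, 0.5, 1),
                            n_clusters = 20, n_perm = 999, q = 0.25,
                            alpha_screen = 0.05, seed = 1) {
  as.list(environment())
}

filter_domain <- function(counts, min_reads, min_prevalence, min_total) {
  dep <- filter_samples_by_depth(counts, min_reads)
  props_full <- to_proportions(dep$counts)
  gen <- filter_genera(dep$counts, min_prevalence, min_total)
  props <- subset_proportions(props_full, genus_ids(gen$counts))
  list(counts = gen$counts, props_full = props_full, props = props,
       reports = list(depth = dep$report, genera = gen$report))
}

#' Run the full cross-domain association pipeline
#'
#' Orchestrates the analysis graph on three genus count tables, their
#' taxonomies and two nutrient inventories: inclusion filters and
#' within-amplicon proportions; Dice co-occurrence with Ward ordering over
#' all three Domains; archaeal-status classification with Kruskal-Wallis /
#' z-score genus screens; fungal-bacterial Spearman correlations; taxonomy
#' trees with generalized UniFrac families and PermanovaG omnibus tests for
#' the Prevotella/Bacteroides ratio and the fungal phylum proportions
#' (weighted/unweighted post hoc); nutrient-cluster dimension reduction
#' with the PERMANOVA screen and post hoc diet associations; and genus
#' richness by archaeal status. Sample sets are aligned by id intersection
#' across tables; every dropped sample or genus is recorded with its
#' triggering rule in the run manifest.
#'
#' @param counts named list of [count_table()]s (`bacteria`, `archaea`,
#'   `fungi`).
#' @param taxonomy named list of [taxonomy_table()]s, same names.
#' @param nutrients list with `usual` and `recent` [nutrient_table()]s.
#' @param params a [pipeline_params()] list.
#' @param out_dir optional directory; when given, matrices and association
#'   tables are written as TSV with provenance headers plus a manifest.
#' @return nested list with all stage outputs and `manifest`.
#' @export
run_pipeline <- function(counts, taxonomy, nutrients, params = pipeline_params(),
                         out_dir = NULL) {
  t0 <- Sys.time()
  stopifnot(all(c("bacteria", "archaea", "fungi") %in% names(counts)))
  shared <- Reduce(intersect, lapply(counts, colnames))
  shared <- intersect(shared, rownames(nutrients$usual))
  shared <- intersect(shared, rownames(nutrients$recent))
  dropped_align <- lapply(counts, function(ct) setdiff(colnames(ct), shared))
  counts <- lapply(counts, function(ct)
    count_table(unclass(ct)[, shared, drop = FALSE], attr(ct, "domain")))

  # stage 1: filters + proportions (fungal ITS depth rule only)
  flt <- list(
    bacteria = filter_domain(counts$bacteria, 0, params$min_prevalence, params$min_total),
    archaea = filter_domain(counts$archaea, 0, params$min_prevalence, params$min_total),
    fungi = filter_domain(counts$fungi, params$min_reads_fungi,
                          params$min_prevalence, params$min_total))
  core <- Reduce(intersect, lapply(flt, function(f) colnames(f$props)))
  pr <- lapply(flt, function(f) subset_proportions(f$props, samples = core))

  # stage 2: archaeal status (full archaeal proportions, pre genus-filter)
  status <- classify_archaeal_status(
    subset_proportions(flt$archaea$props_full, samples = core))

  # stage 3: co-occurrence across all three Domains
  presence <- do.call(rbind, lapply(pr, presence_matrix,
                                    threshold = params$presence_threshold))
  dice <- dice_matrix(presence)
  dice_order <- dice_cluster_order(dice)

  # stage 4: taxonomy trees + UniFrac families
  trees <- lapply(names(pr), function(dom)
    taxonomy_to_tree(taxonomy_table(taxonomy[[dom]][rownames(pr[[dom]]), , drop = FALSE],
                                    colnames(taxonomy[[dom]]))))
  names(trees) <- names(pr)
  unifracs <- lapply(c("bacteria", "fungi"), function(dom) {
    fam <- lapply(params$alphas, function(a) generalized_unifrac(trees[[dom]], pr[[dom]], a))
    names(fam) <- paste0("gunifrac_a", params$alphas)
    fam$weighted <- fam[[paste0("gunifrac_a", 1)]]
    fam$unweighted <- unweighted_unifrac(trees[[dom]], pr[[dom]])
    fam
  })
  names(unifracs) <- c("bacteria", "fungi")
  gu_names <- paste0("gunifrac_a", params$alphas)

  # stage 5: archaeal-status genus screen + z-score heatmap matrices
  taxa_bf <- rbind(unclass(pr$fungi), unclass(pr$bacteria))
  kw_status <- do.call(rbind, lapply(rownames(taxa_bf), function(g)
    kruskal_wallis(taxa_bf[g, ], status, feature = g)))
  kw_status$q_bh <- stats::p.adjust(kw_status$p_raw, method = "BH")
  zsum <- group_zscore_summary(taxa_bf, status)

  # stage 6: fungal x bacterial Spearman matrix (one FDR family)
  sp_fb <- spearman_matrix(unclass(pr$fungi), unclass(pr$bacteria))

  # stage 7: P/B ratio and fungal-phylum PermanovaG + post hoc
  pb <- pb_ratio(subset_proportions(flt$bacteria$props_full, samples = core))
  pg_pb <- permanova_g(unifracs$fungi[gu_names], pb, n_perm = params$n_perm,
                       seed = params$seed)
  posthoc_pb <- lapply(c("weighted", "unweighted"), function(w)
    permanova(unifracs$fungi[[w]], pb, n_perm = params$n_perm, seed = params$seed,
              label = c(covariate = "pb_ratio", distance = paste0("fungi_", w))))
  names(posthoc_pb) <- c("weighted", "unweighted")

  fphy <- fungal_phylum_proportions(flt$fungi$props_full, taxonomy$fungi, core)
  pg_phyla <- lapply(rownames(fphy), function(ph)
    permanova_g(unifracs$bacteria[gu_names], fphy[ph, ], n_perm = params$n_perm,
                seed = params$seed))
  names(pg_phyla) <- rownames(fphy)
  posthoc_phyla <- lapply(rownames(fphy), function(ph) {
    out <- lapply(c("weighted", "unweighted"), function(w)
      permanova(unifracs$bacteria[[w]], fphy[ph, ], n_perm = params$n_perm,
                seed = params$seed,
                label = c(covariate = ph, distance = paste0("bacteria_", w))))
    names(out) <- c("weighted", "unweighted")
    out
  })
  names(posthoc_phyla) <- rownames(fphy)

  # stage 8: diet dimension reduction + screen + post hoc
  screen_dists <- c(list(fungi_weighted = unifracs$fungi$weighted,
                         fungi_unweighted = unifracs$fungi$unweighted,
                         bacteria_weighted = unifracs$bacteria$weighted,
                         bacteria_unweighted = unifracs$bacteria$unweighted))
  diet <- lapply(nutrients, function(nut) {
    ncm <- nutrient_cluster_measurements(
      nutrient_table(unclass(nut)[core, , drop = FALSE], attr(nut, "inventory")),
      n_clusters = params$n_clusters)
    res <- screen_and_posthoc(ncm, screen_dists, taxa_bf, status,
                              n_perm = params$n_perm, seed = params$seed,
                              q = params$q, alpha_screen = params$alpha_screen)
    c(list(ncm = ncm), res)
  })

  # stage 9: genus richness by archaeal status
  richness <- lapply(c("bacteria", "fungi"), function(dom)
    genus_richness(unclass(counts[[dom]])[, core, drop = FALSE]))
  names(richness) <- c("bacteria", "fungi")
  rich_kw <- lapply(names(richness), function(dom) {
    list(kw = kruskal_wallis(richness[[dom]], status, feature = paste0(dom, "_richness")),
         dunn = dunn_posthoc(richness[[dom]], status, feature = paste0(dom, "_richness")))
  })
  names(rich_kw) <- names(richness)

  manifest <- list(
    version = as.character(utils::packageVersion("tridomain")),
    params = params,
    n_samples_aligned = length(core),
    dropped_by_alignment = dropped_align,
    filter_reports = lapply(flt, function(f) f$reports),
    stages = c("align", "filter", "status", "cooccurrence", "unifrac",
               "status-screen", "spearman", "permanovag", "diet", "richness"),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  result <- list(samples = core, filtered = flt, proportions = pr, status = status,
                 dice = dice, dice_order = dice_order$order, trees = trees,
                 unifracs = unifracs, kw_status = kw_status, zscore_summary = zsum,
                 spearman_fb = sp_fb, pb_ratio = pb, permanovag_pb = pg_pb,
                 posthoc_pb = posthoc_pb, fungal_phyla = fphy,
                 permanovag_phyla = pg_phyla, posthoc_phyla = posthoc_phyla,
                 diet = diet, richness = richness, richness_tests = rich_kw,
                 manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

fungal_phylum_proportions <- function(fungi_props_full, fungi_tax, samples) {
  m <- unclass(fungi_props_full)[, samples, drop = FALSE]
  phylum <- fungi_tax[rownames(m), 1]
  ph <- rowsum(m, group = phylum)
  ph[intersect(c("Ascomycota", "Basidiomycota"), rownames(ph)), , drop = FALSE]
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_distance_matrix(result$dice, file.path(out_dir, "dice_matrix.tsv"))
  utils::write.table(result$kw_status, file.path(out_dir, "kw_archaeal_status.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$spearman_fb, file.path(out_dir, "spearman_fungi_bacteria.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(result$pb_ratio),
                                pb_ratio = result$pb_ratio,
                                status = as.character(result$status)),
                     file.path(out_dir, "sample_covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  zs <- result$zscore_summary
  utils::write.table(data.frame(feature = rownames(zs), zs, check.names = FALSE),
                     file.path(out_dir, "zscore_by_status.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (inv in names(result$diet)) {
    utils::write.table(result$diet[[inv]]$screen,
                       file.path(out_dir, paste0("diet_screen_", inv, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(result$diet[[inv]]$spearman,
                       file.path(out_dir, paste0("diet_spearman_", inv, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  mf <- result$manifest
  lines <- c(sprintf("version\t%s", mf$version),
             sprintf("n_samples_aligned\t%d", mf$n_samples_aligned),
             sprintf("elapsed_sec\t%.2f", mf$elapsed_sec),
             vapply(names(mf$params), function(p)
               sprintf("param:%s\t%s", p, paste(mf$params[[p]], collapse = ",")),
               character(1)))
  writeLines(lines, file.path(out_dir, "run_manifest.tsv"))
  invisible(out_dir)
}
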