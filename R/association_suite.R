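#' Presence/absence matrix from proportions
#'
#' A genus is scored present in a sample when its within-amplicon sequence
#' proportion is at least `threshold` (inclusive). Note that `threshold = 0`
#' marks everything present (0 >= 0); use a positive threshold for nonzero
#' detection.
#'
#' @param props a `proportion_table` or plain matrix of proportions.
#' @param threshold inclusive presence cutoff (default 0.01).
#' @return binary 0/1 genus x sample matrix.
#' @export
presence_matrix <- function(props, threshold = 0.01) {
  m <- (unclass(props) >= threshold) * 1L
  dimnames(m) <- dimnames(props)
  m
}

#' Dice co-occurrence index between genera
#'
#' `S(i,j) = 2 |A ∩ B| / (|A| + |B|)` where A and B are the sets of samples
#' in which genus i and genus j are present. The diagonal is 1; a pair of
#' never-present genera is assigned 0 by convention so the matrix stays
#' complete for clustering.
#'
#' @param presence binary genus x sample matrix (see [presence_matrix()]).
#' @return symmetric genus x genus similarity matrix in `[0, 1]`.
#' @export
dice_matrix <- function(presence) {
  m <- unclass(presence) * 1.0
  if (nrow(m) < 2) stop("need at least 2 genera")
  inter <- tcrossprod(m)
  sizes <- rowSums(m)
  den <- outer(sizes, sizes, "+")
  S <- ifelse(den > 0, 2 * inter / den, 0)
  diag(S) <- 1
  dimnames(S) <- list(rownames(presence), rownames(presence))
  S
}

#' Ward clustering order of genera from their Dice profiles
#'
#' Each genus is represented by its row of the Dice matrix (its
#' co-occurrence profile across all genera); genera are clustered by Ward's
#' criterion on the Euclidean distances between these profiles, as used to
#' order co-occurrence heatmaps.
#'
#' @param S symmetric Dice matrix from [dice_matrix()].
#' @return list with `order` (genus ids in dendrogram leaf order) and
#'   `hclust` (the merge tree).
#' @export
dice_cluster_order <- function(S) {
  if (nrow(S) < 2) stop("need at least 2 genera to cluster")
  hc <- stats::hclust(stats::dist(S, method = "euclidean"), method = "ward.D2")
  list(order = rownames(S)[hc$order], hclust = hc)
}

#' Classify samples by predominant archaeal lineage
#'
#' Each sample is labelled by which of the two focal archaeal genera it
#' carries; when both are present the predominant (more abundant) lineage
#' wins. Samples with neither genus are `"none"`. An exact tie is
#' unresolvable and yields `"none"` with a warning.
#'
#' @param arch_props archaeal `proportion_table`.
#' @param genera the two focal genus ids (default Methanobrevibacter and
#'   Nitrososphaera).
#' @return named factor of per-sample labels in
#'   `{genera[1], genera[2], "none"}`.
#' @export
classify_archaeal_status <- function(arch_props,
                                     genera = c("Methanobrevibacter", "Nitrososphaera")) {
  stopifnot(length(genera) == 2)
  m <- unclass(arch_props)
  pa <- if (genera[1] %in% rownames(m)) m[genera[1], ] else rep(0, ncol(m))
  pb <- if (genera[2] %in% rownames(m)) m[genera[2], ] else rep(0, ncol(m))
  lab <- rep("none", ncol(m))
  lab[pa > 0 & pa > pb] <- genera[1]
  lab[pb > 0 & pb > pa] <- genera[2]
  tie <- pa > 0 & pb > 0 & pa == pb
  if (any(tie)) {
    warning("exact archaeal abundance tie in samples ",
            paste(colnames(m)[tie], collapse = ", "), "; classified as 'none'")
    lab[tie] <- "none"
  }
  factor(stats::setNames(lab, colnames(m)), levels = c(genera, "none"))
}

association_result <- function(feature_a, feature_b, test, statistic, p_raw,
                               q_bh = NA_real_, n = NA_integer_) {
  data.frame(feature_a = feature_a, feature_b = feature_b, test = test,
             statistic = statistic, p_raw = p_raw, q_bh = q_bh, n = n,
             stringsAsFactors = FALSE)
}

#' Kruskal-Wallis rank test of one feature across groups
#'
#' Wraps the standard tie-corrected Kruskal-Wallis chi-square test. The
#' degenerate case where every value is identical (H is 0/0 under full
#' ties) is defined as H = 0, p = 1.
#'
#' @param values numeric per-sample vector.
#' @param groups group labels aligned with `values`.
#' @param feature feature name recorded in the result.
#' @return one-row association-result data frame (statistic = H).
#' @export
kruskal_wallis <- function(values, groups, feature = "feature") {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least 2 non-empty groups")
  if (any(table(groups) == 0)) stop("empty group after alignment")
  if (max(values) == min(values))
    return(association_result(feature, "groups", "kruskal-wallis", 0, 1,
                              n = length(values)))
  kt <- stats::kruskal.test(values, groups)
  association_result(feature, "groups", "kruskal-wallis",
                     unname(kt$statistic), kt$p.value, n = length(values))
}

#' Dunn's post hoc pairwise comparisons after Kruskal-Wallis
#'
#' For each group pair, `z = (mean rank difference) / SE` with the
#' tie-corrected standard error
#' `SE = sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`,
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups; two-sided normal
#' p-values, BH-adjusted across the pairs.
#'
#' @inheritParams kruskal_wallis
#' @return association-result data frame, one row per group pair
#'   (statistic = z).
#' @export
dunn_posthoc <- function(values, groups, feature = "feature") {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 non-empty groups")
  N <- length(values)
  r <- rank(values)
  tie_tab <- table(r)
  Tcorr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  mean_ranks <- tapply(r, groups, mean)
  n_g <- table(groups)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z <- if (se > 0) (mean_ranks[[a]] - mean_ranks[[b]]) / se else 0
    p <- if (se > 0) 2 * stats::pnorm(-abs(z)) else 1
    association_result(paste0(feature, ":", a), b, "dunn", z, p,
                       n = n_g[[a]] + n_g[[b]])
  })
  out <- do.call(rbind, res)
  out$q_bh <- stats::p.adjust(out$p_raw, method = "BH")
  out
}

spearman_test <- function(x, y) {
  n <- sum(stats::complete.cases(x, y))
  rho <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  if (is.na(rho)) return(list(rho = NA_real_, p = NA_real_, n = n))
  if (abs(rho) >= 1) return(list(rho = rho, p = if (n > 2) 0 else 1, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), n - 2), n = n)
}

#' All-pairs Spearman correlations between two feature tables
#'
#' Computes tie-handled (average-rank) Spearman rho for every pair of a row
#' feature of `x` and a row feature of `y`, with two-sided p-values from the
#' t approximation and BH q-values across the whole matrix (one FDR family
#' per call). Constant features yield undefined rho; these pairs are
#' returned flagged (`NA` statistic) and are excluded from the FDR family.
#'
#' @param x feature x sample matrix (e.g. fungal proportions).
#' @param y feature x sample matrix over the same samples (e.g. bacterial
#'   proportions, or nutrient-cluster scores transposed to cluster x sample).
#' @return association-result data frame, one row per feature pair.
#' @export
spearman_matrix <- function(x, y) {
  x <- unclass(x); y <- unclass(y)
  if (!identical(colnames(x), colnames(y)))
    stop("x and y must share the same sample set (same order)")
  rows <- vector("list", nrow(x) * nrow(y))
  k <- 0
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(nrow(y))) {
      st <- spearman_test(x[i, ], y[j, ])
      k <- k + 1
      rows[[k]] <- association_result(rownames(x)[i], rownames(y)[j], "spearman",
                                      st$rho, st$p, n = st$n)
    }
  }
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p_raw)
  out$q_bh[ok] <- stats::p.adjust(out$p_raw[ok], method = "BH")
  out
}

#' Benjamini-Hochberg q-values with significance tiers
#'
#' Step-up BH q-values plus the tier labelling used on association heatmaps:
#' findings at FDR 25, 20, 15 and 10% receive 1-4 asterisks.
#'
#' @param p_values numeric vector of raw p-values.
#' @param q FDR level for the selection mask (default 0.25).
#' @param tiers decreasing FDR levels defining the asterisk tiers.
#' @return data.frame with `p_raw`, `q_bh`, `selected` (q_bh <= q) and
#'   `tier` (number of asterisks, 0 if above all tiers).
#' @export
bh_fdr <- function(p_values, q = 0.25, tiers = c(0.25, 0.20, 0.15, 0.10)) {
  qv <- stats::p.adjust(p_values, method = "BH")
  tier <- vapply(qv, function(x) sum(x <= tiers), integer(1))
  data.frame(p_raw = p_values, q_bh = qv, selected = qv <= q, tier = tier)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test; the two-sided p-value sums the probabilities
#' of all tables (at fixed margins) no more likely than the observed one
#' (minimum-likelihood convention).
#'
#' @param a,b,c,d cell counts, row-wise.
#' @return one-row association-result data frame (statistic = odds ratio
#'   estimate).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  tab <- matrix(c(a, c, b, d), 2, 2)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (sum(tab) == 0) stop("all-zero table")
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  association_result("row1", "col1", "fisher-exact", unname(ft$estimate),
                     ft$p.value, n = sum(tab))
}

#' Per-sample log10 Prevotella/Bacteroides ratio
#'
#' `log10((p_Prevotella + pseudocount) / (p_Bacteroides + pseudocount))`,
#' the continuous covariate summarizing the reciprocal abundance axis of
#' the two genera.
#'
#' @param bact_props bacterial `proportion_table` containing both genus
#'   rows.
#' @param genera the two genus ids (numerator first).
#' @param pseudocount added to both proportions (default 1e-6).
#' @return named numeric vector per sample.
#' @export
pb_ratio <- function(bact_props, genera = c("Prevotella", "Bacteroides"),
                     pseudocount = 1e-6) {
  m <- unclass(bact_props)
  for (g in genera)
    if (!g %in% rownames(m)) stop("genus row missing from table: ", g)
  log10((m[genera[1], ] + pseudocount) / (m[genera[2], ] + pseudocount))
}

#' Group means of per-feature z-scores
#'
#' Each feature (row) is z-scored across all samples (mean 0, sd 1), then
#' averaged within groups: the normalized summary shown on group heatmaps.
#' Zero-variance features give an all-zero row, flagged in the
#' `flat_features` attribute.
#'
#' @param props feature x sample matrix.
#' @param groups per-sample group labels (e.g. archaeal status).
#' @return feature x group matrix of mean z-scores.
#' @export
group_zscore_summary <- function(props, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 represented groups")
  m <- unclass(props)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  flat <- sdv == 0
  z <- (m - mu) / ifelse(flat, 1, sdv)
  z[flat, ] <- 0
  out <- vapply(levels(groups),
                function(g) rowMeans(z[, groups == g, drop = FALSE]),
                numeric(nrow(m)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(rownames(m), levels(groups)))
  structure(out, flat_features = rownames(m)[flat])
}

#' Number of genera detected per sample
#'
#' @param counts genus x sample count matrix (count > 0 = detected) or a
#'   `proportion_table` with `threshold` for presence.
#' @param threshold optional presence threshold applied to proportions.
#' @return named integer vector per sample.
#' @export
genus_richness <- function(counts, threshold = NULL) {
  m <- unclass(counts)
  if (is.null(threshold)) colSums(m > 0) else colSums(m >= threshold)
}
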