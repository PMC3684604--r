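#' Nutrient cluster measurements (per-cluster PC1 dietary scores)
#'
#' Reduces a nutrient inventory to a small set of surrogate dietary
#' covariates: (1) pairwise Spearman correlations between all non-constant
#' nutrients; (2) dissimilarity `sqrt(1 - rho)`; (3) Ward agglomeration cut
#' into `n_clusters` clusters (about 10% of a typical ~200-nutrient panel);
#' (4) within each cluster, member nutrients are z-standardized and the
#' first principal component score per sample is extracted. PC1 sign is
#' fixed so that its correlation with the mean of the member z-scores is
#' non-negative; a singleton cluster's score is the z-scored nutrient
#' itself.
#'
#' @param nut a [nutrient_table()] (samples x nutrients).
#' @param n_clusters number of nutrient clusters (default 20).
#' @return object of class `nutrient_cluster_measurement`: list with
#'   `scores` (sample x cluster matrix, columns mean 0), `membership`
#'   (named nutrient -> cluster id), `loadings` (per-cluster PC1 loading
#'   vectors), `explained_variance` (per-cluster PC1 variance share) and
#'   `inventory`.
#' @export
nutrient_cluster_measurements <- function(nut, n_clusters = 20) {
  m <- unclass(nut)
  const <- apply(m, 2, function(v) max(v) - min(v) == 0)
  if (any(const)) {
    warning("excluding constant nutrients: ",
            paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
  }
  if (ncol(m) < n_clusters)
    stop(sprintf("need at least %d non-constant nutrients, have %d",
                 n_clusters, ncol(m)))
  rho <- stats::cor(m, method = "spearman")
  dd <- stats::as.dist(sqrt(pmax(1 - rho, 0)))
  hc <- stats::hclust(dd, method = "ward.D2")
  membership <- stats::cutree(hc, k = n_clusters)
  cluster_ids <- paste0("NC", sprintf("%02d", seq_len(n_clusters)))
  scores <- matrix(NA_real_, nrow(m), n_clusters,
                   dimnames = list(rownames(m), cluster_ids))
  loadings <- vector("list", n_clusters)
  names(loadings) <- cluster_ids
  expl <- stats::setNames(numeric(n_clusters), cluster_ids)
  for (k in seq_len(n_clusters)) {
    members <- colnames(m)[membership == k]
    z <- scale(m[, members, drop = FALSE])
    if (length(members) == 1) {
      scores[, k] <- z[, 1]
      loadings[[k]] <- stats::setNames(1, members)
      expl[k] <- 1
    } else {
      pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
      s1 <- pc$x[, 1]
      if (stats::cor(s1, rowMeans(z)) < 0) {
        s1 <- -s1
        pc$rotation[, 1] <- -pc$rotation[, 1]
      }
      scores[, k] <- s1
      loadings[[k]] <- stats::setNames(pc$rotation[, 1], members)
      expl[k] <- pc$sdev[1]^2 / sum(pc$sdev^2)
    }
  }
  structure(list(scores = scores,
                 membership = stats::setNames(cluster_ids[membership], colnames(m)),
                 loadings = loadings, explained_variance = expl,
                 inventory = attr(nut, "inventory")),
            class = "nutrient_cluster_measurement")
}

#' @export
print.nutrient_cluster_measurement <- function(x, ...) {
  cat(sprintf("<nutrient_cluster_measurement> %s inventory: %d samples x %d clusters (%d nutrients)\n",
              x$inventory, nrow(x$scores), ncol(x$scores), length(x$membership)))
  invisible(x)
}

#' PERMANOVA screen of nutrient clusters followed by post hoc tests
#'
#' Stage 1 screens every nutrient-cluster score against every supplied
#' community distance matrix with [permanova()]; a cluster is carried
#' forward if any of its PERMANOVA p-values falls below `alpha_screen`.
#' Stage 2, for screened-in clusters only: Spearman correlation of the
#' cluster score with each genus proportion, and a Kruskal-Wallis test of
#' the score across archaeal status groups. BH adjustment at FDR `q` is
#' applied within each stage-2 family (one family per test type).
#'
#' @param ncm a [nutrient_cluster_measurements()] result.
#' @param dists named list of sample x sample distance matrices.
#' @param taxa_props genus x sample proportion matrix for the post hoc
#'   correlations.
#' @param status per-sample archaeal status factor.
#' @param n_perm permutations for stage 1.
#' @param seed integer seed.
#' @param q FDR level for stage-2 selection (default 0.25).
#' @param alpha_screen stage-1 raw-p threshold per (cluster, matrix) pair
#'   (default 0.05).
#' @return list with `screen` (stage-1 table), `selected` (cluster ids
#'   carried forward), `spearman` and `kruskal` (stage-2 association-result
#'   tables with q-values).
#' @export
screen_and_posthoc <- function(ncm, dists, taxa_props, status, n_perm = 999,
                               seed = 1, q = 0.25, alpha_screen = 0.05) {
  scores <- ncm$scores
  screen <- do.call(rbind, lapply(colnames(scores), function(cl) {
    do.call(rbind, lapply(seq_along(dists), function(m) {
      pr <- permanova(dists[[m]], stats::setNames(scores[, cl], rownames(scores)),
                      n_perm = n_perm, seed = seed + m,
                      label = c(covariate = cl,
                                distance = names(dists)[m] %||% paste0("d", m)))
      data.frame(cluster = cl, distance = pr$distance, pseudo_F = pr$pseudo_F,
                 p_value = pr$p_value, stringsAsFactors = FALSE)
    }))
  }))
  sel <- unique(screen$cluster[screen$p_value < alpha_screen])
  sp <- NULL
  kw <- NULL
  if (length(sel) > 0) {
    sp <- spearman_matrix(t(scores[, sel, drop = FALSE]), unclass(taxa_props))
    ok <- !is.na(sp$p_raw)
    sp$q_bh[ok] <- stats::p.adjust(sp$p_raw[ok], method = "BH")
    kw <- do.call(rbind, lapply(sel, function(cl)
      kruskal_wallis(scores[, cl], status, feature = cl)))
    kw$q_bh <- stats::p.adjust(kw$p_raw, method = "BH")
  }
  empty <- data.frame(feature_a = character(0), feature_b = character(0),
                      test = character(0), statistic = numeric(0),
                      p_raw = numeric(0), q_bh = numeric(0), n = integer(0))
  list(screen = screen, selected = sel,
       spearman = sp %||% empty, kruskal = kw %||% empty,
       q = q, alpha_screen = alpha_screen)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
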