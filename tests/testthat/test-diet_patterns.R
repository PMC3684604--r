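block_nutrients <- function(n = 60, blocks = c(6, 6), rho = 0.95, seed = 1,
                            inventory = "usual") {
  set.seed(seed)
  vals <- do.call(cbind, lapply(seq_along(blocks), function(b) {
    f <- rnorm(n)
    vapply(seq_len(blocks[b]), function(j)
      sqrt(rho) * f + sqrt(1 - rho) * rnorm(n), numeric(n))
  }))
  dimnames(vals) <- list(sprintf("S%02d", seq_len(n)),
                         sprintf("nut%02d", seq_len(sum(blocks))))
  nutrient_table(vals, inventory)
}

test_that("planted correlation blocks are recovered exactly (ARI = 1)", {
  nut <- block_nutrients(seed = 4)
  ncm <- nutrient_cluster_measurements(nut, n_clusters = 2)
  truth <- rep(1:2, each = 6)
  ari <- mclust::adjustedRandIndex(as.integer(factor(ncm$membership)), truth)
  expect_equal(ari, 1)
  expect_equal(sort(unique(ncm$membership)), c("NC01", "NC02"))
})

test_that("a cluster of identical nutrients has PC1 = shared z-profile, EV 1", {
  set.seed(6)
  base <- rnorm(40)
  vals <- cbind(nutA = base, nutB = base, nutC = base, other = rnorm(40))
  rownames(vals) <- sprintf("S%02d", 1:40)
  ncm <- nutrient_cluster_measurements(nutrient_table(vals, "usual"), n_clusters = 2)
  k_ident <- ncm$membership[["nutA"]]
  expect_equal(ncm$explained_variance[[k_ident]], 1, tolerance = 1e-12)
  sc <- ncm$scores[, k_ident]
  z <- scale(base)[, 1]
  expect_equal(abs(cor(sc, z)), 1, tolerance = 1e-12)
  expect_gte(cor(sc, z), 0) # sign convention: aligned with member mean
  # all score columns are centred
  expect_true(all(abs(colMeans(ncm$scores)) < 1e-10))
})

test_that("singleton clusters return the z-scored nutrient itself", {
  set.seed(8)
  vals <- cbind(a = rnorm(30), b = rnorm(30))
  vals <- cbind(vals, c = vals[, "a"] + rnorm(30, sd = 0.01))
  rownames(vals) <- sprintf("S%02d", 1:30)
  ncm <- nutrient_cluster_measurements(nutrient_table(vals, "recent"), n_clusters = 2)
  singleton <- names(which(table(ncm$membership) == 1))
  memb <- names(ncm$membership)[ncm$membership == singleton]
  expect_length(memb, 1)
  expect_equal(ncm$scores[, singleton], scale(vals[, memb])[, 1],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("cluster scores are invariant to affine rescaling of raw nutrients", {
  nut <- block_nutrients(seed = 12)
  scaled <- unclass(nut)
  scaled <- sweep(sweep(scaled, 2, runif(ncol(scaled), 0.5, 20), "*"),
                  2, rnorm(ncol(scaled), 100), "+")
  ncm1 <- nutrient_cluster_measurements(nut, 2)
  ncm2 <- nutrient_cluster_measurements(
    nutrient_table(scaled, attr(nut, "inventory")), 2)
  expect_equal(ncm1$scores, ncm2$scores, tolerance = 1e-8)
  expect_equal(ncm1$membership, ncm2$membership)
})

test_that("permuting nutrient input order changes nothing but labels", {
  nut <- block_nutrients(seed = 17)
  o <- sample(ncol(nut))
  ncm1 <- nutrient_cluster_measurements(nut, 2)
  ncm2 <- nutrient_cluster_measurements(
    nutrient_table(unclass(nut)[, o], attr(nut, "inventory")), 2)
  same_block <- outer(ncm1$membership, ncm1$membership, "==")
  same_block2 <- outer(ncm2$membership[names(ncm1$membership)],
                       ncm2$membership[names(ncm1$membership)], "==")
  expect_equal(same_block, same_block2)
})

test_that("constant nutrients are excluded with a warning before clustering", {
  nut <- block_nutrients(seed = 9)
  vals <- cbind(unclass(nut), flat = rep(1, nrow(nut)))
  expect_warning(
    ncm <- nutrient_cluster_measurements(nutrient_table(vals, "usual"), 2),
    "constant")
  expect_false("flat" %in% names(ncm$membership))
  expect_error(nutrient_cluster_measurements(
    nutrient_table(vals[, 1:3], "usual"), 5), "at least 5")
})

test_that("about 10% of a 200-nutrient panel yields 20 clusters", {
  nut <- block_nutrients(n = 50, blocks = rep(10, 20), rho = 0.8, seed = 30)
  ncm <- nutrient_cluster_measurements(nut, n_clusters = 20)
  expect_equal(ncol(ncm$scores), 20)
  expect_equal(ncol(ncm$scores) / length(ncm$membership), 0.1)
})

test_that("stage-2 post hoc tests are gated on the stage-1 screen", {
  nut <- block_nutrients(n = 24, blocks = c(4, 4), seed = 21)
  ncm <- nutrient_cluster_measurements(nut, 2)
  set.seed(1)
  x <- matrix(rnorm(24 * 3), 24)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(rownames(nut), rownames(nut))
  taxa <- matrix(runif(5 * 24), 5, 24,
                 dimnames = list(paste0("g", 1:5), rownames(nut)))
  status <- factor(rep(c("Methanobrevibacter", "none"), 12))
  gated <- screen_and_posthoc(ncm, list(d = d), taxa, status, n_perm = 99,
                              seed = 2, alpha_screen = 0) # nothing can pass
  expect_length(gated$selected, 0)
  expect_equal(nrow(gated$spearman), 0)
  expect_equal(nrow(gated$kruskal), 0)

  open <- screen_and_posthoc(ncm, list(d = d), taxa, status, n_perm = 99,
                             seed = 2, alpha_screen = 1.1) # everything passes
  expect_setequal(open$selected, colnames(ncm$scores))
  expect_equal(nrow(open$spearman), 2 * 5)
  expect_true(all(open$kruskal$test == "kruskal-wallis"))
})
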