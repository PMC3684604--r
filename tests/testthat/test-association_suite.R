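test_that("presence threshold is inclusive at 0.01", {
  m <- matrix(c(0.01, 0.0099, 0.5, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  p <- presence_matrix(m, 0.01)
  expect_equal(unname(p), rbind(c(1, 1), c(0, 0)))
  # threshold 0 marks everything present (documented boundary semantics)
  expect_true(all(presence_matrix(m, 0) == 1))
})

test_that("Dice index matches set enumeration and the naive quadratic oracle", {
  pres <- rbind(A = c(1, 1, 1, 0, 0),
                B = c(0, 1, 1, 1, 0),
                C = c(0, 0, 0, 0, 0),
                D = c(1, 1, 1, 0, 0))
  colnames(pres) <- paste0("s", 1:5)
  S <- dice_matrix(pres)
  expect_equal(S["A", "B"], 2 * 2 / (3 + 3))
  expect_equal(S["A", "D"], 1)          # identical non-empty profiles
  expect_equal(S["A", "C"], 0)          # empty partner
  expect_equal(S["C", "C"], 1)          # diagonal convention
  expect_equal(S, t(S))

  set.seed(20)
  big <- matrix(rbinom(20 * 30, 1, 0.3), 20, 30,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:30)))
  expect_equal(unname(dice_matrix(big)), oracle_dice(big), tolerance = 1e-12)
})

test_that("Ward ordering merges identical profiles first and is input-order invariant", {
  pres <- rbind(A = c(1, 1, 1, 0, 0, 0),
                B = c(1, 1, 1, 0, 0, 0),
                C = c(0, 0, 0, 1, 1, 1),
                D = c(0, 1, 0, 1, 1, 0))
  colnames(pres) <- paste0("s", 1:6)
  S <- dice_matrix(pres)
  cl <- dice_cluster_order(S)
  first <- cl$hclust$merge[1, ]
  expect_setequal(rownames(S)[-first], c("A", "B"))

  # first merge equals the brute-force Ward objective minimizer
  set.seed(3)
  pres2 <- matrix(rbinom(5 * 12, 1, 0.4), 5, 12,
                  dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  S2 <- dice_matrix(pres2)
  cl2 <- dice_cluster_order(S2)
  expect_setequal(-cl2$hclust$merge[1, ], oracle_ward_first_merge(S2))

  # permuting genus order relabels but preserves the merge heights
  o <- c(3, 1, 5, 2, 4)
  cl3 <- dice_cluster_order(S2[o, o])
  expect_equal(sort(cl3$hclust$height), sort(cl2$hclust$height), tolerance = 1e-12)
  expect_error(dice_cluster_order(S2[1, 1, drop = FALSE]), "at least 2")
})

test_that("archaeal status follows the predominance rule", {
  m <- rbind(Methanobrevibacter = c(0.9, 0, 0.8, 0, 0.3),
             Nitrososphaera     = c(0,   0, 0.2, 0.4, 0.3))
  colnames(m) <- paste0("s", 1:5)
  props <- structure(m, empty_samples = character(0),
                     class = c("proportion_table", "matrix", "array"))
  expect_warning(st <- classify_archaeal_status(props), "tie")
  expect_equal(as.character(st),
               c("Methanobrevibacter", "none", "Methanobrevibacter",
                 "Nitrososphaera", "none"))
})

test_that("Kruskal-Wallis wrapper matches the hand rank formula and handles degeneracy", {
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2),
               tolerance = 1e-10)
  # rank invariance under strictly monotone transforms
  set.seed(7)
  v <- rnorm(30)
  g <- sample(c("a", "b", "c"), 30, replace = TRUE)
  expect_equal(kruskal_wallis(v, g)$statistic,
               kruskal_wallis(exp(v), g)$statistic, tolerance = 1e-10)
  deg <- kruskal_wallis(rep(2, 10), rep(c("a", "b"), 5))
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p_raw, 1)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 non-empty groups")
})

test_that("Dunn post hoc matches the tie-corrected hand formula", {
  v <- c(1, 3, 5, 2, 2, 8, 9, 10, 7)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- dunn_posthoc(v, g)
  # hand computation
  r <- rank(v)
  N <- 9
  ties <- table(r)
  Tc <- sum(ties^3 - ties) / (12 * (N - 1))
  se <- sqrt((N * (N + 1) / 12 - Tc) * (2 / 3))
  z_ab <- (mean(r[g == "a"]) - mean(r[g == "b"])) / se
  row_ab <- res[res$feature_a == "feature:a" & res$feature_b == "b", ]
  expect_equal(row_ab$statistic, z_ab, tolerance = 1e-12)
  expect_equal(row_ab$p_raw, 2 * pnorm(-abs(z_ab)), tolerance = 1e-12)
  # p ordering follows |z| ordering
  expect_equal(order(res$p_raw), order(-abs(res$statistic)))
  # identical groups give z = 0, p = 1
  res2 <- dunn_posthoc(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_raw, 1)
})

test_that("Spearman matrix equals rank-then-Pearson with tie handling", {
  x <- rbind(f1 = c(1, 2, 2, 4, 5, 6), f2 = c(6, 5, 4, 3, 2, 1))
  y <- rbind(b1 = c(2, 3, 5, 7, 11, 13), b2 = c(2, 2, 3, 3, 1, 9))
  colnames(x) <- colnames(y) <- paste0("s", 1:6)
  res <- spearman_matrix(x, y)
  # y monotone in x -> rho 1; y = reversal -> rho -1 (tie-free features)
  expect_equal(res$statistic[res$feature_a == "f2" & res$feature_b == "b1"], -1)
  expect_equal(spearman_matrix(y["b1", , drop = FALSE],
                               y["b1", , drop = FALSE])$statistic, 1)
  r12 <- res$statistic[res$feature_a == "f1" & res$feature_b == "b2"]
  expect_equal(r12, oracle_spearman(x["f1", ], y["b2", ]), tolerance = 1e-12)

  # naive loop concordance on a 20 x 30 random fixture
  set.seed(15)
  X <- matrix(rnorm(10 * 30), 10, dimnames = list(paste0("f", 1:10), paste0("s", 1:30)))
  Y <- matrix(rnorm(8 * 30), 8, dimnames = list(paste0("b", 1:8), paste0("s", 1:30)))
  res2 <- spearman_matrix(X, Y)
  for (k in sample(nrow(res2), 10)) {
    expect_equal(res2$statistic[k],
                 oracle_spearman(X[res2$feature_a[k], ], Y[res2$feature_b[k], ]),
                 tolerance = 1e-12)
  }
  # constant feature flagged and excluded from the FDR family
  Xc <- rbind(X, flat = rep(1, 30))
  res3 <- spearman_matrix(Xc, Y)
  expect_true(all(is.na(res3$statistic[res3$feature_a == "flat"])))
  expect_true(all(is.na(res3$q_bh[res3$feature_a == "flat"])))
})

test_that("BH q-values match the step-up hand computation and tier labels", {
  out <- bh_fdr(c(0.01, 0.02, 0.5))
  expect_equal(out$q_bh, c(0.03, 0.03, 0.5))
  expect_equal(out$q_bh, oracle_bh(c(0.01, 0.02, 0.5)))
  expect_true(all(diff(sort(out$q_bh)) >= 0))
  single <- bh_fdr(0.01, q = 0.25)
  expect_true(single$selected)
  # tiers: q=0.09 earns all four asterisks, q=0.22 only the 25% tier
  expect_equal(bh_fdr(0.09)$tier, 4)
  expect_equal(bh_fdr(0.22)$tier, 1)
  set.seed(22)
  p <- runif(50)
  expect_equal(bh_fdr(p)$q_bh, oracle_bh(p), tolerance = 1e-12)
})

test_that("Fisher exact two-sided p matches hypergeometric enumeration", {
  res <- fisher_exact_2x2(1, 9, 11, 3)
  expect_equal(res$p_raw, oracle_fisher_p(1, 9, 11, 3), tolerance = 1e-9)
  expect_equal(res$p_raw, 0.002759, tolerance = 1e-3)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p_raw, 1)
  # symmetry under row and column swaps
  expect_equal(fisher_exact_2x2(9, 1, 3, 11)$p_raw, res$p_raw, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(11, 3, 1, 9)$p_raw, res$p_raw, tolerance = 1e-12)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
})

test_that("P/B ratio evaluates the pseudocounted log ratio and is monotone", {
  m <- rbind(Prevotella = c(0.2, 0, 0.4),
             Bacteroides = c(0.2, 0.5, 0.1))
  colnames(m) <- paste0("s", 1:3)
  pb <- pb_ratio(m)
  expect_equal(unname(pb[1]), 0)
  expect_equal(unname(pb[2]), log10(1e-6 / (0.5 + 1e-6)), tolerance = 1e-12)
  expect_gt(pb[3], pb[1])
  expect_error(pb_ratio(m[1, , drop = FALSE]), "Bacteroides")
})

test_that("group z-score summary centres features and respects group weighting", {
  m <- rbind(f1 = c(1, 2, 3, 4), f2 = c(5, 5, 5, 5))
  colnames(m) <- paste0("s", 1:4)
  gr <- c("a", "a", "b", "b")
  zs <- group_zscore_summary(m, gr)
  expect_equal(unname(zs["f2", ]), c(0, 0))
  expect_equal(attr(zs, "flat_features"), "f2")
  z <- (m["f1", ] - mean(m["f1", ])) / sd(m["f1", ])
  expect_equal(unname(zs["f1", "a"]), mean(z[1:2]), tolerance = 1e-12)
  # group means weighted by group sizes sum to zero
  sizes <- table(gr)
  expect_equal(sum(zs["f1", names(sizes)] * as.numeric(sizes)), 0, tolerance = 1e-12)
})

test_that("genus richness counts detected genera per sample", {
  ct <- toy_counts(rbind(c(0, 3, 1), c(0, 0, 2), c(0, 5, 0)))
  expect_equal(unname(genus_richness(ct)), c(0, 2, 2))
  set.seed(2)
  big <- random_counts(25, 10, seed = 2, sparsity = 0.6)
  brute <- vapply(seq_len(10), function(j) sum(unclass(big)[, j] > 0), numeric(1))
  expect_equal(unname(genus_richness(big)), brute)
})
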