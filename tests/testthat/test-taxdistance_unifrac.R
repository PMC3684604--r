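test_that("taxonomic distance follows 1 - k/L with non-matching sentinel", {
  tax <- toy_taxonomy(list(
    gA = c("P1", "C1", "O1", "F1", "gA"),
    gB = c("P1", "C1", "O2", "F2", "gB"),       # shares Phylum+Class -> 0.6
    gC = c("P2", "C9", "O9", "F9", "gC"),       # different phylum -> 1
    gD = c("P1", "unclassified", "O1", "F1", "gD")))
  d <- taxonomic_distance(tax)
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(d["gA", "gB"], 1 - 2 / 5)
  expect_equal(d["gA", "gC"], 1)
  # sentinel stops matching even though deeper ranks agree
  expect_equal(d["gA", "gD"], 1 - 1 / 5)
  expect_equal(d, t(d))
})

test_that("taxonomy tree cophenetic distances reproduce the formula", {
  # two genera in the same family: path 2 steps, 2/(2*5) = 0.2
  tax2 <- toy_taxonomy(list(gA = c("P1", "C1", "O1", "F1", "gA"),
                            gB = c("P1", "C1", "O1", "F1", "gB")))
  tr2 <- taxonomy_to_tree(tax2)
  expect_equal(unname(ape::cophenetic.phylo(tr2)["gA", "gB"]) / 10,
               taxonomic_distance(tax2)["gA", "gB"])

  tax <- random_taxonomy(20, seed = 7)
  tree <- taxonomy_to_tree(tax)
  coph <- ape::cophenetic.phylo(tree) / (2 * 5)
  d <- taxonomic_distance(tax)
  expect_equal(coph[rownames(d), colnames(d)], d, tolerance = 1e-12)

  # unclassified ranks create private lineages but still match the formula
  taxu <- random_taxonomy(15, seed = 8, p_unclassified = 0.25)
  cophu <- ape::cophenetic.phylo(taxonomy_to_tree(taxu)) / 10
  du <- taxonomic_distance(taxu)
  expect_equal(cophu[rownames(du), colnames(du)], du, tolerance = 1e-12)
})

test_that("single-genus taxonomy gives a one-leaf tree", {
  tax <- toy_taxonomy(list(gA = c("P1", "C1", "O1", "F1", "gA")))
  tr <- taxonomy_to_tree(tax)
  expect_equal(tr$tip.label, "gA")
  expect_equal(sum(tr$edge.length), 5)
})

test_that("generalized UniFrac matches the per-branch brute-force oracle", {
  tax <- toy_taxonomy(list(
    gA = c("P1", "C1", "O1", "F1", "gA"),
    gB = c("P1", "C1", "O1", "F1", "gB"),
    gC = c("P1", "C2", "O2", "F2", "gC"),
    gD = c("P2", "C3", "O3", "F3", "gD")))
  tree <- taxonomy_to_tree(tax)
  props <- as_props(rbind(c(10, 5, 0), c(0, 5, 1), c(0, 0, 9), c(10, 10, 0)),
                    domain = "fungi")
  rownames(props) <- rownames(tax)
  for (alpha in c(0, 0.25, 0.5, 1)) {
    d <- generalized_unifrac(tree, props, alpha)
    for (i in 1:2) for (j in (i + 1):3) {
      expect_equal(d[i, j],
                   oracle_gunifrac_pair(tree, unclass(props)[, i],
                                        unclass(props)[, j], alpha),
                   tolerance = 1e-12)
    }
  }
  du <- unweighted_unifrac(tree, props)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(du[i, j],
                 oracle_unweighted_pair(tree, unclass(props)[, i], unclass(props)[, j]),
                 tolerance = 1e-12)
})

test_that("UniFrac limits: identical profiles give 0, disjoint phyla give 1", {
  tax <- toy_taxonomy(list(
    gA = c("P1", "C1", "O1", "F1", "gA"),
    gB = c("P2", "C2", "O2", "F2", "gB")))
  tree <- taxonomy_to_tree(tax)
  props <- as_props(rbind(c(3, 0, 2), c(0, 5, 2)))
  rownames(props) <- rownames(tax)
  for (alpha in c(0, 0.5, 1)) {
    d <- generalized_unifrac(tree, props, alpha)
    expect_equal(d["s1", "s2"], 1)       # disjoint communities
    expect_equal(unname(diag(d)), c(0, 0, 0))
  }
  expect_equal(unweighted_unifrac(tree, props)["s1", "s2"], 1)
  # presence-identical profiles: unweighted 0 regardless of abundance
  props2 <- as_props(rbind(c(1, 9), c(9, 1)))
  rownames(props2) <- rownames(tax)
  expect_equal(unweighted_unifrac(tree, props2)["s1", "s2"], 0)
})

test_that("UniFrac outputs are metric-shaped and bounded in [0,1]", {
  tax <- random_taxonomy(15, seed = 4)
  tree <- taxonomy_to_tree(tax)
  ct <- random_counts(15, 12, seed = 4, sparsity = 0.4)
  props <- to_proportions(ct)
  rownames(props) <- rownames(tax)
  for (alpha in c(0, 0.5, 1)) {
    d <- generalized_unifrac(tree, props, alpha)
    expect_equal(d, t(d), tolerance = 1e-12)
    expect_true(all(d >= 0 & d <= 1 + 1e-12, na.rm = TRUE))
    expect_true(all(diag(d) == 0 | is.na(diag(d))))
  }
})

test_that("moving mass from a shared branch to an unshared one never decreases d", {
  tax <- toy_taxonomy(list(
    gA = c("P1", "C1", "O1", "F1", "gA"),
    gB = c("P1", "C1", "O1", "F1", "gB"),
    gC = c("P2", "C2", "O2", "F2", "gC")))
  tree <- taxonomy_to_tree(tax)
  base <- c(0.6, 0.2, 0.2)
  for (alpha in c(0, 0.5, 1)) {
    prev <- -1
    for (shift in seq(0, 0.2, by = 0.05)) {
      # sample B moves mass from gA (shared with sample A) to gC (unshared)
      m <- cbind(s1 = c(0.8, 0.2, 0), s2 = base + c(-shift, 0, shift))
      rownames(m) <- rownames(tax)
      props <- structure(m, empty_samples = character(0),
                         class = c("proportion_table", "matrix", "array"))
      d <- generalized_unifrac(tree, props, alpha)["s1", "s2"]
      expect_gte(d, prev - 1e-12)
      prev <- d
    }
  }
})

test_that("empty samples get NA distances with a warning", {
  tax <- toy_taxonomy(list(gA = c("P1", "C1", "O1", "F1", "gA"),
                           gB = c("P1", "C2", "O2", "F2", "gB")))
  tree <- taxonomy_to_tree(tax)
  props <- as_props(rbind(c(2, 0, 1), c(1, 0, 1)))
  rownames(props) <- rownames(tax)
  expect_warning(d <- generalized_unifrac(tree, props, 0.5), "empty samples")
  expect_true(all(is.na(d["s2", ])))
  expect_false(anyNA(d[c("s1", "s3"), c("s1", "s3")]))
})
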