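# Shared fixtures and independent reference (oracle) implementations.
# Oracles are written as plain loops/enumerations, independent of the
# package's vectorized code paths.

toy_counts <- function(m, domain = "bacteria", genera = NULL, samples = NULL) {
  m <- as.matrix(m)
  rownames(m) <- genera %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  count_table(m, domain)
}

random_counts <- function(G, n, domain = "bacteria", lambda = 3, sparsity = 0.5,
                          seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(G * n, lambda) * (runif(G * n) > sparsity), G, n)
  toy_counts(m, domain)
}

toy_taxonomy <- function(lineages, genera = names(lineages)) {
  m <- do.call(rbind, lineages)
  rownames(m) <- genera
  taxonomy_table(m)
}

random_taxonomy <- function(G, seed = 1, p_unclassified = 0) {
  set.seed(seed)
  phyla <- paste0("P", 1:3)
  lin <- t(vapply(seq_len(G), function(g) {
    p <- sample(phyla, 1)
    cl <- paste0(p, "_C", sample(1:2, 1))
    or <- paste0(cl, "_O", sample(1:2, 1))
    fa <- paste0(or, "_F", sample(1:2, 1))
    out <- c(p, cl, or, fa, paste0("g", g))
    drop <- runif(5) < p_unclassified
    out[drop] <- "unclassified"
    out[5] <- if (drop[5]) "unclassified" else paste0("g", g)
    out
  }, character(5)))
  rownames(lin) <- paste0("g", seq_len(G))
  taxonomy_table(lin)
}

as_props <- function(m, domain = "bacteria") {
  to_proportions(toy_counts(m, domain))
}

# --- oracle: per-branch UniFrac by explicit descendant enumeration ---------
tree_descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tree_descendant_tips, tree = tree))
}

oracle_gunifrac_pair <- function(tree, pA, pB, alpha) {
  # pA, pB named by tip label
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tree$tip.label[tree_descendant_tips(tree, tree$edge[e, 2])]
    a <- sum(pA[tips]); b <- sum(pB[tips])
    if (a + b > 0) {
      w <- tree$edge.length[e] * (a + b)^alpha
      num <- num + w * abs(a - b) / (a + b)
      den <- den + w
    }
  }
  num / den
}

oracle_unweighted_pair <- function(tree, pA, pB) {
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tree$tip.label[tree_descendant_tips(tree, tree$edge[e, 2])]
    a <- sum(pA[tips]) > 0; b <- sum(pB[tips]) > 0
    if (a || b) den <- den + tree$edge.length[e]
    if (xor(a, b)) num <- num + tree$edge.length[e]
  }
  num / den
}

# --- oracle: naive Dice by set enumeration ---------------------------------
oracle_dice <- function(presence) {
  G <- nrow(presence)
  S <- matrix(0, G, G)
  for (i in 1:G) for (j in 1:G) {
    A <- which(presence[i, ] == 1); B <- which(presence[j, ] == 1)
    S[i, j] <- if (length(A) + length(B) == 0) 0 else
      2 * length(intersect(A, B)) / (length(A) + length(B))
  }
  diag(S) <- 1
  S
}

# --- oracle: Spearman as Pearson on average ranks --------------------------
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# --- oracle: two-sided Fisher by hypergeometric enumeration ----------------
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(xs, c1, N - c1, r1)
  p_obs <- stats::dhyper(a, c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- oracle: BH step-up by hand --------------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m); out[o] <- pmin(q, 1)
  out
}

# --- oracle: Ward objective (increase in within-cluster SSE) ---------------
oracle_ward_first_merge <- function(X) {
  # which pair of rows of X would Ward merge first (minimum SSE increase;
  # for singletons this is half the squared Euclidean distance)
  n <- nrow(X)
  best <- c(NA, NA); best_cost <- Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cost <- sum((X[i, ] - X[j, ])^2) / 2
    if (cost < best_cost) { best_cost <- cost; best <- c(i, j) }
  }
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a
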