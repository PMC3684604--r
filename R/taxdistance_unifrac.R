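#' Taxonomic distance between genera from ranked lineages
#'
#' For lineages of length L, `d(i,j) = 1 - k/L` where `k` is the number of
#' consecutive ranks, from the top (Phylum) down, at which the two lineages
#' carry identical labels. The `"unclassified"` sentinel never matches
#' anything, including itself, so comparison stops at the first unclassified
#' rank of either lineage. The diagonal is 0 by definition.
#'
#' @param tax a [taxonomy_table()].
#' @return symmetric genus x genus numeric matrix in `[0, 1]`.
#' @export
taxonomic_distance <- function(tax) {
  L <- ncol(tax)
  G <- nrow(tax)
  acc <- matrix(TRUE, G, G)
  k <- matrix(0, G, G)
  for (r in seq_len(L)) {
    lab <- tax[, r]
    eq <- outer(lab, lab, "==")
    uncl <- lab == UNCLASSIFIED
    eq[uncl, ] <- FALSE
    eq[, uncl] <- FALSE
    acc <- acc & eq
    k <- k + acc
  }
  d <- 1 - k / L
  diag(d) <- 0
  dimnames(d) <- list(rownames(tax), rownames(tax))
  d
}

#' Materialize a ranked taxonomy as a rooted ultrametric tree
#'
#' The rank hierarchy itself is used as the tree: one internal node per
#' distinct rank label nested under its parent label, unit branch lengths,
#' genera as leaves at depth L. An `"unclassified"` label starts a private
#' lineage for its genus (it is never merged with any other label, including
#' other `"unclassified"` labels), so shared ancestry is never invented.
#' Leaf-to-leaf path length divided by 2L reproduces [taxonomic_distance()].
#'
#' @param tax a [taxonomy_table()].
#' @param branch_length length assigned to every rank step (default 1).
#' @return an [ape::read.tree()]-style `phylo` object with tip labels equal
#'   to the genus ids.
#' @export
taxonomy_to_tree <- function(tax, branch_length = 1) {
  L <- ncol(tax)
  G <- nrow(tax)
  genera <- rownames(tax)
  keys <- matrix("", G, L)
  for (g in seq_len(G)) {
    private <- FALSE
    prefix <- ""
    for (r in seq_len(L)) {
      lab <- tax[g, r]
      if (lab == UNCLASSIFIED) private <- TRUE
      eff <- if (private) paste0(lab, "@", genera[g]) else lab
      prefix <- paste(prefix, eff, sep = "|")
      keys[g, r] <- prefix
    }
  }
  int_keys <- unique(as.vector(keys[, seq_len(L - 1), drop = FALSE]))
  node_of <- c(stats::setNames(seq_len(G), keys[, L]),
               stats::setNames(G + 1, "ROOT"),
               stats::setNames(G + 1 + seq_along(int_keys), int_keys))
  parent <- character(0)
  child <- character(0)
  for (g in seq_len(G)) {
    parent <- c(parent, "ROOT", keys[g, seq_len(L - 1)])
    child <- c(child, keys[g, ])
  }
  ek <- !duplicated(child)
  edge <- cbind(unname(node_of[parent[ek]]), unname(node_of[child[ek]]))
  tr <- structure(list(edge = edge,
                       edge.length = rep(branch_length, nrow(edge)),
                       tip.label = genera,
                       Nnode = 1L + length(int_keys)),
                  class = "phylo", order = "cladewise")
  storage.mode(tr$edge) <- "integer"
  tr
}

# branch x sample matrix of descendant-leaf proportion totals, plus lengths
branch_profiles <- function(tree, props) {
  G <- length(tree$tip.label)
  missing <- setdiff(rownames(props), tree$tip.label)
  if (length(missing))
    stop("proportion rows absent from tree: ", paste(missing, collapse = ", "))
  P <- matrix(0, G, ncol(props), dimnames = list(tree$tip.label, colnames(props)))
  P[rownames(props), ] <- unclass(props)
  nE <- nrow(tree$edge)
  parent_of <- integer(max(tree$edge))
  edge_of_child <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of_child[tree$edge[, 2]] <- seq_len(nE)
  member <- matrix(FALSE, nE, G)
  root <- G + 1L
  for (tip in seq_len(G)) {
    node <- tip
    while (node != root) {
      member[edge_of_child[node], tip] <- TRUE
      node <- parent_of[node]
    }
  }
  list(abund = member %*% P, lengths = tree$edge.length)
}

unifrac_pair_matrix <- function(bp, pair_fun, empty_samples = character(0)) {
  M <- bp$abund
  b <- bp$lengths
  ids <- colnames(M)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (length(empty_samples))
    warning("empty samples excluded (distances set to NA): ",
            paste(empty_samples, collapse = ", "))
  for (i in seq_len(n)) {
    for (j in seq_len(max(0, i - 1))) {
      if (ids[i] %in% empty_samples || ids[j] %in% empty_samples) {
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        d[i, j] <- d[j, i] <- pair_fun(M[, i], M[, j], b)
      }
    }
    if (ids[i] %in% empty_samples) d[i, i] <- NA_real_
  }
  d
}

#' Generalized UniFrac distance on a taxonomy tree
#'
#' For branches i with lengths `b_i` and descendant-proportion totals
#' `p_Ai`, `p_Bi` in samples A and B:
#' `d^(alpha)(A,B) = sum_i b_i (p_Ai+p_Bi)^alpha |p_Ai-p_Bi|/(p_Ai+p_Bi) /
#'  sum_i b_i (p_Ai+p_Bi)^alpha`, skipping branches with `p_Ai+p_Bi = 0`.
#' `alpha = 1` is the weighted-normalized form; `alpha = 0` weights all
#' occupied branches equally.
#'
#' @param tree a `phylo` tree whose tips cover the proportion table rows.
#' @param props a `proportion_table` (genus x sample).
#' @param alpha abundance-weighting exponent in `[0, 1]`.
#' @return symmetric sample x sample distance matrix in `[0, 1]`; samples
#'   flagged empty get NA distances with a warning.
#' @export
generalized_unifrac <- function(tree, props, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1)
  bp <- branch_profiles(tree, props)
  pair <- function(pa, pb, b) {
    tot <- pa + pb
    idx <- tot > 0
    if (!any(idx)) return(NA_real_)
    w <- b[idx] * tot[idx]^alpha
    sum(w * abs(pa[idx] - pb[idx]) / tot[idx]) / sum(w)
  }
  unifrac_pair_matrix(bp, pair, attr(props, "empty_samples"))
}

#' Weighted-normalized UniFrac (generalized UniFrac at alpha = 1)
#' @inheritParams generalized_unifrac
#' @return symmetric sample x sample distance matrix.
#' @export
weighted_unifrac <- function(tree, props) generalized_unifrac(tree, props, alpha = 1)

#' Unweighted (presence/absence) UniFrac distance
#'
#' `d(A,B) = sum_i b_i |1(p_Ai>0) - 1(p_Bi>0)| / sum_i b_i 1(p_Ai+p_Bi>0)`.
#'
#' @inheritParams generalized_unifrac
#' @return symmetric sample x sample distance matrix in `[0, 1]`.
#' @export
unweighted_unifrac <- function(tree, props) {
  bp <- branch_profiles(tree, props)
  pair <- function(pa, pb, b) {
    ia <- pa > 0
    ib <- pb > 0
    den <- sum(b[ia | ib])
    if (den == 0) return(NA_real_)
    sum(b[xor(ia, ib)]) / den
  }
  unifrac_pair_matrix(bp, pair, attr(props, "empty_samples"))
}

#' Write a square distance matrix as TSV with ids
#' @param d symmetric matrix with dimnames.
#' @param path output file path.
#' @export
write_distance_matrix <- function(d, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(), con)
  writeLines(paste(c("id", colnames(d)), collapse = "\t"), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a square distance matrix written by [write_distance_matrix()]
#' @param path file path.
#' @return symmetric matrix with ids.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-12) stop("matrix is not symmetric")
  m
}
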