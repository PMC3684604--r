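align_covariate <- function(d, covariate) {
  ids <- colnames(d)
  if (!is.null(names(covariate)) && !is.null(ids)) {
    if (!all(ids %in% names(covariate)))
      stop("covariate is missing samples: ",
           paste(setdiff(ids, names(covariate)), collapse = ", "))
    covariate <- covariate[ids]
  }
  if (length(covariate) != ncol(d))
    stop("covariate length != number of samples in the distance matrix")
  covariate
}

covariate_design <- function(covariate) {
  if (is.numeric(covariate)) {
    X <- cbind(1, covariate)
  } else {
    f <- factor(covariate)
    if (nlevels(f) < 2) stop("zero-variance covariate")
    X <- stats::model.matrix(~f)
  }
  qrX <- qr(X)
  if (qrX$rank < 2) stop("zero-variance covariate")
  # symmetric projection onto the column space of X
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  list(H = tcrossprod(Q), q = qrX$rank - 1L)
}

gower_center <- function(d) {
  n <- ncol(d)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

drop_na_samples <- function(d) {
  bad <- apply(d, 1, function(r) any(is.na(r)))
  if (any(bad)) {
    warning("excluding samples with missing distances: ",
            paste(colnames(d)[bad], collapse = ", "))
    d <- d[!bad, !bad, drop = FALSE]
  }
  d
}

permanova_trace_stats <- function(G, H, q, perm_idx) {
  n <- ncol(G)
  trG <- sum(diag(G))
  stat <- function(Gm) {
    t1 <- sum(H * Gm)
    (t1 / q) / ((trG - t1) / (n - q - 1))
  }
  F_obs <- stat(G)
  F_perm <- apply(perm_idx, 2, function(p) stat(G[p, p]))
  list(F_obs = F_obs, F_perm = F_perm)
}

#' Distance-based permutation MANOVA (PERMANOVA)
#'
#' Tests whether a per-sample covariate explains structure in a distance
#' matrix. With Gower-centred `G = -1/2 J D^2 J` and the hat matrix `H` of
#' the design (intercept + covariate; one-hot for group labels, regression
#' form for continuous covariates), the pseudo-F is
#' `[tr(HGH)/q] / [tr((I-H)G(I-H))/(n-q-1)]` with `q` the covariate rank.
#' Significance is assessed by permuting sample labels; the p-value uses the
#' add-one counting rule `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)` so
#' p is never 0.
#'
#' @param d symmetric sample x sample distance matrix with sample ids as
#'   dimnames.
#' @param covariate numeric vector (regression form) or group labels
#'   (factor/character), aligned to the samples of `d` (by name when named).
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed; required for reproducibility.
#' @param label optional covariate/distance names recorded in the result.
#' @return object of class `permanova_result` with fields `pseudo_F`,
#'   `p_value`, `n_perm`, `covariate`, `distance`, `seed`.
#' @export
permanova <- function(d, covariate, n_perm = 9999, seed = 1,
                      label = c(covariate = "covariate", distance = "distance")) {
  d <- drop_na_samples(as.matrix(d))
  covariate <- align_covariate(d, covariate)
  stopifnot(n_perm >= 99)
  des <- covariate_design(covariate)
  G <- gower_center(d)
  n <- ncol(G)
  set.seed(seed)
  perm_idx <- replicate(n_perm, sample.int(n))
  st <- permanova_trace_stats(G, des$H, des$q, perm_idx)
  p <- (1 + sum(st$F_perm >= st$F_obs - 1e-12)) / (1 + n_perm)
  structure(list(pseudo_F = st$F_obs, p_value = p, n_perm = n_perm,
                 covariate = unname(label["covariate"]),
                 distance = unname(label["distance"]), seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA %s ~ %s: pseudo-F = %.4g, p = %.4g (%d permutations, seed %d)\n",
              x$distance, x$covariate, x$pseudo_F, x$p_value, x$n_perm, x$seed))
  invisible(x)
}

#' Multi-distance omnibus PERMANOVA (PermanovaG)
#'
#' Combines PERMANOVA over several distance matrices on the same samples
#' (typically a family of generalized UniFrac distances at several alpha
#' values). The observed statistic is the minimum over matrices of the
#' per-matrix permutation p-value; its null distribution is built from the
#' SAME permutations applied jointly to all matrices, so dependence between
#' the matrices is respected.
#'
#' @param ds named list of symmetric distance matrices sharing the sample
#'   set (same ids, same order).
#' @param covariate as in [permanova()].
#' @param n_perm number of joint permutations.
#' @param seed integer seed.
#' @return object of class `permanova_g_result` with the per-matrix
#'   [permanova()]-style results and the omnibus p-value.
#' @export
permanova_g <- function(ds, covariate, n_perm = 9999, seed = 1) {
  stopifnot(is.list(ds), length(ds) >= 1)
  ds <- lapply(ds, function(d) drop_na_samples(as.matrix(d)))
  ids <- colnames(ds[[1]])
  for (d in ds[-1])
    if (!identical(colnames(d), ids)) stop("distance matrices have mismatched sample sets")
  covariate <- align_covariate(ds[[1]], covariate)
  des <- covariate_design(covariate)
  n <- length(ids)
  set.seed(seed)
  perm_idx <- replicate(n_perm, sample.int(n))
  N <- n_perm + 1
  per_matrix <- vector("list", length(ds))
  p_mat <- matrix(NA_real_, N, length(ds)) # pooled p of obs (row 1) and perms
  for (m in seq_along(ds)) {
    st <- permanova_trace_stats(gower_center(ds[[m]]), des$H, des$q, perm_idx)
    stats_all <- c(st$F_obs, st$F_perm)
    p_mat[, m] <- (N - rank(stats_all, ties.method = "min") + 1) / N
    per_matrix[[m]] <- structure(
      list(pseudo_F = st$F_obs,
           p_value = (1 + sum(st$F_perm >= st$F_obs - 1e-12)) / N,
           n_perm = n_perm,
           covariate = "covariate",
           distance = if (!is.null(names(ds))) names(ds)[m] else paste0("d", m),
           seed = seed),
      class = "permanova_result")
  }
  min_p <- apply(p_mat, 1, min)
  omnibus_p <- (1 + sum(min_p[-1] <= min_p[1] + 1e-15)) / N
  structure(list(per_matrix = per_matrix, omnibus_p = omnibus_p,
                 n_perm = n_perm, seed = seed),
            class = "permanova_g_result")
}

#' @export
print.permanova_g_result <- function(x, ...) {
  cat(sprintf("PermanovaG over %d distance matrices: omnibus p = %.4g (%d joint permutations)\n",
              length(x$per_matrix), x$omnibus_p, x$n_perm))
  for (r in x$per_matrix)
    cat(sprintf("  %-12s pseudo-F = %.4g, p = %.4g\n", r$distance, r$pseudo_F, r$p_value))
  invisible(x)
}
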