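#' Drop samples below a sequencing-depth threshold
#'
#' Samples are retained if they yielded at least `min_reads` sequences in
#' this amplicon ("at least" = inclusive boundary). The 200-read default is
#' the rule used for fungal ITS1 libraries; bacterial and archaeal tables
#' are conventionally filtered with `min_reads = 0` (no depth rule).
#'
#' @param counts a [count_table()].
#' @param min_reads inclusive minimum column sum (default 200).
#' @return list with `counts` (filtered [count_table()]) and `report`
#'   (a `filter_report` recording each dropped sample and the rule that
#'   triggered it).
#' @export
filter_samples_by_depth <- function(counts, min_reads = 200) {
  depth <- colSums(counts)
  keep <- depth >= min_reads
  if (!any(keep)) stop("empty result: all samples fall below the depth threshold")
  dropped <- data.frame(
    id = colnames(counts)[!keep],
    reason = sprintf("depth %d < min_reads %d", depth[!keep], min_reads),
    stringsAsFactors = FALSE)
  out <- count_table(counts[, keep, drop = FALSE], attr(counts, "domain"))
  list(counts = out,
       report = filter_report(dropped_samples = dropped,
                              thresholds = list(min_reads = min_reads)))
}

#' Drop rare genera
#'
#' A genus is kept iff it is present (count > 0) in at least
#' `min_prevalence` samples AND its total read count across samples is
#' greater than or equal to `min_total`. Both boundaries are inclusive.
#'
#' @param counts a [count_table()].
#' @param min_prevalence inclusive minimum number of positive samples
#'   (default 9, the rule used with 96 available samples).
#' @param min_total inclusive minimum total reads (default 10).
#' @return list with `counts` and `report`, as in
#'   [filter_samples_by_depth()].
#' @export
filter_genera <- function(counts, min_prevalence = 9, min_total = 10) {
  prev <- rowSums(counts > 0)
  tot <- rowSums(counts)
  keep <- prev >= min_prevalence & tot >= min_total
  if (!any(keep)) warning("no genus survives the prevalence/total filter")
  reason <- ifelse(prev[!keep] < min_prevalence,
                   sprintf("prevalence %d < min_prevalence %d", prev[!keep], min_prevalence),
                   sprintf("total %d < min_total %d", tot[!keep], min_total))
  dropped <- data.frame(id = rownames(counts)[!keep], reason = reason,
                        stringsAsFactors = FALSE)
  out <- count_table(counts[keep, , drop = FALSE], attr(counts, "domain"))
  list(counts = out,
       report = filter_report(dropped_genera = dropped,
                              thresholds = list(min_prevalence = min_prevalence,
                                                min_total = min_total)))
}

filter_report <- function(dropped_samples = empty_drop(), dropped_genera = empty_drop(),
                          thresholds = list()) {
  structure(list(dropped_samples = dropped_samples, dropped_genera = dropped_genera,
                 thresholds = thresholds,
                 order = "depth-filter -> proportions -> genus-filter"),
            class = "filter_report")
}

empty_drop <- function() data.frame(id = character(), reason = character(),
                                    stringsAsFactors = FALSE)

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>", nrow(x$dropped_samples), "samples and",
      nrow(x$dropped_genera), "genera dropped;",
      paste(names(x$thresholds), unlist(x$thresholds), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Convert counts to within-amplicon proportions
#'
#' Each sample column is divided by its own column sum, i.e. proportions
#' are computed within one amplicon (one Domain's sequencing study) at a
#' time. All-zero samples are left at zero and flagged in the
#' `empty_samples` attribute rather than producing NaN.
#'
#' @param counts a [count_table()].
#' @return a `proportion_table`: numeric matrix (genus x sample) with
#'   attributes `domain` and `empty_samples`.
#' @export
to_proportions <- function(counts) {
  depth <- colSums(counts)
  div <- ifelse(depth > 0, depth, 1)
  props <- sweep(unclass(counts) * 1.0, 2, div, "/")
  structure(props, domain = attr(counts, "domain"),
            empty_samples = colnames(counts)[depth == 0],
            class = c("proportion_table", "matrix", "array"))
}

#' @export
print.proportion_table <- function(x, ...) {
  cat(sprintf("<proportion_table> domain=%s: %d genera x %d samples (%d empty)\n",
              attr(x, "domain"), nrow(x), ncol(x), length(attr(x, "empty_samples"))))
  invisible(x)
}

subset_proportions <- function(props, genera = rownames(props), samples = colnames(props)) {
  structure(unclass(props)[genera, samples, drop = FALSE],
            domain = attr(props, "domain"),
            empty_samples = intersect(attr(props, "empty_samples"), samples),
            class = c("proportion_table", "matrix", "array"))
}
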