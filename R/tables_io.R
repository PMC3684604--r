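DOMAINS <- c("bacteria", "archaea", "fungi")
UNCLASSIFIED <- "unclassified"
DEFAULT_RANKS <- c("Phylum", "Class", "Order", "Family", "Genus")

#' Construct a validated genus-by-sample count table
#'
#' A count table holds non-negative integer marker-gene read counts for one
#' Domain of life (bacteria, archaea or fungi), with genera as rows and
#' samples as columns.
#'
#' @param counts integer matrix, genera in rows, samples in columns; must
#'   carry unique rownames (genus ids) and colnames (sample ids).
#' @param domain one of `"bacteria"`, `"archaea"`, `"fungi"`.
#' @return an object of class `count_table`: the integer matrix with a
#'   `domain` attribute.
#' @export
count_table <- function(counts, domain) {
  domain <- match.arg(domain, DOMAINS)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table needs genus rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate genus ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-integer or negative count at genus '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "integer"
  structure(counts, domain = domain, class = c("count_table", "matrix", "array"))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> domain=%s: %d genera x %d samples, %s reads\n",
              attr(x, "domain"), nrow(x), ncol(x),
              format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

genus_ids <- function(x) rownames(x)
sample_ids <- function(x) colnames(x)

#' Read a genus-by-sample count table from TSV
#'
#' Dialect: UTF-8 TSV, first column feature (genus) id, first row sample ids,
#' integer cells. Lines starting with `#` are provenance comments and are
#' skipped. Row and column order are preserved.
#'
#' @param path file path.
#' @param domain Domain of the table (`"bacteria"`, `"archaea"`, `"fungi"`).
#' @return a [count_table()].
#' @export
read_count_table <- function(path, domain) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs at least one sample column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (!is.numeric(m)) {
    suppressWarnings(m2 <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m)))
    bad <- which(is.na(m2) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-numeric cell at genus '%s', sample '%s' in %s",
                   rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], path))
    m <- m2
  }
  count_table(m, domain)
}

provenance_header <- function(params = list()) {
  kv <- if (length(params))
    paste(names(params), vapply(params, function(p) paste(format(p), collapse = ","), ""),
          sep = "=", collapse = " ") else ""
  sprintf("# tridomain %s | %s", as.character(utils::packageVersion("tridomain")), kv)
}

#' Write a count table as TSV (with a `#` provenance header line)
#' @param x a [count_table()].
#' @param path output file path.
#' @param params named list recorded in the provenance header.
#' @export
write_count_table <- function(x, path, params = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(c(list(domain = attr(x, "domain")), params)), con)
  writeLines(paste(c("genus_id", colnames(x)), collapse = "\t"), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a validated taxonomy table
#'
#' Each genus carries a ranked lineage of exactly `length(ranks)` labels
#' (default Phylum, Class, Order, Family, Genus). Missing labels are the
#' sentinel `"unclassified"`. For classified genera the terminal rank equals
#' the genus id.
#'
#' @param lineages character matrix, one row per genus (rownames = genus
#'   ids), one column per rank.
#' @param ranks rank names; defines lineage length L.
#' @return an object of class `taxonomy_table`.
#' @export
taxonomy_table <- function(lineages, ranks = DEFAULT_RANKS) {
  lineages <- as.matrix(lineages)
  if (ncol(lineages) != length(ranks))
    stop(sprintf("lineage length %d != number of ranks %d", ncol(lineages), length(ranks)))
  if (is.null(rownames(lineages))) stop("taxonomy needs genus rownames")
  if (anyDuplicated(rownames(lineages))) stop("duplicate genus ids in taxonomy")
  lineages[is.na(lineages) | !nzchar(trimws(lineages))] <- UNCLASSIFIED
  colnames(lineages) <- ranks
  structure(lineages, class = c("taxonomy_table", "matrix", "array"))
}

#' Read a taxonomy table (genus_id + one column per rank) from TSV
#' @param path file path.
#' @param ranks rank schema (default 5 ranks, Phylum..Genus).
#' @return a [taxonomy_table()]. Blank or missing rank cells become
#'   `"unclassified"`.
#' @export
read_taxonomy <- function(path, ranks = DEFAULT_RANKS) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 1 + length(ranks))
    stop(sprintf("taxonomy file must have genus_id + %d rank columns", length(ranks)))
  m <- as.matrix(df[, 2:(1 + length(ranks)), drop = FALSE])
  rownames(m) <- df[[1]]
  taxonomy_table(m, ranks)
}

#' Write a taxonomy table as TSV
#' @param x a [taxonomy_table()].
#' @param path output file path.
#' @export
write_taxonomy <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(), con)
  writeLines(paste(c("genus_id", colnames(x)), collapse = "\t"), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a nutrient inventory table
#'
#' Samples by nutrients, real valued. `inventory` distinguishes the usual
#' (food-frequency questionnaire, long-term) panel from the recent (recall)
#' panel. Constant-valued nutrient columns are flagged because they break
#' rank correlation.
#'
#' @param values numeric matrix, samples in rows, nutrients in columns.
#' @param inventory `"usual"` or `"recent"`.
#' @return object of class `nutrient_table` with attributes `inventory` and
#'   `constant_nutrients`.
#' @export
nutrient_table <- function(values, inventory = c("usual", "recent")) {
  inventory <- match.arg(inventory)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("nutrient table needs sample rownames and nutrient colnames")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicate sample or nutrient ids")
  if (any(!is.finite(values))) stop("non-finite nutrient values")
  const <- colnames(values)[apply(values, 2, function(v) max(v) - min(v) == 0)]
  structure(values, inventory = inventory, constant_nutrients = const,
            class = c("nutrient_table", "matrix", "array"))
}

#' Read a nutrient inventory (samples x nutrients) from CSV
#' @param path file path; first column sample id, remaining columns nutrients.
#' @param inventory `"usual"` or `"recent"`.
#' @return a [nutrient_table()].
#' @export
read_nutrient_table <- function(path, inventory = c("usual", "recent")) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  nutrient_table(m, inventory)
}

#' Write a nutrient inventory as CSV
#' @param x a [nutrient_table()].
#' @param path output file path.
#' @export
write_nutrient_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate an OTU-level count table to genus level
#'
#' OTUs with fewer than `min_otu_total` reads summed across all samples are
#' dropped before aggregation. Surviving OTUs are summed into the genus
#' named by the terminal rank of their lineage; lineages unclassified at
#' genus level are pooled into an `Other_<lowest classified rank>` bucket
#' (e.g. `Other_Ascomycota` when only the phylum is known).
#'
#' @param otu_counts [count_table()]-like matrix of OTU x sample counts
#'   (rownames = OTU ids).
#' @param otu_taxonomy [taxonomy_table()] keyed by OTU id.
#' @param domain Domain of the table.
#' @param min_otu_total minimum total reads for an OTU to be retained
#'   (default 5).
#' @return a [count_table()] at genus level.
#' @export
aggregate_otus_to_genus <- function(otu_counts, otu_taxonomy, domain,
                                    min_otu_total = 5) {
  m <- as.matrix(otu_counts)
  missing <- setdiff(rownames(m), rownames(otu_taxonomy))
  if (length(missing))
    stop("OTUs without taxonomy entry: ", paste(missing, collapse = ", "))
  keep <- rowSums(m) >= min_otu_total
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) stop("no OTU survives the minimum-total filter")
  lin <- otu_taxonomy[rownames(m), , drop = FALSE]
  L <- ncol(lin)
  bucket <- vapply(seq_len(nrow(lin)), function(i) {
    lv <- lin[i, ]
    if (lv[L] != UNCLASSIFIED) return(lv[L])
    classified <- which(lv != UNCLASSIFIED)
    if (length(classified) == 0) return("Other_unclassified")
    paste0("Other_", lv[max(classified)])
  }, character(1))
  agg <- rowsum(m, group = bucket, reorder = FALSE)
  count_table(agg, domain)
}
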