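# Single-sample plasticity scoring: probe collapsing, per-gene
# z-normalization, +/-1 weighted averaging, and sign-based classification.

#' Validate a probe-to-gene map
#'
#' @param df Data frame with columns `probe_id`, `gene_id`; each probe must
#'   map to exactly one gene (many probes per gene are allowed).
#' @return The validated data frame, classed `probe_gene_map`.
#' @export
probe_gene_map <- function(df) {
  need <- c("probe_id", "gene_id")
  if (!all(need %in% names(df)))
    validation_error("probe map needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$probe_id))
    validation_error("a probe maps to more than one gene")
  df <- df[, need]
  class(df) <- c("probe_gene_map", "data.frame")
  df
}

#' Collapse probes to genes by maximal variance
#'
#' When several probes measure one gene, the probe with the highest
#' across-sample variance (unbiased, n-1 denominator) represents the gene.
#' Ties are broken by the lexicographically smallest probe id.
#'
#' @param x An [expression_matrix()] at probe level.
#' @param map A [probe_gene_map()] covering every feature of `x`.
#' @return A gene-level `expr_matrix` (rows named by gene id, same scale),
#'   with the chosen probe per gene in attribute `selected_probes`.
#' @export
collapse_probes <- function(x, map) {
  stopifnot(inherits(x, "expr_matrix"))
  map <- probe_gene_map(map)
  missing <- setdiff(feature_ids(x), map$probe_id)
  if (length(missing))
    validation_error("probes without gene mapping: ", paste(missing, collapse = ", "))
  v <- apply(x$values, 1L, stats::var)
  gene <- map$gene_id[match(feature_ids(x), map$probe_id)]
  chosen <- vapply(split(feature_ids(x), gene), function(probes) {
    probes <- sort(probes)                      # lexicographic tie-break
    probes[which.max(v[probes])]
  }, character(1L))
  out <- x$values[chosen, , drop = FALSE]
  rownames(out) <- names(chosen)
  res <- expression_matrix(out, x$scale)
  attr(res, "selected_probes") <- chosen
  res
}

#' Z-normalize each gene across samples
#'
#' Transforms every row to mean 0 and unbiased sample variance 1 across the
#' data set being scored. Constant rows (zero variance) are dropped with a
#' warning, since their z-score is undefined.
#'
#' @param x An [expression_matrix()] with >= 2 samples.
#' @return An `expr_matrix` of z-scores (scale flag `"log2"`, i.e. analysis
#'   scale).
#' @export
zscore_rows <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (ncol(x$values) < 2L) abort("z-normalization needs >= 2 samples")
  m <- rowMeans(x$values)
  s <- apply(x$values, 1L, stats::sd)
  const <- s == 0
  if (any(const)) {
    warning(sprintf("dropping %d constant gene(s) before scoring: %s",
                    sum(const),
                    paste(utils::head(feature_ids(x)[const], 5L), collapse = ", ")),
            call. = FALSE)
  }
  if (all(const)) abort("all genes constant; nothing to score")
  z <- (x$values[!const, , drop = FALSE] - m[!const]) / s[!const]
  expression_matrix(z, "log2")
}

#' Score samples against a signed signature
#'
#' The plasticity score of a sample is the mean of its z-scores over the
#' signature genes present in the matrix, with up genes weighted +1 and down
#' genes -1. Signature genes absent from the matrix are skipped and counted.
#'
#' @param z A z-scored gene-level [expression_matrix()] (see [zscore_rows()]).
#' @param signature A [gene_signature()] in the matrix's gene namespace.
#' @return A data frame of class `score_set` with columns `sample_id`,
#'   `signature`, `score`, `n_genes_used`; attribute `n_genes_missing` counts
#'   skipped signature genes.
#' @export
score_signature <- function(z, signature) {
  stopifnot(inherits(z, "expr_matrix"), inherits(signature, "gene_signature"))
  up <- intersect(signature$up, feature_ids(z))
  down <- intersect(signature$down, feature_ids(z))
  n_used <- length(up) + length(down)
  if (n_used == 0L)
    abort("no signature genes of '", signature$name, "' present in the matrix")
  total <- colSums(z$values[up, , drop = FALSE]) -
    colSums(z$values[down, , drop = FALSE])
  out <- data.frame(sample_id = sample_ids(z), signature = signature$name,
                    score = as.numeric(total) / n_used, n_genes_used = n_used,
                    stringsAsFactors = FALSE)
  attr(out, "n_genes_missing") <-
    length(signature$up) + length(signature$down) - n_used
  class(out) <- c("score_set", "data.frame")
  out
}

#' Classify metastatic competence from plasticity scores
#'
#' A strictly positive plasticity (E6.5-type) score calls a sample
#' metastatic-competent; zero or negative calls it non-competent.
#'
#' @param score_set A `score_set` from [score_signature()].
#' @return The score set with an added `label` column
#'   (`"metastatic-competent"` / `"non-competent"`).
#' @export
classify_metastatic <- function(score_set) {
  stopifnot(inherits(score_set, "score_set"))
  score_set$label <- ifelse(score_set$score > 0,
                            "metastatic-competent", "non-competent")
  score_set
}

#' Write a score set as TSV
#' @param score_set A `score_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(score_set, path) {
  utils::write.table(score_set, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
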