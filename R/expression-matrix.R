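#' Construct an expression matrix
#'
#' The package's central container: a numeric features-by-samples matrix with
#' unique row (feature) and column (sample) identifiers and a scale flag
#' recording whether values are raw linear intensities (`"linear"`, all
#' non-negative) or on the log2/analysis scale (`"log2"`, e.g. logged
#' intensities or z-scores).
#'
#' @param values Numeric matrix, rows = features, columns = samples, with
#'   complete `dimnames`.
#' @param scale Either `"linear"` or `"log2"`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `scale`.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' em <- expression_matrix(m, "linear")
#' feature_ids(em)
#' @export
expression_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    validation_error("`values` must be a numeric matrix")
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    validation_error("expression matrix requires feature and sample ids as dimnames")
  if (anyDuplicated(fid))
    validation_error("duplicate feature ids: ",
                     paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (anyDuplicated(sid))
    validation_error("duplicate sample ids: ",
                     paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (any(!is.finite(values)))
    validation_error("expression values must be finite (no NA/NaN/Inf)")
  if (scale == "linear" && any(values < 0))
    validation_error("linear-scale expression values must be >= 0")
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @rdname expression_matrix
#' @param x An `expr_matrix`.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an expression matrix by sample ids
#'
#' @param x An `expr_matrix`.
#' @param samples Character vector of sample ids to keep (order preserved).
#' @return An `expr_matrix` restricted to `samples`.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "expr_matrix"))
  missing <- setdiff(samples, sample_ids(x))
  if (length(missing))
    validation_error("samples not in matrix: ", paste(missing, collapse = ", "))
  expression_matrix(x$values[, samples, drop = FALSE], x$scale)
}

#' Read a tab-delimited expression matrix
#'
#' Expects the dialect used by series-matrix-style exports: UTF-8, tab
#' separated, no quoting, a header row whose first cell is ignored and whose
#' remaining cells are sample ids, and one row per feature with the feature id
#' in the first column. Missing values (`NA` or empty cells) are rejected
#' rather than imputed.
#'
#' @param path File to read.
#' @param scale Declared scale of the stored values (`"linear"` or `"log2"`).
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) abort("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) parse_error("expression TSV needs a header and >= 1 data row: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) parse_error("header row has no sample columns: ", path)
  sid <- header[-1L]
  n <- length(sid)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  fid <- character(length(rows))
  values <- matrix(NA_real_, length(rows), n)
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != n + 1L)
      parse_error(sprintf("line %d: expected %d fields, found %d", i + 1L, n + 1L, length(f)))
    fid[i] <- f[1L]
    v <- suppressWarnings(as.numeric(f[-1L]))
    bad <- which(is.na(v))
    if (length(bad))
      parse_error(sprintf("line %d: non-numeric or missing value '%s' in column %d",
                          i + 1L, f[-1L][bad[1L]], bad[1L] + 1L))
    values[i, ] <- v
  }
  if (anyDuplicated(fid))
    validation_error("duplicate feature ids in ", path, ": ",
                     paste(unique(fid[duplicated(fid)]), collapse = ", "))
  dimnames(values) <- list(fid, sid)
  expression_matrix(values, scale)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_tsv()]; numeric values are written with enough
#' digits that a round trip preserves them to better than 1e-12.
#'
#' @param x An `expr_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("feature_id", sample_ids(x)), collapse = "\t"), con)
  body <- apply(x$values, 1L, function(v) paste(format_num(v), collapse = "\t"))
  writeLines(paste(feature_ids(x), body, sep = "\t"), con)
  invisible(path)
}
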