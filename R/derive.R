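# Atlas filtering, log2 transform, moderated two-group differential
# expression with empirical-Bayes variance shrinkage, and fold-change/FDR
# signature selection.

#' Filter atlas samples before signature derivation
#'
#' Drops cell-line and stimulated samples, and undeveloped-tissue samples
#' unless they carry an embryonic stage between E6.5 and E10.5 (staged embryos
#' are undeveloped tissue but are the point of the contrast). All adult tissue
#' samples without exclusion flags are retained.
#'
#' @param annotation A [sample_annotation()] data frame.
#' @return Character vector of retained sample ids.
#' @export
filter_atlas_samples <- function(annotation) {
  annotation <- sample_annotation(annotation)
  staged <- annotation$embryonic_stage %in% EMBRYONIC_STAGES
  keep <- !annotation$is_cell_line & !annotation$is_stimulated &
    (!annotation$is_undeveloped | staged)
  ids <- annotation$sample_id[keep]
  if (!length(ids)) abort("no samples retained after atlas filtering")
  ids
}

#' Log2-transform a linear-scale expression matrix
#'
#' @param x A linear-scale [expression_matrix()].
#' @param pseudocount Non-negative offset added before taking log2. The
#'   default 0 assumes strictly positive intensities.
#' @return An `expr_matrix` on the log2 scale.
#' @export
log2_transform <- function(x, pseudocount = 0) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "linear")
    validation_error("matrix is already on the log2 scale")
  if (!is_number(pseudocount) || pseudocount < 0)
    validation_error("pseudocount must be >= 0")
  if (any(x$values < 0)) validation_error("negative values cannot be log-transformed")
  if (pseudocount == 0 && any(x$values == 0))
    validation_error("zero values require a positive pseudocount")
  expression_matrix(log2(x$values + pseudocount), "log2")
}

# Newton inversion of the trigamma function (y = trigamma(x), y > 0),
# monotone decreasing so the iteration converges from any positive start.
trigamma_inverse <- function(y) {
  stopifnot(is_number(y), y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-12) break
  }
  x
}

#' Moderated two-group differential expression
#'
#' Fits, per feature, the two-group difference of means on log2 data, then
#' shrinks the per-feature residual variance `s2` (pooled, `df = n_a + n_b -
#' 2` degrees of freedom) toward a prior variance `s0_sq` with prior degrees
#' of freedom `d0`, estimated by matching the first two moments of `log(s2)`
#' to a scaled-F model: with `e = log(s2) - digamma(df/2) + log(df/2)`,
#' `trigamma(d0/2) = var(e) - trigamma(df/2)` (inverted numerically; `d0 =
#' Inf` when the right side is non-positive) and `s0_sq = exp(mean(e) +
#' digamma(d0/2) - log(d0/2))`. The posterior variance is `s_tilde_sq = (d0 *
#' s0_sq + df * s2) / (d0 + df)` and the moderated t-statistic
#' `log2fc / sqrt(s_tilde_sq * (1/n_a + 1/n_b))` is referred to a t
#' distribution on `d0 + df` degrees of freedom (two-sided p, BH-adjusted q).
#'
#' Features with zero residual variance are excluded from hyperparameter
#' estimation (their log variance is undefined) but still receive a posterior
#' variance and test.
#'
#' @param x A log2-scale [expression_matrix()].
#' @param group_a_ids,group_b_ids Disjoint sample-id vectors, each >= 2.
#' @return An object of class `moderated_fit`: list with `table` (data frame:
#'   `feature_id`, `mean_a`, `mean_b`, `log2fc`, `s2`, `df`, `t_ordinary`,
#'   `t_moderated`, `p_value`, `q_value`) and `params` (`d0`, `s0_sq`,
#'   `df_residual`, `n_a`, `n_b`).
#' @export
fit_moderated_two_group <- function(x, group_a_ids, group_b_ids) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "log2") validation_error("moderated fit requires a log2-scale matrix")
  group_a_ids <- as.character(group_a_ids)
  group_b_ids <- as.character(group_b_ids)
  if (length(intersect(group_a_ids, group_b_ids)))
    validation_error("groups overlap")
  missing <- setdiff(c(group_a_ids, group_b_ids), sample_ids(x))
  if (length(missing))
    validation_error("samples not in matrix: ", paste(missing, collapse = ", "))
  n_a <- length(group_a_ids); n_b <- length(group_b_ids)
  if (n_a < 2L || n_b < 2L) abort("each group needs >= 2 samples")

  xa <- x$values[, group_a_ids, drop = FALSE]
  xb <- x$values[, group_b_ids, drop = FALSE]
  mean_a <- rowMeans(xa)
  mean_b <- rowMeans(xb)
  df <- n_a + n_b - 2L
  s2 <- (rowSums((xa - mean_a)^2) + rowSums((xb - mean_b)^2)) / df
  if (all(s2 == 0)) abort("zero residual variance for all features; shrinkage prior undefined")

  ok <- s2 > 0
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- if (length(e) >= 2L) stats::var(e) else 0
  excess <- evar - trigamma(df / 2)
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }

  s_tilde_sq <- if (is.finite(d0)) (d0 * s0_sq + df * s2) / (d0 + df) else rep(s0_sq, length(s2))
  se_factor <- sqrt(1 / n_a + 1 / n_b)
  log2fc <- mean_a - mean_b
  t_ordinary <- log2fc / (sqrt(s2) * se_factor)
  t_moderated <- log2fc / (sqrt(s_tilde_sq) * se_factor)
  p <- 2 * stats::pt(-abs(t_moderated), df = d0 + df)
  tab <- data.frame(feature_id = feature_ids(x), mean_a = mean_a, mean_b = mean_b,
                    log2fc = log2fc, s2 = s2, df = df, t_ordinary = t_ordinary,
                    t_moderated = t_moderated, p_value = p,
                    q_value = bh_adjust(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 params = list(d0 = d0, s0_sq = s0_sq, df_residual = df,
                               n_a = n_a, n_b = n_b)),
            class = "moderated_fit")
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("moderated_fit: %d features, %d vs %d samples, d0 = %.4g, s0_sq = %.4g\n",
              nrow(x$table), x$params$n_a, x$params$n_b, x$params$d0, x$params$s0_sq))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity; input order preserved.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0) || any(p_values > 1))
    validation_error("p-values must be numbers in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Select a signed signature from a differential-expression fit
#'
#' A feature enters the up set when `q_value < fdr_threshold` and
#' `log2fc >= log2(fold_threshold)`, and the down set when the fold change is
#' below `-log2(fold_threshold)` at the same FDR. The FDR cut is strict.
#'
#' @param fit A `moderated_fit`.
#' @param fold_threshold Linear fold-change threshold (> 1 scale, default 5).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return List with character vectors `up` and `down`.
#' @export
select_signature <- function(fit, fold_threshold = 5, fdr_threshold = 0.05) {
  stopifnot(inherits(fit, "moderated_fit"))
  if (!is_number(fold_threshold) || fold_threshold <= 0)
    validation_error("fold_threshold must be > 0")
  if (!is_number(fdr_threshold) || fdr_threshold <= 0)
    validation_error("fdr_threshold must be > 0")
  tab <- fit$table
  lfc <- log2(fold_threshold)
  sig <- tab$q_value < fdr_threshold
  list(up = tab$feature_id[sig & tab$log2fc >= lfc],
       down = tab$feature_id[sig & tab$log2fc <= -lfc])
}

# Build contrast groups from a filtered annotation; errors name any stage
# that is required but empty.
contrast_groups <- function(annotation, contrast = c("e65", "adult")) {
  contrast <- match.arg(contrast)
  stage <- annotation$embryonic_stage
  for (st in c("E6.5", "E7.5", "E9.5", "E10.5"))
    if (!any(stage == st)) abort("no samples for stage ", st, " after filtering")
  if (!any(annotation$sample_class == "adult"))
    abort("no adult samples after filtering")
  if (contrast == "e65") {
    list(a = annotation$sample_id[stage %in% c("E6.5", "E7.5")],
         b = annotation$sample_id[stage %in% c("E9.5", "E10.5") |
                                    annotation$sample_class == "adult"])
  } else {
    list(a = annotation$sample_id[annotation$sample_class == "adult"],
         b = annotation$sample_id[stage %in% c("E6.5", "E7.5", "E9.5", "E10.5")])
  }
}

#' Derive the early-embryonic (E6.5) and adult stage signatures
#'
#' Runs the full derivation chain on a staged atlas: sample filtering, log2
#' transform (if the matrix is linear), then for each of two contrasts a
#' moderated two-group fit, BH adjustment and fold/FDR selection. The E6.5
#' contrast compares E6.5+E7.5 against E9.5+E10.5+adult; the adult contrast
#' compares adult tissues against all four retained embryonic stages. E8.5 is
#' omitted from both contrasts as a transition stage.
#'
#' @param x An [expression_matrix()] (linear or log2 scale).
#' @param annotation A [sample_annotation()] covering the matrix samples.
#' @param fold_threshold,fdr_threshold Selection thresholds, see
#'   [select_signature()].
#' @param pseudocount Passed to [log2_transform()] when `x` is linear.
#' @return A list with `e65` and `adult` ([gene_signature()] objects, or
#'   `NULL` when a contrast selects no genes) and `fits` (the two
#'   `moderated_fit` objects).
#' @export
derive_stage_signatures <- function(x, annotation, fold_threshold = 5,
                                    fdr_threshold = 0.05, pseudocount = 0) {
  stopifnot(inherits(x, "expr_matrix"))
  annotation <- sample_annotation(annotation)
  keep <- intersect(filter_atlas_samples(annotation), sample_ids(x))
  if (!length(keep)) abort("no annotated samples present in the matrix")
  ann <- annotation[match(keep, annotation$sample_id), ]
  x <- subset_samples(x, keep)
  if (x$scale == "linear") x <- log2_transform(x, pseudocount)

  out <- list(e65 = NULL, adult = NULL, fits = list())
  for (ct in c("e65", "adult")) {
    grp <- contrast_groups(ann, ct)
    fit <- fit_moderated_two_group(x, grp$a, grp$b)
    sel <- select_signature(fit, fold_threshold, fdr_threshold)
    out$fits[[ct]] <- fit
    if (length(sel$up) + length(sel$down) > 0L) {
      prov <- sprintf("%s contrast: fold >= %g, FDR < %g, d0 = %.6g, s0_sq = %.6g",
                      ct, fold_threshold, fdr_threshold,
                      fit$params$d0, fit$params$s0_sq)
      out[[ct]] <- gene_signature(if (ct == "e65") "E6.5" else "adult",
                                  up = sel$up, down = sel$down,
                                  species = "mouse", provenance = prov)
    }
  }
  out
}
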