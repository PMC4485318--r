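# Kaplan-Meier estimation, two-group log-rank testing, score-based
# discretization and the time-to-10%-events group comparison. The estimators
# are computed with the survival package behind this module's interface.

#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator; at tied times events precede censorings,
#' and censored subjects leave the risk set after their censoring time.
#'
#' @param records A [survival_records()] data frame (>= 1 row).
#' @return An object of class `km_estimate`: list with vectors `time`
#'   (distinct event times, increasing), `n_risk`, `n_event` and `survival`
#'   (S at each event time; S(0) = 1 implicitly), plus `n` and `n_events`.
#' @export
km_estimate <- function(records) {
  records <- survival_records(as.data.frame(records))
  if (!nrow(records)) abort("no survival records")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  keep <- fit$n.event > 0
  structure(list(time = fit$time[keep], n_risk = fit$n.risk[keep],
                 n_event = fit$n.event[keep], survival = fit$surv[keep],
                 n = nrow(records), n_events = sum(records$event)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("km_estimate: %d subjects, %d events at %d distinct times\n",
              x$n, x$n_events, length(x$time)))
  invisible(x)
}

#' Plot a Kaplan-Meier estimate as a step function
#' @param x A `km_estimate`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.km_estimate <- function(x, ...) {
  graphics::plot(c(0, x$time), c(1, x$survival), type = "s", ylim = c(0, 1),
                 xlab = "time", ylab = "survival", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' At each distinct event time the expected per-group events and their
#' hypergeometric variance are accumulated; the statistic
#' `(O - E)^2 / V` is referred to a chi-square distribution on 1 degree of
#' freedom.
#'
#' @param records_a,records_b [survival_records()] for the two groups (each
#'   non-empty; at least one event overall).
#' @return An object of class `logrank_result`: `chi_square`, `df` (= 1),
#'   `p_value`, and per-group `observed`/`expected` event counts (named `a`,
#'   `b`).
#' @export
logrank_test <- function(records_a, records_b) {
  records_a <- survival_records(as.data.frame(records_a))
  records_b <- survival_records(as.data.frame(records_b))
  if (!nrow(records_a) || !nrow(records_b)) abort("both groups must be non-empty")
  if (sum(records_a$event) + sum(records_b$event) == 0L)
    abort("log-rank statistic undefined: no events in either group")
  df <- rbind(cbind(records_a, group = "a"), cbind(records_b, group = "b"))
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  v <- sd_fit$var[1L, 1L]
  if (!is.finite(v) || v <= 0)
    abort("log-rank statistic undefined: zero variance")
  chi <- sd_fit$chisq
  structure(list(chi_square = chi, df = 1L,
                 p_value = stats::pchisq(chi, df = 1L, lower.tail = FALSE),
                 observed = stats::setNames(as.numeric(sd_fit$obs), c("a", "b")),
                 expected = stats::setNames(as.numeric(sd_fit$exp), c("a", "b"))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi-square = %.4g (1 df), p = %.4g\n",
              x$chi_square, x$p_value))
  invisible(x)
}

#' Discretize patients into high/low groups by score
#'
#' `method = "median"` assigns scores above the cohort median to `high` and
#' the rest to `low` (balanced up to median ties); `method = "sign"` splits at
#' zero.
#'
#' @param score_set A `score_set` with >= 2 patients.
#' @param method `"median"` or `"sign"`.
#' @return Named character vector (`"high"`/`"low"`), names = sample ids.
#' @export
discretize_by_score <- function(score_set, method = c("median", "sign")) {
  method <- match.arg(method)
  stopifnot(inherits(score_set, "score_set"))
  s <- score_set$score
  if (length(s) < 2L) abort("discretization needs >= 2 patients")
  if (diff(range(s)) == 0) abort("all scores identical; no high/low split exists")
  cut <- if (method == "median") stats::median(s) else 0
  stats::setNames(ifelse(s > cut, "high", "low"), score_set$sample_id)
}

#' Time until a given fraction of patients has acquired the outcome
#'
#' The earliest observed event time at which the Kaplan-Meier survival falls
#' to `1 - fraction` or below; `NA` ("not reached") if survival never falls
#' that low.
#'
#' @param km A `km_estimate`.
#' @param fraction Outcome fraction in (0, 1); default 0.10, the 10%-event
#'   comparison point used for sparse-event cancer cohorts.
#' @return A time, or `NA_real_` if not reached.
#' @export
time_to_fraction <- function(km, fraction = 0.10) {
  stopifnot(inherits(km, "km_estimate"))
  if (!is_number(fraction) || fraction <= 0 || fraction >= 1)
    abort("fraction must lie strictly between 0 and 1")
  idx <- which(km$survival <= 1 - fraction)
  if (!length(idx)) NA_real_ else km$time[min(idx)]
}

#' Score-stratified survival analysis of one cohort
#'
#' Chains the scoring and survival machinery for one endpoint: restrict the
#' records to the endpoint and to patients present in the matrix, z-normalize
#' the cohort's genes, score the signature (a single-gene signature realizes
#' single-gene analyses), discretize into high/low groups, then compare the
#' groups by Kaplan-Meier curves, the log-rank test, and the
#' time-to-`fraction` statistic per group.
#'
#' @param gene_matrix Gene-level [expression_matrix()] of the cohort.
#' @param clinical_records A [survival_records()] data frame.
#' @param signature A [gene_signature()] matching the matrix namespace.
#' @param endpoint `"DMFS"` or `"RFS"`.
#' @param discretize_method Passed to [discretize_by_score()].
#' @param fraction Passed to [time_to_fraction()].
#' @return An object of class `outcome_analysis`: group sizes, `t10_high`,
#'   `t10_low`, `delta_t10` (= t10 low - t10 high; `NA` when either is not
#'   reached), `logrank`, per-group `km` estimates, `scores` and the `groups`
#'   assignment.
#' @export
run_outcome_analysis <- function(gene_matrix, clinical_records, signature,
                                 endpoint = c("DMFS", "RFS"),
                                 discretize_method = c("median", "sign"),
                                 fraction = 0.10) {
  endpoint <- match.arg(endpoint)
  discretize_method <- match.arg(discretize_method)
  stopifnot(inherits(gene_matrix, "expr_matrix"))
  records <- survival_records(as.data.frame(clinical_records))
  records <- records[records$endpoint == endpoint, ]
  common <- intersect(sample_ids(gene_matrix), records$sample_id)
  if (length(common) < 4L)
    abort("need >= 4 patients with both expression and ", endpoint, " follow-up")
  records <- records[match(common, records$sample_id), ]

  z <- zscore_rows(subset_samples(gene_matrix, common))
  scores <- score_signature(z, signature)
  groups <- discretize_by_score(scores, discretize_method)
  rec_high <- records[groups[records$sample_id] == "high", ]
  rec_low <- records[groups[records$sample_id] == "low", ]
  if (nrow(rec_high) < 2L || nrow(rec_low) < 2L)
    abort("fewer than 2 patients in a score group; cannot compare")

  km_high <- km_estimate(rec_high)
  km_low <- km_estimate(rec_low)
  t10_high <- time_to_fraction(km_high, fraction)
  t10_low <- time_to_fraction(km_low, fraction)
  structure(list(endpoint = endpoint, signature_name = signature$name,
                 fraction = fraction,
                 n_high = nrow(rec_high), n_low = nrow(rec_low),
                 t10_high = t10_high, t10_low = t10_low,
                 delta_t10 = t10_low - t10_high,
                 logrank = logrank_test(rec_high, rec_low),
                 km = list(high = km_high, low = km_low),
                 scores = scores, groups = groups),
            class = "outcome_analysis")
}

#' @export
print.outcome_analysis <- function(x, ...) {
  fmt_t <- function(t) if (is.na(t)) "not reached" else sprintf("%.3g", t)
  cat(sprintf("%s stratification by '%s': %d high vs %d low\n", x$endpoint,
              x$signature_name, x$n_high, x$n_low))
  cat(sprintf("  time to %.0f%% events: high %s, low %s (delta %s)\n",
              100 * x$fraction, fmt_t(x$t10_high), fmt_t(x$t10_low),
              fmt_t(x$delta_t10)))
  cat(sprintf("  log-rank chi-square = %.4g, p = %.4g\n",
              x$logrank$chi_square, x$logrank$p_value))
  invisible(x)
}

#' Write a group comparison and KM curves as TSV
#'
#' @param analysis An `outcome_analysis`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_outcome_tsv <- function(analysis, dir, prefix = "outcome") {
  stopifnot(inherits(analysis, "outcome_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cmp <- data.frame(endpoint = analysis$endpoint,
                    signature = analysis$signature_name,
                    n_high = analysis$n_high, n_low = analysis$n_low,
                    t10_high = analysis$t10_high, t10_low = analysis$t10_low,
                    delta_t10 = analysis$delta_t10,
                    chi_square = analysis$logrank$chi_square,
                    p_value = analysis$logrank$p_value)
  p1 <- file.path(dir, paste0(prefix, "_comparison.tsv"))
  utils::write.table(cmp, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  curves <- do.call(rbind, lapply(names(analysis$km), function(g) {
    k <- analysis$km[[g]]
    if (!length(k$time)) return(NULL)
    data.frame(group = g, time = k$time, survival = k$survival,
               n_risk = k$n_risk, n_event = k$n_event)
  }))
  p2 <- file.path(dir, paste0(prefix, "_km.tsv"))
  utils::write.table(curves, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
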