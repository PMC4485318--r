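# Atlas filtering, log2 transform, moderated differential expression and
# signature selection.

test_that("atlas filtering applies the exclusion rules", {
  df <- data.frame(
    sample_id = c("cl", "stim", "e75", "liver", "undev"),
    tissue_name = c("line", "spleen", "E7.5", "liver", "residue"),
    sample_class = c("adult", "adult", "embryo", "adult", "adult"),
    embryonic_stage = c("none", "none", "E7.5", "none", "none"),
    is_cell_line = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    is_stimulated = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    is_undeveloped = c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_setequal(filter_atlas_samples(sample_annotation(df)), c("e75", "liver"))

  all_lines <- df
  all_lines$is_cell_line <- TRUE
  all_lines$is_undeveloped <- FALSE
  all_lines$is_stimulated <- FALSE
  all_lines$sample_class <- "adult"
  all_lines$embryonic_stage <- "none"
  expect_error(filter_atlas_samples(sample_annotation(all_lines)), "no samples")
})

test_that("log2 transform handles pseudocounts and rejects log2 input", {
  m <- matrix(c(8, 0, 1, 3), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  em <- expression_matrix(m, "linear")
  out <- log2_transform(em, pseudocount = 1)
  expect_equal(out$values["g1", "a"], log2(9))
  expect_equal(out$values["g2", "a"], 0)  # log2(0 + 1)
  expect_identical(out$scale, "log2")

  m2 <- matrix(c(8, 2, 1, 4), 2, 2, dimnames = dimnames(m))
  expect_equal(log2_transform(expression_matrix(m2, "linear"))$values["g1", "a"], 3)
  expect_error(log2_transform(out), "already")
  expect_error(log2_transform(em, pseudocount = 0), "zero values")
})

test_that("moderated fit matches the step-by-step moment-matching oracle", {
  # heteroskedastic per-gene variances so the prior df is finite
  vals <- withr::with_seed(101, {
    sds <- sqrt(rchisq(50, df = 3) / 3)
    matrix(rnorm(50 * 6, sd = rep(sds, 6)), 50, 6,
           dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:6))) +
      c(rep(2, 10), rep(0, 40))
  })
  em <- expression_matrix(vals, "log2")
  fit <- fit_moderated_two_group(em, c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  orc <- oracle_moderated_fit(vals, c("s1", "s2", "s3"), c("s4", "s5", "s6"))

  expect_equal(fit$params$d0, orc$d0, tolerance = 1e-8)
  expect_equal(fit$params$s0_sq, orc$s0_sq, tolerance = 1e-8)
  expect_equal(fit$table$log2fc, unname(orc$log2fc), tolerance = 1e-12)
  expect_equal(fit$table$s2, unname(orc$s2), tolerance = 1e-12)
  expect_equal(fit$table$t_moderated, unname(orc$t_moderated), tolerance = 1e-8)
  expect_equal(fit$table$p_value, unname(orc$p_value), tolerance = 1e-8)
})

test_that("moderated fit agrees with an independent reference implementation", {
  skip_if_not_installed("limma")
  vals <- withr::with_seed(202, {
    sds <- sqrt(rchisq(80, df = 5) / 5)
    matrix(rnorm(80 * 9, sd = rep(sds, 9)), 80, 9,
           dimnames = list(sprintf("g%02d", 1:80), sprintf("s%d", 1:9)))
  })
  em <- expression_matrix(vals, "log2")
  a <- sprintf("s%d", 1:4); b <- sprintf("s%d", 5:9)
  fit <- fit_moderated_two_group(em, a, b)
  design <- cbind(intercept = 1, grp = colnames(vals) %in% a)
  ref <- limma::eBayes(limma::lmFit(vals, design))
  expect_equal(fit$params$d0, ref$df.prior, tolerance = 1e-9)
  expect_equal(fit$params$s0_sq, ref$s2.prior, tolerance = 1e-9)
  expect_equal(fit$table$t_moderated, unname(ref$t[, "grp"]), tolerance = 1e-9)
  expect_equal(fit$table$p_value, unname(ref$p.value[, "grp"]), tolerance = 1e-9)
})

test_that("shrinkage keeps every posterior variance between s2 and the prior", {
  vals <- withr::with_seed(303, {
    sds <- sqrt(rchisq(100, df = 2) / 2)
    matrix(rnorm(100 * 8, sd = rep(sds, 8)), 100, 8,
           dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:8)))
  })
  em <- expression_matrix(vals, "log2")
  fit <- fit_moderated_two_group(em, sprintf("s%d", 1:4), sprintf("s%d", 5:8))
  s0 <- fit$params$s0_sq
  d0 <- fit$params$d0
  df <- fit$params$df_residual
  s_tilde <- (d0 * s0 + df * fit$table$s2) / (d0 + df)
  expect_true(all(s_tilde >= pmin(s0, fit$table$s2) - 1e-12))
  expect_true(all(s_tilde <= pmax(s0, fit$table$s2) + 1e-12))
  # moderated t is pulled toward (never past) the ordinary t for noisy genes
  expect_true(all(fit$table$q_value >= fit$table$p_value - 1e-15))
})

test_that("reversing a contrast negates statistics and swaps the selection", {
  vals <- withr::with_seed(404, {
    matrix(rnorm(60 * 8), 60, 8,
           dimnames = list(sprintf("g%02d", 1:60), sprintf("s%d", 1:8)))
  })
  vals[1:6, 1:4] <- vals[1:6, 1:4] + 4
  vals[7:9, 5:8] <- vals[7:9, 5:8] + 4
  em <- expression_matrix(vals, "log2")
  a <- sprintf("s%d", 1:4); b <- sprintf("s%d", 5:8)
  fwd <- fit_moderated_two_group(em, a, b)
  rev <- fit_moderated_two_group(em, b, a)
  expect_equal(rev$table$log2fc, -fwd$table$log2fc)
  expect_equal(rev$table$t_moderated, -fwd$table$t_moderated)
  expect_equal(rev$table$p_value, fwd$table$p_value)
  sf <- select_signature(fwd, fold_threshold = 5, fdr_threshold = 0.05)
  sr <- select_signature(rev, fold_threshold = 5, fdr_threshold = 0.05)
  expect_identical(sf$up, sr$down)
  expect_identical(sf$down, sr$up)
})

test_that("moderated fit validates groups and degenerate variances", {
  em <- random_matrix(sprintf("g%d", 1:5), sprintf("s%d", 1:4), seed = 1)
  expect_error(fit_moderated_two_group(em, "s1", c("s2", "s3")), ">= 2")
  expect_error(fit_moderated_two_group(em, c("s1", "s2"), c("s2", "s3")), "overlap")
  lin <- expression_matrix(abs(em$values), "linear")
  expect_error(fit_moderated_two_group(lin, c("s1", "s2"), c("s3", "s4")), "log2")
  const <- expression_matrix(matrix(1, 3, 4, dimnames = list(letters[1:3], sprintf("s%d", 1:4))),
                             "log2")
  expect_error(fit_moderated_two_group(const, c("s1", "s2"), c("s3", "s4")),
               "zero residual variance")
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.03), 0.03)
  # q >= p everywhere and q is monotone in the order statistics of p
  p <- withr::with_seed(7, runif(100))
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("signature selection applies strict FDR and log2 fold cuts", {
  tab <- data.frame(feature_id = c("a", "b", "c", "d"),
                    mean_a = 0, mean_b = 0,
                    log2fc = c(3, 3, -2.4, 2.0), s2 = 1, df = 4,
                    t_ordinary = 1, t_moderated = 1,
                    p_value = c(0.001, 0.05, 0.001, 0.001),
                    q_value = c(0.01, 0.05, 0.01, 0.01))
  fit <- structure(list(table = tab, params = list(d0 = 1, s0_sq = 1,
                                                   df_residual = 4, n_a = 3, n_b = 3)),
                   class = "moderated_fit")
  sel <- select_signature(fit, fold_threshold = 5, fdr_threshold = 0.05)
  expect_identical(sel$up, "a")        # b fails the strict q < 0.05 cut
  expect_identical(sel$down, "c")      # |−2.4| ≥ log2(5) ≈ 2.32; d is below it
  expect_error(select_signature(fit, fold_threshold = 0), "> 0")
})

test_that("stage signatures recover the planted programs and omit E8.5", {
  atl <- generate_atlas(n_background_genes = 300, n_up = 25, n_down = 8,
                        samples_per_group = 4, log2_effect = 3, noise_sd = 0.5,
                        seed = 21)
  res <- derive_stage_signatures(atl$matrix, atl$annotation)
  expect_s3_class(res$e65, "gene_signature")
  expect_identical(res$e65$species, "mouse")
  expect_gte(length(intersect(res$e65$up, atl$truth$planted_up)),
             ceiling(0.95 * length(atl$truth$planted_up)))
  expect_gte(length(intersect(res$e65$down, atl$truth$planted_down)),
             ceiling(0.95 * length(atl$truth$planted_down)))
  expect_lte(length(setdiff(c(res$e65$up, res$e65$down),
                            c(atl$truth$planted_up, atl$truth$planted_down))), 5)
  # E8.5 samples take part in neither contrast group
  keep <- filter_atlas_samples(atl$annotation)
  ann <- atl$annotation[match(keep, atl$annotation$sample_id), ]
  e85 <- ann$sample_id[ann$embryonic_stage == "E8.5"]
  expect_length(e85, 4)
  grp <- plastisig:::contrast_groups(ann, "e65")
  expect_length(intersect(e85, c(grp$a, grp$b)), 0)
  grp_adult <- plastisig:::contrast_groups(ann, "adult")
  expect_length(intersect(e85, c(grp_adult$a, grp_adult$b)), 0)
})

test_that("a null atlas yields empty or near-empty signatures", {
  atl <- generate_atlas(n_background_genes = 500, n_up = 0, n_down = 0,
                        samples_per_group = 4, seed = 22)
  res <- derive_stage_signatures(atl$matrix, atl$annotation)
  n_e65 <- length(res$e65$up) + length(res$e65$down)
  n_adult <- length(res$adult$up) + length(res$adult$down)
  expect_lte(n_e65, ceiling(0.05 * 500))
  expect_lte(n_adult, ceiling(0.05 * 500))
})

test_that("derivation errors when a required stage is missing", {
  atl <- generate_atlas(n_background_genes = 50, n_up = 2, n_down = 1,
                        samples_per_group = 2, seed = 23)
  ann <- atl$annotation[atl$annotation$embryonic_stage != "E9.5", ]
  expect_error(derive_stage_signatures(atl$matrix, sample_annotation(ann)),
               "E9.5")
})
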