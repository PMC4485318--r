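# Generators: determinism, planted effect sizes, and tuned event/censoring
# models, checked against law-of-large-numbers / closed-form oracles.

test_that("generators are pure functions of their seed", {
  a1 <- generate_atlas(n_background_genes = 40, n_up = 4, n_down = 2,
                       samples_per_group = 2, seed = 5)
  a2 <- generate_atlas(n_background_genes = 40, n_up = 4, n_down = 2,
                       samples_per_group = 2, seed = 5)
  expect_identical(a1, a2)
  a3 <- generate_atlas(n_background_genes = 40, n_up = 4, n_down = 2,
                       samples_per_group = 2, seed = 6)
  expect_false(identical(a1$matrix$values, a3$matrix$values))

  sig <- demo_signature()
  expect_identical(generate_cohort(sig, n_patients = 30, seed = 3),
                   generate_cohort(sig, n_patients = 30, seed = 3))
  expect_identical(generate_cell_line_panel(sig, seed = 3),
                   generate_cell_line_panel(sig, seed = 3))
  expect_identical(generate_homology_table(letters, seed = 3, frac_unmapped = 0.2),
                   generate_homology_table(letters, seed = 3, frac_unmapped = 0.2))
  # generators leave the caller's RNG stream untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_atlas(n_background_genes = 5, n_up = 1,
                                         n_down = 1, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("atlas structure: groups, decoys, scale and argument validation", {
  atl <- generate_atlas(n_background_genes = 30, n_up = 3, n_down = 2,
                        samples_per_group = 3, seed = 2)
  ann <- atl$annotation
  expect_identical(atl$matrix$scale, "linear")
  expect_true(all(atl$matrix$values > 0))
  expect_setequal(setdiff(unique(ann$embryonic_stage), "none"),
                  c("E6.5", "E7.5", "E8.5", "E9.5", "E10.5"))
  expect_gte(length(unique(ann$tissue_name[ann$sample_class == "adult" &
                                             !ann$is_cell_line & !ann$is_stimulated &
                                             !ann$is_undeveloped])), 3)
  expect_true(any(ann$is_cell_line) && any(ann$is_stimulated))
  expect_true(any(ann$is_undeveloped & ann$embryonic_stage == "none"))
  expect_true(all(sort(c(atl$truth$planted_up, atl$truth$planted_down)) %in%
                    feature_ids(atl$matrix)))
  expect_length(intersect(atl$truth$planted_up, atl$truth$planted_down), 0)

  null_atlas <- generate_atlas(n_background_genes = 20, n_up = 0, n_down = 0,
                               samples_per_group = 2, seed = 4)
  expect_length(null_atlas$truth$planted_up, 0)
  expect_error(generate_atlas(log2_effect = 0), "log2_effect")
  expect_error(generate_atlas(noise_sd = -1), "noise_sd")
})

test_that("planted atlas effect matches its nominal size at large n", {
  spg <- 10000
  atl <- generate_atlas(n_background_genes = 3, n_up = 2, n_down = 1,
                        samples_per_group = spg, log2_effect = 3,
                        noise_sd = 0.5, seed = 8)
  lg <- log2(atl$matrix$values)
  ann <- atl$annotation
  e65 <- ann$sample_id[ann$embryonic_stage == "E6.5"]
  adult <- ann$sample_id[ann$sample_class == "adult" & !ann$is_cell_line &
                           !ann$is_stimulated & !ann$is_undeveloped]
  for (g in atl$truth$planted_up) {
    diff <- mean(lg[g, e65]) - mean(lg[g, adult])
    expect_lt(abs(diff - 3), 3 * 0.5 / sqrt(spg))
  }
  for (g in setdiff(feature_ids(atl$matrix),
                    c(atl$truth$planted_up, atl$truth$planted_down))) {
    expect_lt(abs(mean(lg[g, e65]) - mean(lg[g, adult])), 3 * 0.5 / sqrt(spg))
  }
})

test_that("homology generator hits its unmapped and one-to-many fractions", {
  genes <- sprintf("m%03d", 1:5)
  tab <- generate_homology_table(genes, seed = 1, frac_unmapped = 0,
                                 frac_one_to_many = 0)
  expect_equal(sum(tab$taxid == 10090), 5)
  expect_equal(sum(tab$taxid == 9606), 5)
  expect_true(all(table(tab$hid) == 2))

  tab <- generate_homology_table(genes, seed = 1, frac_unmapped = 1)
  expect_equal(sum(tab$taxid == 9606), 0)

  genes <- sprintf("m%03d", 1:400)
  tab <- generate_homology_table(genes, seed = 2, frac_one_to_many = 0.5)
  n_two <- sum(table(tab$hid[tab$taxid == 9606]) == 2)
  # binomial(400, 0.5): 3 sigma is 30
  expect_lt(abs(n_two - 200), 30)
})

test_that("cohort event model follows its two-level exponential hazard", {
  sig <- demo_signature(2, 1)
  coh <- generate_cohort(sig, n_patients = 1e5, hazard_ratio = 3,
                         baseline_hazard = 0.02, censoring_rate = 0,
                         n_background_genes = 0, seed = 12)
  expect_true(all(coh$records$event == 1))
  L <- coh$truth$latent_scores
  high <- L[coh$records$sample_id] > median(L)
  rate_high <- 1 / mean(coh$records$time[high])
  rate_low <- 1 / mean(coh$records$time[!high])
  expect_equal(rate_high / rate_low, 3, tolerance = 0.05)

  # null hazard ratio: the two groups' event-time distributions coincide
  coh0 <- generate_cohort(sig, n_patients = 2e4, hazard_ratio = 1,
                          baseline_hazard = 0.02, censoring_rate = 0,
                          n_background_genes = 0, seed = 13)
  L0 <- coh0$truth$latent_scores
  high0 <- L0[coh0$records$sample_id] > median(L0)
  expect_equal(mean(coh0$records$time[high0]) / mean(coh0$records$time[!high0]),
               1, tolerance = 0.06)
})

test_that("cohort censoring rate is tuned to its nominal value", {
  sig <- demo_signature(2, 1)
  coh <- generate_cohort(sig, n_patients = 2e4, hazard_ratio = 3,
                         censoring_rate = 0.5, n_background_genes = 0, seed = 14)
  expect_equal(mean(coh$records$event == 0), 0.5, tolerance = 0.03)
  expect_true(all(coh$records$time > 0))
  expect_setequal(names(coh$truth$latent_scores), coh$records$sample_id)
})

test_that("noiseless cohort expression ranks patients exactly by latent level", {
  sig <- demo_signature(3, 2)
  coh <- generate_cohort(sig, n_patients = 50, noise_sd = 0,
                         n_background_genes = 5, seed = 15)
  scores <- score_signature(zscore_rows(coh$matrix), sig)
  expect_identical(order(scores$score), order(coh$truth$latent_scores[scores$sample_id]))
})

test_that("cell-line panel separates groups by shift and is null at shift 0", {
  sig <- demo_signature(4, 2)
  panel <- generate_cell_line_panel(sig, n_metastatic = 8, n_nonmetastatic = 8,
                                    shift = 3, noise_sd = 0.1, seed = 16)
  sc <- score_signature(zscore_rows(panel$matrix), sig)
  met <- panel$labels$metastatic[match(sc$sample_id, panel$labels$sample_id)]
  expect_true(min(sc$score[met]) > max(sc$score[!met]))

  null_panel <- generate_cell_line_panel(sig, n_metastatic = 10,
                                         n_nonmetastatic = 10, shift = 0,
                                         noise_sd = 1, seed = 17)
  sc0 <- score_signature(zscore_rows(null_panel$matrix), sig)
  met0 <- null_panel$labels$metastatic[match(sc0$sample_id, null_panel$labels$sample_id)]
  expect_gt(t.test(sc0$score[met0], sc0$score[!met0])$p.value, 0.001)
})
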