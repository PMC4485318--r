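# Synthetic-data generators. Every generator is a pure function of its
# arguments including `seed` (RNG state is restored afterwards), and returns
# its planted truth alongside the data so recovery can be measured.

#' Simulate a staged expression atlas with planted gene programs
#'
#' Emulates a staged developmental atlas: groups of replicate samples at
#' embryonic days E6.5--E10.5 plus several adult tissues, with a handful of
#' cell-line / stimulated / undeveloped decoy samples that sample filtering
#' must remove. In log2 space each gene has a per-gene baseline plus Gaussian
#' noise; a planted "plasticity" program is elevated by `log2_effect` at
#' E6.5/E7.5 (and by half that at the E8.5 transition stage), and a planted
#' "differentiated" program is elevated by `log2_effect` at E9.5/E10.5 and in
#' adult tissues. The matrix is emitted on the linear scale (`2^value`) so a
#' downstream log2 step is exercised.
#'
#' @param n_background_genes Number of unplanted genes (>= 1).
#' @param n_up,n_down Sizes of the planted early-embryonic (up) and
#'   late/adult (down) programs; either may be 0 for a null atlas.
#' @param samples_per_group Replicates per stage and per adult tissue.
#' @param log2_effect Planted group-mean difference, log2 units (> 0).
#' @param noise_sd Gaussian noise standard deviation, log2 units (> 0).
#' @param adult_tissues Names of the adult tissue groups (>= 3).
#' @param baseline_range Range of per-gene baseline means, log2 units.
#' @param seed Integer seed; the same seed reproduces the atlas exactly.
#' @return A list with elements `matrix` (linear-scale [expression_matrix()]),
#'   `annotation` ([sample_annotation()]) and `truth` (class `atlas_truth`:
#'   planted gene sets, effect, noise, seed).
#' @examples
#' atl <- generate_atlas(n_background_genes = 50, n_up = 5, n_down = 2,
#'                       samples_per_group = 3, seed = 1)
#' dim(atl$matrix)
#' @export
generate_atlas <- function(n_background_genes = 2000, n_up = 150, n_down = 30,
                           samples_per_group = 4, log2_effect = 3,
                           noise_sd = 0.5,
                           adult_tissues = c("brain", "liver", "kidney", "heart"),
                           baseline_range = c(6, 10), seed = 1) {
  if (!is_count(n_background_genes, 1L)) validation_error("n_background_genes must be >= 1")
  if (!is_count(n_up) || !is_count(n_down)) validation_error("n_up/n_down must be counts >= 0")
  if (!is_count(samples_per_group, 1L)) validation_error("samples_per_group must be >= 1")
  if (!is_number(log2_effect) || log2_effect <= 0) validation_error("log2_effect must be > 0")
  if (!is_number(noise_sd) || noise_sd <= 0) validation_error("noise_sd must be > 0")
  if (length(adult_tissues) < 3L) validation_error("need >= 3 adult tissues")

  n_genes <- n_background_genes + n_up + n_down
  genes <- sprintf("mgene%05d", seq_len(n_genes))

  groups <- c(EMBRYONIC_STAGES, adult_tissues)
  ann <- do.call(rbind, lapply(groups, function(g) {
    embryo <- g %in% EMBRYONIC_STAGES
    data.frame(
      sample_id = sprintf("%s_rep%02d", gsub("[^A-Za-z0-9.]", "_", g), seq_len(samples_per_group)),
      tissue_name = g,
      sample_class = if (embryo) "embryo" else "adult",
      embryonic_stage = if (embryo) g else "none",
      is_cell_line = FALSE, is_stimulated = FALSE,
      is_undeveloped = embryo,   # staged embryos are undeveloped tissue by definition
      stringsAsFactors = FALSE)
  }))
  decoys <- data.frame(
    sample_id = c("cellline_01", "stimulated_01", "undeveloped_01"),
    tissue_name = c("fibroblast_line", "lps_spleen", "fetal_residue"),
    sample_class = "adult", embryonic_stage = "none",
    is_cell_line = c(TRUE, FALSE, FALSE),
    is_stimulated = c(FALSE, TRUE, FALSE),
    is_undeveloped = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  ann <- sample_annotation(rbind(ann, decoys))

  with_seed(seed, {
    planted_up <- sort(sample(genes, n_up))
    planted_down <- sort(sample(setdiff(genes, planted_up), n_down))
    baseline <- stats::runif(n_genes, baseline_range[1L], baseline_range[2L])
    names(baseline) <- genes

    early <- ann$embryonic_stage %in% c("E6.5", "E7.5")
    transition <- ann$embryonic_stage == "E8.5"
    late <- ann$embryonic_stage %in% c("E9.5", "E10.5") |
      (ann$sample_class == "adult" & !ann$is_cell_line)
    # cell-line decoy mimics the early-embryonic program: if filtering fails
    # it contaminates the contrast
    early_like <- early | ann$is_cell_line

    mu <- matrix(baseline, n_genes, nrow(ann), dimnames = list(genes, ann$sample_id))
    mu[planted_up, early_like] <- mu[planted_up, early_like] + log2_effect
    mu[planted_up, transition] <- mu[planted_up, transition] + log2_effect / 2
    mu[planted_down, late] <- mu[planted_down, late] + log2_effect
    mu[planted_down, transition] <- mu[planted_down, transition] + log2_effect / 2

    vals <- mu + matrix(stats::rnorm(length(mu), sd = noise_sd), nrow(mu), ncol(mu))
    truth <- structure(list(planted_up = planted_up, planted_down = planted_down,
                            log2_effect = log2_effect, noise_sd = noise_sd,
                            seed = seed),
                       class = "atlas_truth")
    list(matrix = expression_matrix(2^vals, "linear"), annotation = ann, truth = truth)
  })
}

#' Simulate a Homologene-format mouse/human homology table
#'
#' Produces the standard 6-column layout (homology group id, taxid, gene id,
#' gene symbol, protein gi, protein accession) pairing each mouse gene (taxid
#' 10090) with invented human partners (taxid 9606). A fraction of mouse genes
#' is left unmapped (no human row in the group) and a fraction mapped to two
#' human genes.
#'
#' @param mouse_gene_ids Character vector of mouse gene ids.
#' @param seed Integer seed.
#' @param frac_unmapped,frac_one_to_many Probabilities in `[0, 1]`.
#' @return A data frame with columns `hid`, `taxid`, `gene_id`, `symbol`,
#'   `protein_gi`, `protein_accession`, classed `homology_table`.
#' @export
generate_homology_table <- function(mouse_gene_ids, seed = 1,
                                    frac_unmapped = 0, frac_one_to_many = 0) {
  stopifnot(is.character(mouse_gene_ids), length(mouse_gene_ids) >= 1L)
  if (anyDuplicated(mouse_gene_ids)) validation_error("duplicate mouse gene ids")
  for (f in c(frac_unmapped, frac_one_to_many))
    if (!is_number(f) || f < 0 || f > 1) validation_error("fractions must lie in [0, 1]")

  with_seed(seed, {
    n <- length(mouse_gene_ids)
    unmapped <- stats::rbinom(n, 1L, frac_unmapped) == 1L
    two <- !unmapped & stats::rbinom(n, 1L, frac_one_to_many) == 1L
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      g <- mouse_gene_ids[i]
      mouse <- data.frame(hid = i, taxid = 10090L, gene_id = g, symbol = g,
                          protein_gi = 2L * i, protein_accession = sprintf("NP_%06d", 2L * i),
                          stringsAsFactors = FALSE)
      if (unmapped[i]) { rows[[i]] <- mouse; next }
      hum_ids <- paste0("h.", g, if (two[i]) c("", ".2") else "")
      human <- data.frame(hid = i, taxid = 9606L, gene_id = hum_ids, symbol = toupper(hum_ids),
                          protein_gi = 2L * i + 1L,
                          protein_accession = sprintf("NP_%06d", 2L * i + 1L),
                          stringsAsFactors = FALSE)
      rows[[i]] <- rbind(mouse, human)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    class(tab) <- c("homology_table", "data.frame")
    tab
  })
}

#' Write a homology table in homologene.data layout (6 columns, no header)
#' @param table A `homology_table` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_homologene <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate a patient cohort whose hazard is driven by a latent plasticity level
#'
#' Each patient receives a latent plasticity level `L ~ Normal(0, 1)`.
#' Expression of the signature's up genes is `L` plus Gaussian noise, of the
#' down genes `-L` plus noise, and of background genes pure noise (analysis
#' scale). Event times are exponential with hazard
#' `baseline_hazard * hazard_ratio^[L > median(L)]`; censoring is an
#' independent exponential whose rate is tuned so the expected censored
#' fraction equals `censoring_rate`.
#'
#' @param signature A [gene_signature()] defining the up/down programs.
#' @param n_patients Number of patients (>= 2).
#' @param hazard_ratio Hazard ratio between high- and low-latent patients (> 0).
#' @param baseline_hazard Event hazard of the low group, per study time unit.
#' @param censoring_rate Expected fraction of censored patients in `[0, 1)`.
#' @param noise_sd Expression noise standard deviation.
#' @param n_background_genes Number of unrelated genes added to the matrix.
#' @param endpoint `"DMFS"` or `"RFS"` stamped on the records.
#' @param seed Integer seed.
#' @return A list with `matrix` (log2-scale [expression_matrix()]), `records`
#'   ([survival_records()]) and `truth` (class `cohort_truth` with the latent
#'   scores and simulation parameters).
#' @export
generate_cohort <- function(signature, n_patients = 200, hazard_ratio = 3,
                            baseline_hazard = 0.01, censoring_rate = 0.5,
                            noise_sd = 1, n_background_genes = 100,
                            endpoint = c("DMFS", "RFS"), seed = 1) {
  stopifnot(inherits(signature, "gene_signature"))
  endpoint <- match.arg(endpoint)
  if (!is_count(n_patients, 2L)) validation_error("n_patients must be >= 2")
  if (!is_number(hazard_ratio) || hazard_ratio <= 0) validation_error("hazard_ratio must be > 0")
  if (!is_number(baseline_hazard) || baseline_hazard <= 0) validation_error("baseline_hazard must be > 0")
  if (!is_number(censoring_rate) || censoring_rate < 0 || censoring_rate >= 1)
    validation_error("censoring_rate must lie in [0, 1)")
  if (!is_number(noise_sd) || noise_sd < 0) validation_error("noise_sd must be >= 0")

  with_seed(seed, {
    pid <- sprintf("patient%04d", seq_len(n_patients))
    L <- stats::rnorm(n_patients)
    names(L) <- pid
    high <- L > stats::median(L)
    rate <- baseline_hazard * hazard_ratio^high
    t_event <- stats::rexp(n_patients, rate)
    if (censoring_rate > 0) {
      # expected censored fraction of an Exp(c) censor against a 50/50 mix of
      # Exp(lambda1)/Exp(lambda2) event times is mean(c / (c + lambda))
      lam <- baseline_hazard * c(1, hazard_ratio)
      f <- function(cr) mean(cr / (cr + lam)) - censoring_rate
      c_rate <- stats::uniroot(f, lower = baseline_hazard * 1e-9,
                               upper = baseline_hazard * 1e9, tol = 1e-12)$root
      t_cens <- stats::rexp(n_patients, c_rate)
    } else {
      t_cens <- rep(Inf, n_patients)
    }
    records <- survival_records(data.frame(
      sample_id = pid,
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      endpoint = endpoint, stringsAsFactors = FALSE))

    genes <- c(signature$up, signature$down,
               if (n_background_genes > 0) sprintf("bg%04d", seq_len(n_background_genes)))
    vals <- matrix(stats::rnorm(length(genes) * n_patients, sd = max(noise_sd, 1e-12)),
                   length(genes), n_patients, dimnames = list(genes, pid))
    vals[signature$up, ] <- sweep(vals[signature$up, , drop = FALSE], 2L, L, `+`)
    vals[signature$down, ] <- sweep(vals[signature$down, , drop = FALSE], 2L, -L, `+`)

    truth <- structure(list(hazard_ratio = hazard_ratio,
                            baseline_hazard = baseline_hazard,
                            censoring_rate = censoring_rate,
                            latent_scores = L, seed = seed),
                       class = "cohort_truth")
    list(matrix = expression_matrix(vals, "log2"), records = records, truth = truth)
  })
}

#' Simulate a cell-line panel with known metastatic labels
#'
#' Metastatic lines carry the signature's up genes shifted by `+shift` and
#' down genes by `-shift` (z-units); non-metastatic lines the reverse.
#'
#' @param signature A [gene_signature()].
#' @param n_metastatic,n_nonmetastatic Group sizes (>= 1 each).
#' @param shift Planted separation in z-units (> 0 for a signal; 0 allowed for
#'   a null panel).
#' @param noise_sd Gaussian noise standard deviation.
#' @param n_background_genes Unrelated genes added to the matrix.
#' @param seed Integer seed.
#' @return A list with `matrix` (log2-scale [expression_matrix()]) and
#'   `labels` (data frame: `sample_id`, `metastatic` logical).
#' @export
generate_cell_line_panel <- function(signature, n_metastatic = 6,
                                     n_nonmetastatic = 6, shift = 3,
                                     noise_sd = 0.1, n_background_genes = 50,
                                     seed = 1) {
  stopifnot(inherits(signature, "gene_signature"))
  if (!is_count(n_metastatic, 1L) || !is_count(n_nonmetastatic, 1L))
    validation_error("group sizes must be >= 1")
  if (!is_number(shift) || shift < 0) validation_error("shift must be >= 0")
  if (!is_number(noise_sd) || noise_sd <= 0) validation_error("noise_sd must be > 0")

  with_seed(seed, {
    n <- n_metastatic + n_nonmetastatic
    sid <- c(sprintf("met_line%02d", seq_len(n_metastatic)),
             sprintf("nonmet_line%02d", seq_len(n_nonmetastatic)))
    met <- rep(c(TRUE, FALSE), c(n_metastatic, n_nonmetastatic))
    genes <- c(signature$up, signature$down,
               if (n_background_genes > 0) sprintf("bg%04d", seq_len(n_background_genes)))
    vals <- matrix(stats::rnorm(length(genes) * n, sd = noise_sd),
                   length(genes), n, dimnames = list(genes, sid))
    sgn <- ifelse(met, 1, -1)
    vals[signature$up, ] <- sweep(vals[signature$up, , drop = FALSE], 2L, shift * sgn, `+`)
    vals[signature$down, ] <- sweep(vals[signature$down, , drop = FALSE], 2L, -shift * sgn, `+`)
    list(matrix = expression_matrix(vals, "log2"),
         labels = data.frame(sample_id = sid, metastatic = met, stringsAsFactors = FALSE))
  })
}
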