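# End-to-end orchestration: simulate/load -> derive -> map -> score -> survive,
# driven by a single YAML configuration with one master seed.

#' Read and validate a pipeline run configuration
#'
#' The configuration is YAML with named blocks. Each data block supplies
#' either a `simulate:` sub-block (parameters forwarded to the matching
#' generator) or paths to files on disk:
#' \preformatted{
#' seed: 1
#' out_dir: runs/demo
#' thresholds: {fold: 5, fdr: 0.05, fraction: 0.10}
#' split: median
#' atlas:    {simulate: {...}}            # or matrix: PATH, annotation: PATH
#' homology: {simulate: {...}}            # or path: PATH (homologene format)
#' cohort:   {simulate: {...}, endpoint: DMFS}  # or matrix: PATH, clinical: PATH
#' cells:    {simulate: {...}}            # optional
#' }
#' Validation fails before any stage runs if a required block is absent or a
#' referenced path does not exist.
#'
#' @param path YAML file.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: ", path)
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config A config list (as from [yaml::read_yaml()]).
#' @export
validate_run_config <- function(config) {
  if (!is.list(config)) validation_error("config must be a mapping")
  if (is.null(config$seed) || !is_count(config$seed))
    validation_error("config needs an integer `seed`")
  if (is.null(config$out_dir)) validation_error("config needs `out_dir`")
  th <- config$thresholds %||% list()
  config$thresholds <- list(fold = th$fold %||% 5, fdr = th$fdr %||% 0.05,
                            fraction = th$fraction %||% 0.10)
  config$split <- config$split %||% "median"
  if (!config$split %in% c("median", "sign"))
    validation_error("split must be 'median' or 'sign'")

  need_block <- function(name, path_fields) {
    blk <- config[[name]]
    if (is.null(blk))
      validation_error("config block '", name, "' is missing")
    if (is.null(blk$simulate)) {
      for (f in path_fields) {
        if (is.null(blk[[f]]))
          validation_error("config block '", name,
                           "' needs either `simulate:` or `", f, ":`")
        if (!file.exists(blk[[f]]))
          validation_error("config block '", name, "': path does not exist: ", blk[[f]])
      }
    }
  }
  need_block("atlas", c("matrix", "annotation"))
  need_block("homology", "path")
  need_block("cohort", c("matrix", "clinical"))
  if (!is.null(config$cells) && is.null(config$cells$simulate))
    validation_error("config block 'cells' supports only `simulate:`")
  structure(config, class = c("run_config", "list"))
}

call_with <- function(fn, args) do.call(fn, as.list(args))

#' Run the full plasticity-signature pipeline
#'
#' Executes, in order: atlas acquisition, stage-signature derivation, homology
#' mapping, cohort scoring with survival stratification, and (optionally)
#' cell-line panel classification. Every intermediate artifact is written
#' under `out_dir`, and a machine-readable JSON run report (per stage:
#' parameters, counts, artifact MD5 hashes, elapsed seconds) plus a
#' human-readable log are produced. The master seed fans out to per-stage
#' seeds (`seed + stage index`) so any stage can be reproduced alone; the same
#' config and seed give identical artifacts.
#'
#' @param config A `run_config`, a config list, or a path to a YAML config.
#' @return The run report list, invisibly. Artifacts and `run_report.json` /
#'   `run.log` are written under `config$out_dir`.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(unclass(config))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  cat(sprintf("plastisig run: seed %d\n", config$seed), file = log_path)
  logmsg <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)

  report <- list(seed = config$seed, thresholds = config$thresholds,
                 split = config$split, stages = list())
  artifacts <- character()
  stage <- function(name, idx, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(config$seed + idx),
                    error = function(e) abort("stage '", name, "' failed: ",
                                              conditionMessage(e)))
    res$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 3)
    logmsg("stage %s done in %.3fs", name, res$elapsed_s)
    report$stages[[name]] <<- res
    res
  }
  art <- function(path) { artifacts <<- c(artifacts, path); path }

  ## stage 1: atlas ---------------------------------------------------------
  atlas_truth <- NULL
  atlas_mat <- NULL
  atlas_ann <- NULL
  stage("atlas", 1L, function(seed) {
    blk <- config$atlas
    if (!is.null(blk$simulate)) {
      sim_args <- blk$simulate
      sim_args$seed <- sim_args$seed %||% seed
      atl <- call_with(generate_atlas, sim_args)
      atlas_truth <<- atl$truth
      write_expression_tsv(atl$matrix, art(file.path(out, "atlas_matrix.tsv")))
      write_annotation_tsv(atl$annotation, art(file.path(out, "atlas_annotation.tsv")))
      jsonlite::write_json(list(planted_up = atl$truth$planted_up,
                                planted_down = atl$truth$planted_down,
                                log2_effect = atl$truth$log2_effect,
                                noise_sd = atl$truth$noise_sd, seed = atl$truth$seed),
                           art(file.path(out, "atlas_truth.json")), auto_unbox = TRUE)
      mat <- atl$matrix; ann <- atl$annotation
    } else {
      mat <- read_expression_tsv(blk$matrix, scale = blk$scale %||% "linear")
      ann <- read_annotation_tsv(blk$annotation)
    }
    atlas_mat <<- mat
    atlas_ann <<- ann
    list(source = if (is.null(blk$simulate)) "files" else "simulated",
         n_features = nrow(mat$values), n_samples = ncol(mat$values))
  })

  ## stage 2: derive signatures --------------------------------------------
  derived <- NULL
  stage("derive", 2L, function(seed) {
    derived <<- derive_stage_signatures(atlas_mat, atlas_ann,
                                        fold_threshold = config$thresholds$fold,
                                        fdr_threshold = config$thresholds$fdr)
    sigs <- Filter(Negate(is.null), derived[c("e65", "adult")])
    if (!length(sigs)) abort("no genes selected for any contrast")
    write_signature_gmt(sigs, art(file.path(out, "signatures.gmt")))
    write_signature_tsv(sigs, art(file.path(out, "signatures_weighted.tsv")))
    counts <- list()
    for (ct in c("e65", "adult")) {
      fit <- derived$fits[[ct]]
      utils::write.table(fit$table, art(file.path(out, paste0("de_", ct, ".tsv"))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      logmsg("contrast %s: d0 = %.6g, s0_sq = %.6g, selected %d up / %d down",
             ct, fit$params$d0, fit$params$s0_sq,
             length(derived[[ct]]$up), length(derived[[ct]]$down))
      counts[[ct]] <- list(d0 = fit$params$d0, s0_sq = fit$params$s0_sq,
                           n_up = length(derived[[ct]]$up),
                           n_down = length(derived[[ct]]$down))
    }
    counts
  })
  if (is.null(derived$e65))
    abort("stage 'derive' produced no early-embryonic signature; cannot continue")

  ## stage 3: homology mapping ----------------------------------------------
  human_sig <- NULL
  stage("homology", 3L, function(seed) {
    blk <- config$homology
    if (!is.null(blk$simulate)) {
      sim_args <- blk$simulate
      sim_args$mouse_gene_ids <- feature_ids(atlas_mat)
      sim_args$seed <- sim_args$seed %||% seed
      tab <- call_with(generate_homology_table, sim_args)
      write_homologene(tab, art(file.path(out, "homologene.tsv")))
      hmap <- as_homology_map(tab)
    } else {
      hmap <- read_homologene(blk$path)
    }
    mapped <- map_signature(derived$e65, hmap)
    human_sig <<- mapped$signature
    write_signature_gmt(human_sig, art(file.path(out, "signature_e65_human.gmt")))
    utils::write.table(mapped$report, art(file.path(out, "homology_report.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_up_human = length(human_sig$up), n_down_human = length(human_sig$down),
         n_unmapped = sum(mapped$report$status == "unmapped"),
         n_conflict = sum(mapped$report$status == "conflict"))
  })

  ## stage 4: cohort survival stratification --------------------------------
  stage("cohort", 4L, function(seed) {
    blk <- config$cohort
    if (!is.null(blk$simulate)) {
      sim_args <- blk$simulate
      sim_args$signature <- human_sig
      sim_args$seed <- sim_args$seed %||% seed
      sim_args$endpoint <- sim_args$endpoint %||% blk$endpoint %||% "DMFS"
      coh <- call_with(generate_cohort, sim_args)
      write_expression_tsv(coh$matrix, art(file.path(out, "cohort_matrix.tsv")))
      write_clinical_tsv(coh$records, art(file.path(out, "cohort_clinical.tsv")))
      jsonlite::write_json(list(hazard_ratio = coh$truth$hazard_ratio,
                                baseline_hazard = coh$truth$baseline_hazard,
                                censoring_rate = coh$truth$censoring_rate,
                                latent_scores = as.list(coh$truth$latent_scores),
                                seed = coh$truth$seed),
                           art(file.path(out, "cohort_truth.json")), auto_unbox = TRUE)
      mat <- coh$matrix; rec <- coh$records
    } else {
      mat <- read_expression_tsv(blk$matrix, scale = blk$scale %||% "log2")
      rec <- read_clinical_tsv(blk$clinical)
    }
    endpoint <- blk$endpoint %||% rec$endpoint[1L]
    res <- run_outcome_analysis(mat, rec, human_sig, endpoint = endpoint,
                                discretize_method = config$split,
                                fraction = config$thresholds$fraction)
    write_outcome_tsv(res, out, prefix = "cohort")
    art(file.path(out, "cohort_comparison.tsv")); art(file.path(out, "cohort_km.tsv"))
    write_scores_tsv(res$scores, art(file.path(out, "cohort_scores.tsv")))
    list(endpoint = res$endpoint, n_high = res$n_high, n_low = res$n_low,
         t10_high = res$t10_high, t10_low = res$t10_low,
         delta_t10 = res$delta_t10, chi_square = res$logrank$chi_square,
         p_value = res$logrank$p_value)
  })

  ## stage 5: cell-line panel (optional) -------------------------------------
  if (!is.null(config$cells)) {
    stage("cells", 5L, function(seed) {
      sim_args <- config$cells$simulate
      sim_args$signature <- human_sig
      sim_args$seed <- sim_args$seed %||% seed
      panel <- call_with(generate_cell_line_panel, sim_args)
      z <- zscore_rows(panel$matrix)
      calls <- classify_metastatic(score_signature(z, human_sig))
      merged <- merge(calls, panel$labels, by = "sample_id", sort = TRUE)
      acc <- mean((merged$label == "metastatic-competent") == merged$metastatic)
      utils::write.table(merged, art(file.path(out, "cellline_calls.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(n_lines = nrow(merged), accuracy = acc)
    })
  }

  report$artifacts <- lapply(stats::setNames(artifacts, basename(artifacts)),
                             function(p) unname(tools::md5sum(p)))
  report_path <- file.path(out, "run_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  logmsg("report written to %s", report_path)
  invisible(report)
}
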