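# plastisig

Derivation and clinical evaluation of embryonic **plasticity gene
signatures** in R.

Metastasis requires carcinoma cells to transition repeatedly between
epithelial and mesenchymal states (EMT and its reversal, MET). Signatures
that capture one static state predict these transitions poorly; the gene
expression program of early mouse gastrulation (embryonic day 6.5–7.5), when
epiblast cells transiently undergo exactly such transitions, is a
physiological template for the *capacity to switch*. `plastisig` implements
the full analysis pipeline around that idea, for computational biologists
working with staged expression atlases and clinical cohort data:

* **Signature derivation** — filter atlas samples (drop cell lines,
  stimulated and undeveloped tissues), log2-transform, and contrast
  E6.5+E7.5 against E9.5+E10.5+adult (omitting the E8.5 transition stage)
  with a moderated two-group t-test: per-gene variances `s²` on
  `d = nₐ + n_b − 2` df are shrunk toward a prior `(d₀, s₀²)` estimated by
  moment matching on `log s²`, giving
  `t̃ = (x̄ₐ − x̄_b) / √(s̃² (1/nₐ + 1/n_b))` with
  `s̃² = (d₀s₀² + d s²)/(d₀ + d)` on `d₀ + d` df. Genes with BH-adjusted
  `q < 0.05` and `|log₂FC| ≥ log₂ 5` form the signed signature.
* **Homology mapping** — translate mouse signatures to human genes via
  Homologene-format tables, keeping all homologs, counting unmapped genes and
  dropping weight conflicts.
* **Plasticity scoring** — collapse probes to genes by maximal variance,
  z-normalize each gene across the data set, then score each sample as the
  mean z-score with weight +1 (up genes) and −1 (down genes). A strictly
  positive E6.5-type score calls a cell line metastatic-competent.
* **Survival stratification** — split patients at the median score and
  compare high vs low groups by Kaplan–Meier curves, the log-rank test, and
  **t10**, the earliest event time at which a group's KM survival drops to
  0.90 (distant metastasis-free or recurrence-free survival).
* **Synthetic data** — generators for staged atlases with planted gene
  programs, homology tables, proportional-hazards patient cohorts driven by a
  latent plasticity level, and labelled cell-line panels, all with recorded
  ground truth. The whole pipeline runs with no downloads.

## Worked example

```r
library(plastisig)

# a staged atlas with a planted 150-gene early program and 30-gene late program
atlas <- generate_atlas(seed = 42)
derived <- derive_stage_signatures(atlas$matrix, atlas$annotation)
derived$e65
#> gene_signature 'E6.5' (mouse): 150 up, 30 down

# translate to human identifiers
homtab <- generate_homology_table(feature_ids(atlas$matrix), seed = 43,
                                  frac_unmapped = 0.05, frac_one_to_many = 0.1)
mapped <- map_signature(derived$e65, as_homology_map(homtab))
mapped$signature
#> gene_signature 'E6.5' (human): 161 up, 28 down

# a 200-patient cohort whose hazard triples with the latent plasticity level
cohort <- generate_cohort(mapped$signature, n_patients = 200,
                          hazard_ratio = 3, seed = 44)
run_outcome_analysis(cohort$matrix, cohort$records, mapped$signature, "DMFS")
#> DMFS stratification by 'E6.5': 100 high vs 100 low
#>   time to 10% events: high 3.96, low 28.1 (delta 24.2)
#>   log-rank chi-square = 64.54, p = 9.478e-16

# sign-based metastatic-competence calls on a labelled cell-line panel
panel <- generate_cell_line_panel(mapped$signature, seed = 45)
calls <- classify_metastatic(
  score_signature(zscore_rows(panel$matrix), mapped$signature))
```

The derivation recovers all 180 planted genes with no false positives; the
high-plasticity patient half reaches 10% of DMFS events at 3.96 study-time
units versus 28.1 for the low half; and the sign of the score reproduces all
12 planted metastatic labels.

An end-to-end run (simulate → derive → map → score → survive, with all
artifacts and a JSON run report) is driven by one YAML config:

```r
run_full_pipeline("config.yaml")   # or: inst/cli/plastisig run --config config.yaml
```

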