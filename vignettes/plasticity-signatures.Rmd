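---
title: "Deriving and evaluating embryonic plasticity signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and evaluating embryonic plasticity signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastisig)
```

## The idea

Carcinoma cells that metastasize must switch repeatedly between epithelial
and mesenchymal states. Signatures built from any single state (an EMT
signature, a stemness signature) capture a snapshot, not the capacity to
switch. Early gastrulation — embryonic day 6.5–7.5 in the mouse, when
epiblast cells ingress through the primitive streak, transiently lose their
epithelial character and later re-epithelialize — is the canonical
physiological setting of exactly this plasticity. `plastisig` implements the
corresponding analysis pipeline:

1. derive an **up/down gene signature** contrasting E6.5/E7.5 embryos against
   later stages (E9.5, E10.5) and adult tissues in a staged expression atlas,
   and its negative correlate contrasting adult tissues against all retained
   embryonic stages;
2. translate the mouse signature to human identifiers through a
   Homologene-format homology table;
3. compute a per-sample **plasticity score** — the mean of per-gene z-scores,
   weighted +1 for up genes and −1 for down genes — on any human expression
   matrix; and
4. test whether the score stratifies patient survival (distant
   metastasis-free or recurrence-free), using Kaplan–Meier curves, the
   log-rank test, and the time until 10% of a group has acquired the outcome.

A synthetic-data module simulates every input with recorded ground truth, so
the whole pipeline is exercisable and testable without any download.

## Signature derivation

### Sample filtering and transform

Atlas samples from cell lines, stimulated tissues, and undeveloped tissue are
excluded before testing; staged embryos (E6.5–E10.5) are undeveloped tissue
by definition but are retained, since they are the point of the contrast
(`filter_atlas_samples()`). Linear intensities are log2-transformed; the
pseudocount defaults to 0 because atlas-style intensities are strictly
positive, and is configurable where data contain zeros.

### The moderated two-group test

With only a handful of replicates per stage, per-gene variance estimates are
unstable, so the two-group test shrinks them toward a common prior
(`fit_moderated_two_group()`). Per gene, the pooled residual variance $s^2_g$
on $d = n_a + n_b - 2$ degrees of freedom is modeled as $s^2_g \sim s_0^2
F(d, d_0)$. Writing $e_g = \log s^2_g - \psi(d/2) + \log(d/2)$ (with $\psi$
the digamma function), the prior is estimated by matching the first two
moments of $e$:

$$\psi'(d_0/2) = \operatorname{var}(e) - \psi'(d/2), \qquad
  \log s_0^2 = \bar e + \psi(d_0/2) - \log(d_0/2),$$

inverting the trigamma function $\psi'$ by a Newton iteration. When
$\operatorname{var}(e) \le \psi'(d/2)$ there is no evidence of variance
heterogeneity and $d_0 = \infty$: every gene's variance collapses to $s_0^2 =
\exp(\bar e)$. The posterior variance
$\tilde s^2_g = (d_0 s_0^2 + d\, s^2_g)/(d_0 + d)$
always lies between $s^2_g$ and $s_0^2$, and the moderated statistic

$$\tilde t_g = \frac{\bar x_{a,g} - \bar x_{b,g}}
  {\sqrt{\tilde s^2_g\,(1/n_a + 1/n_b)}}$$

is referred to a $t$ distribution on $d_0 + d$ degrees of freedom. Genes with
zero residual variance are excluded from the moment matching (their log
variance is undefined) but still receive a posterior variance; an atlas in
which *every* gene has zero residual variance is an error. The test suite
checks this machinery to $10^{-8}$ against a separate step-by-step evaluation
of the same moment equations (with the trigamma inversion done by root
bracketing rather than Newton), and against an independent reference
implementation of the moderated-t method.

### Selection and contrasts

A gene enters the signature when its BH-adjusted $q < 0.05$ (strict, matching
the "FDR below 5%" convention) **and** $|\log_2 \text{FC}| \ge \log_2 5$.
The 5-fold threshold is interpreted as a difference of group means in log2
space, since the analysis scale is log2 throughout. The FDR procedure is
Benjamini–Hochberg step-up — the standard companion of the moderated test;
the unadjusted test is two-sided.

Two contrasts are run by `derive_stage_signatures()`: **E6.5** (E6.5+E7.5
versus E9.5+E10.5+adult) and **adult** (adult versus all four retained
embryonic stages). E8.5 is omitted from both: expression there is a
transition between the early and late programs, and including it would dilute
both groups. Contrast groups pool all matching samples without per-tissue
averaging; the atlas design gives each stage and tissue equal replication, so
pooling and averaging coincide in expectation, and pooling keeps the residual
degrees of freedom honest.

## Homology mapping

Mouse signatures are translated with a Homologene-format table
(`read_homologene()`, `map_signature()`). One mouse gene with several human
homologs contributes all of them (maximizing coverage), several mouse genes
sharing one human homolog with consistent weights contribute it once, an
unmapped mouse gene is dropped and counted, and a human gene reachable from
both an up- and a down-weighted mouse gene is contradictory and is dropped
from both sets and reported as a conflict. The mapping report accounts for
every input gene. Because homology databases evolve, the table is always an
input, never bundled.

## Plasticity scoring

Scoring (`collapse_probes()`, `zscore_rows()`, `score_signature()`) follows
three fixed conventions:

* **Probe collapsing** keeps, per gene, the probe with the highest
  across-sample variance; variance uses the unbiased $n-1$ estimator (the
  same convention as z-scoring), and exact ties go to the lexicographically
  smallest probe id so the result is deterministic.
* **Z-normalization** is computed per evaluation data set — scores are
  cohort-relative and deliberately not comparable across cohorts. Constant
  genes are dropped with a warning (their z-score is undefined).
* The **score** of a sample is the mean of $w_g z_g$ over the signature genes
  present in the matrix, $w_g = \pm 1$; absent genes are skipped and counted.
  A single-gene signature's score is exactly that gene's z-score, which is
  how single-gene prognostic analyses are realized.

Scores are therefore invariant to positive affine transforms of any gene's
raw values, are exactly negated when up and down sets are swapped, and a
signature of pure-noise genes scores with mean ≈ 0 and variance ≈ $1/|G|$.
For metastatic-competence calls, a strictly positive E6.5-type score is
classified metastatic-competent; zero is non-competent, because a *positive*
score is the stated competence criterion.

## Survival stratification

`run_outcome_analysis()` restricts the clinical records to one endpoint (DMFS
or RFS), z-scores the cohort, scores the signature, splits patients at the
cohort **median** score (high = strictly above; a `sign` split at zero is
available by flag — the median is the common signature-stratification
convention and guarantees balanced groups), and compares the groups with:

* Kaplan–Meier product-limit curves (events precede censorings at tied
  times — the standard convention);
* the two-group log-rank test (hypergeometric expectation and variance at
  each distinct event time, $\chi^2_1$ reference); and
* **t10**, the earliest *observed event time* at which a group's KM survival
  is ≤ 0.90. Outcome events are rare in these cohorts, so comparing the time
  to the first 10% of events is more stable than medians. t10 is defined on
  the KM scale so censoring is respected; when survival never reaches 0.90,
  t10 is "not reached" and the difference is undefined rather than imputed.
  Both groups' t10 values are always reported, so the sign convention of the
  difference (low minus high) is unambiguous.

No multiple-testing correction is applied across signatures or cohorts;
per-cohort p-values are reported as is.

## The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated; they are pure functions of their arguments including the seed.

* **Atlas** (`generate_atlas()`): five embryonic stages and ≥ 3 adult tissues
  with equal replication (default 4), plus cell-line / stimulated /
  undeveloped decoys that filtering must remove (the cell-line decoy carries
  the early-embryonic program, so a filtering failure visibly contaminates
  the contrast). Genes have per-gene baselines (uniform on 6–10 log2 units)
  plus additive Gaussian noise in log2 space (default sd 0.5) — the standard
  microarray approximation. A planted up-program (default 150 genes) is
  elevated by `log2_effect` (default 3) at E6.5/E7.5, a planted down-program
  (default 30 genes) at E9.5/E10.5/adult, and both sit halfway in between at
  E8.5, mimicking the transition that motivates omitting that stage. The
  matrix is emitted on the linear scale so the log2 step is exercised.
  Note a structural consequence of this two-program design: in the *adult*
  contrast each planted program straddles the groups, so its maximal
  attainable fold change is half the planted effect (1.5 log2 units at the
  defaults), below the log2(5) cut — the adult signature is empty by design
  under the default truth, and the pipeline tolerates an empty contrast.
* **Cohorts** (`generate_cohort()`): each patient has a latent plasticity
  level $L \sim N(0,1)$; up genes express $L$ plus noise, down genes $-L$
  plus noise, background genes pure noise. Event times are exponential with
  hazard $0.01 \cdot \text{HR}^{[L > \text{median}]}$ per study time unit (a
  months-like scale; the time unit is carried as opaque "study time units"
  since clinical exports rarely declare it) — the simplest model with a known
  log-rank power benchmark. Censoring is an independent exponential whose
  rate is solved numerically so the expected censored fraction equals
  `censoring_rate` (default 0.5, typical of breast-cancer follow-up);
  independent censoring keeps the KM estimator unbiased so recovery tests are
  clean.
* **Cell-line panels** (`generate_cell_line_panel()`): metastatic lines carry
  the up genes at $+$`shift` and down genes at $-$`shift` z-units,
  non-metastatic lines the reverse.
* **Homology tables** (`generate_homology_table()`): per mouse gene,
  independent draws decide unmapped status and one-to-two mapping at the
  stated fractions.

What the generators do **not** emulate: probe-level effects and probe sets
(atlas features are already gene-level; probe collapsing is tested on its own
fixtures), batch and platform effects, non-proportional hazards, informative
censoring, correlated co-expression structure beyond the single latent
factor, and the heavy-tailed intensity distributions of real arrays. Passing
tests therefore demonstrate correctness of the *procedure* under a clean
generative model, not performance on real cohorts.

## Problem sizes and numerical choices

The validation suite uses desk-scale problem sizes chosen to make the
statistical checks sharp: recovery runs use the default atlas
(2,180 genes, 4 samples per group, 10 seeds), calibration uses 2,000 null
cohorts of 100 patients and a 2,000-gene null atlas, power uses 100 cohorts
of 200 patients at hazard ratio 3, and law-of-large-numbers checks use up to
$10^5$ simulated patients. Tolerances follow the estimator: exact identities
(score negation, KM on worked examples) are asserted to machine precision or
$10^{-12}$, oracle equivalences to $10^{-8}$–$10^{-9}$, and Monte-Carlo
quantities to 3-sigma binomial or quantile bands.

Numerical details worth knowing: the trigamma inversion iterates Newton steps
to relative $10^{-12}$ with closed-form endpoints for extreme arguments; BH
adjustment clips to [0, 1] and preserves input order; TSV writers emit 17
significant digits so write-then-read is the identity well below $10^{-12}$;
and all generators restore the caller's RNG state.

## Known limitations

* t10 is a quantile crossing estimated from roughly the first tenth of each
  group's events; in cohorts of a few hundred patients its sampling noise is
  one to a few study-time units, so an occasional t10 inversion between
  clearly separated groups (with a highly significant log-rank test in the
  same cohort) is expected over many simulations. Interpret t10 as a
  descriptive effect-size summary, not a test.
* Scores are cohort-relative (per-data-set z-normalization); pooling scores
  across cohorts requires a shared normalization that this package
  deliberately does not provide.
* The derivation assumes a two-group contrast on log2 data; covariate
  adjustment and multi-group designs are out of scope.
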