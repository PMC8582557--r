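---
title: "Digital cytometry and STEM scoring of the gastric tumor microenvironment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tmescore methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Bulk tumor transcriptomes mix signals from epithelial, stromal and immune
cells. `tmescore` implements a digital-cytometry pipeline for gastric
cancer that (i) builds a cell-population signature matrix from an annotated
single-cell reference, (ii) deconvolves bulk samples into relative
population fractions, (iii) summarises each sample by ratio scores,
chiefly the STEM score

$$\mathrm{STEM} = \frac{f_{\mathrm{EMEC}}}{f_{\mathrm{Stromal}}} +
  \frac{f_{\mathrm{T\,adaptive}}}{f_{\mathrm{Monocytes}}},$$

the sum of the most prognostic non-immune ratio (early malignant
epithelial cells, EMEC, over stromal cells) and the most prognostic immune
ratio (adaptive T cells over monocytes), and (iv) relates scores and
spectral TME subtypes to overall survival with Cox models, log-rank tests
and fixed-effects meta-analysis. Higher STEM scores indicate an
epithelial/lymphocyte-dominated microenvironment and longer survival;
lower scores indicate stromal/monocyte dominance and shorter survival.

Because the real cohorts (one scRNA-seq reference of gastric biopsies
across the gastritis-to-early-cancer cascade, plus four bulk cohorts with
outcomes) cannot be redistributed, the package ships synthetic-data
generators with planted ground truth; every pipeline stage is exercised
and validated against that truth.

## Reference preprocessing

`qc_filter()` applies three filters in a fixed order, each a literal
reading of the underlying rules:

1. *Type level*: keep cell types with **more than** 20 cells spanning
   **at least** 2 disease stages. A 25-cell type confined to one stage is
   removed outright.
2. *Cell level*: cells with **fewer than** 500 expressed genes are
   removed, so a cell with exactly 500 is kept.
3. *Gene level*: genes detected in **less than** 2% of the remaining
   cells are removed, so exactly 2% survives.

The order matters (the gene detection fractions are computed after cell
removal); the reported dimensions of a filtered reference depend on it,
and applying the filter twice changes nothing (idempotence is tested).

`pseudobulk_summarize()` sums counts over cells sharing a grouping key —
(cell type, subject) for gene ranking, (cell type, stage, subject) for the
tree leaves — and `tpm_normalize()` scales each profile to one million.
No gene-length term is used: the reference is 3'-tag droplet data, where
length normalisation is inapplicable; a length vector is accepted
optionally for full-length bulk data.

## Population discovery

Cell-type-informative genes are ranked by a per-gene additive two-way
ANOVA of log2(TPM + 1) on cell type and subject. The published criterion —
a high cell-type F value *compared to* the subject F value — is
formalised as the ratio $F_{\mathrm{celltype}}/F_{\mathrm{subject}}$, the
simplest monotone reading; genes with $F_{\mathrm{subject}} = 0$ rank
above all finite ratios, ordered by $F_{\mathrm{celltype}}$. Designs are
generally unbalanced after QC, so type-II sums of squares are used
(`car::Anova`); on balanced designs this reduces to the textbook
computation, which an independent sums-of-squares oracle verifies to
1e-8 in the test suite. Whether the ANOVA should run on raw or
log-transformed TPM is not fixed by the source description; we use
log2(TPM + 1) (pseudocount 1, base 2), the conventional variance
stabilisation for expression data.

The cluster tree is grown on the top-N (default 100) genes' mean
log-profiles per (cell type, stage), with pairwise distance $1 - r^2$
(Pearson) and Ward linkage. Note a deliberate quirk: $1 - r^2$ treats
perfect anti-correlation as perfect similarity. The metric is implemented
exactly as stated because it is the reference behaviour; `cluster_config`
exposes $1 - r$ as an alternative without changing the default.
`population_stability()` reports how the cut changes across
N ∈ {50, 100, 150, 200}, mirroring the robustness check that motivated
N = 100. Cutting the tree at k = 10 reproduces, on the real reference,
the ten non-immune populations (EMEC, PMEC, enteroendocrine, GMC, goblet,
MSC, PC, PMC, endothelial, stromal); on synthetic references k equals the
number of planted types.

## Signature matrix

For each population, `select_markers()` keeps genes at least two-fold
elevated (mean TPM, pseudocount 1 in numerator and denominator) over all
other populations and significant at p ≤ 0.01 in a one-way ANOVA of the
population's per-subject pseudobulk profiles versus the rest; survivors
are ranked by fold change (ties: smaller p, then gene id — making the
marker count reproducible) and the top M kept. The unit of replication is
the (population, subject) pseudobulk profile rather than single cells,
which avoids pseudo-replication. The two-group ANOVA is computed in
closed form, vectorised over genes, and is verified against
`oneway.test(var.equal = TRUE)` in the tests.

The marker depth M is chosen by `choose_M()`: artificial bulk is built by
summing each biopsy's single-cell counts (`make_artificial_bulk()`), so
the true composition is known; each candidate M is scored by the mean
per-biopsy RMSE between deconvolved and true fractions (Pearson r
reported alongside), and the smallest M wins ties. "True" fractions
default to cell-count proportions; UMI-mass proportions are available
behind the `weight` flag since the right notion is arguable for summed
counts. On the real reference this sweep selects M = 150 over the grid
50–250 (step 50) and yields a 1319-gene signature; the synthetic drivers
use smaller grids at their scale.

Immune fractions are handled by the same machinery against any
fine-grained immune signature; `merge_lineages()` collapses fine types
into major lineages (e.g. naive/memory CD4 and CD8 T cells into adaptive
T) and conserves fraction mass exactly. The published 17-type immune
signature is not redistributed; the analysis scripts build a synthetic
stand-in, clearly labelled as such.

## Deconvolution

`deconvolve()` follows the CIBERSORT support-vector-regression recipe,
whose internals are not restated in the source description and are
therefore adopted from the published algorithm: per sample, restrict to
genes shared with the signature, z-standardise mixture and signature, fit
a linear-kernel ν-SVR for ν ∈ {0.25, 0.5, 0.75}, keep the ν minimising
reconstruction RMSE on the signature genes, clip negative coefficients to
zero and renormalise to the simplex. Every choice sits in
`deconv_config`. Consequences tested as invariants: fractions are
non-negative and sum to one; scaling a mixture by a positive constant
changes nothing; permuting signature columns permutes fractions; a
noiseless mixture $S w$ returns $w$ (to 1e-3, cross-checked against a
non-negative least-squares oracle).

The cross-platform batch correction of the full CIBERSORTx workflow is
out of scope; microarray inputs are assumed pre-quantile-normalised, and
only non-negativity is checked. This simplification is deliberate and
documented: group-mode/single-cell-mode correction would dominate the
package without changing the statistical pipeline downstream.

## Scores

Ratio scores are computed for every ordered pair of non-rare populations
— both A/B and B/A, since both directions can carry distinct prognostic
value — where non-rare means a cohort-mean fraction above 5% of the
compartment ("cohort-level" because the rarity rule describes the
population's share of the total compartment, not any single sample).
Denominators carry a small stabiliser ε = 1e-6 because clipping can
produce exact zeros; for fractions comfortably above zero the results
with and without ε are identical, so the choice is benign. The STEM score
is the sum of the EMEC/stromal and adaptive-T/monocyte ratios, and is
invariant to rescaling either compartment.

## Stratification

`optimal_cutoff()` scans score quantiles 0.10–0.90 in steps of 0.01,
dichotomises at each, and fits a univariate Cox model of the binary group
(Wald p; the cutoff criterion is Cox because the optimisation is defined
through proportional-hazards modelling, with log-rank available by
config). The minimising cutoff is returned; ties go to the smaller
quantile, and grid points where a group has no events are skipped with a
warning. The grid-minimal p is optimistically biased — a multiplicity
effect the test suite documents by checking that null data rarely
produce extreme minima.

`tme_subtype()` clusters samples on the four STEM population fractions
(EMEC, stromal, adaptive T, monocytes) by spectral clustering with an RBF
affinity; the bandwidth defaults to the median pairwise distance (a
standard heuristic, unstated in the source). The cluster count is either
fixed (k = 3, the published outcome, is the reproduction default) or
chosen by a majority vote of four validity indices — silhouette,
Calinski–Harabasz, Davies–Bouldin, gap statistic — evaluated on Ward/
Euclidean cuts for k ∈ 2..6. The original choice used a 26-index majority
rule whose constituent votes are unknowable from the text; a four-index
panel keeps the spirit at a fraction of the machinery, and the fallback
is the published k = 3. Clusters are named by composition: H = highest
mean stromal + monocyte (worst prognosis), L = highest mean EMEC +
adaptive T, M = the remainder. The spectral routine is written in the
package (normalised Laplacian, row-normalised eigenvector embedding,
k-means with fixed seed) so assignments are deterministic under
`subtype_config(seed=)`; agreement with `kernlab::specc` on separated
data is a test, not an implementation dependency.

## Survival statistics

Kaplan–Meier curves and log-rank tests come from the `survival` package
(`survfit`/`survdiff`), verified against a hand-worked
observed-minus-expected table on a six-subject example. Cox models use
`coxph` with Efron tie handling (the stronger default; the source is
silent on ties). Stage enters as a factor with level I as reference, so
coefficients read "II vs I", "III vs I", "IV vs I". Multiple testing is
adjusted by Benjamini–Hochberg (`p.adjust`). Fixed-effects meta-analysis
pools per-cohort log hazard ratios with inverse-variance weights — the
closed form is authored here and cross-checked against
`metafor::rma(method = "FE")`.

The prognostic gene screen fits, per gene and cohort, a multivariate Cox
model with the gene as a continuous term plus whatever covariates the
cohort carries (absent covariates are dropped per cohort with a log
message, matching the uneven covariate sets of real validation cohorts).
Expression is z-scored per cohort by default so hazard ratios are
per-SD — the per-gene HR scale in the source is unstated, and reported
magnitudes are consistent with a standardised or log scale; the choice is
configurable. Genes must pass p < 0.05 with the expected direction
(HR > 1 for stromal markers, HR < 1 for EMEC markers) in all cohorts —
relaxing to all-but-one only when the strict rule selects nothing,
mirroring the "three of the four cohorts" narrative — and then achieve
overall p < 1e-5 in the fixed-effects meta-analysis.

## The synthetic-data generators

`simulate_sc_dataset()` draws negative-binomial counts (dispersion 0.5)
around log-normal gene baselines; each cell type owns a disjoint block of
50 marker genes elevated 8-fold; each (subject, gene) pair carries a
log-normal effect (sd 0.2) so the ANOVA's subject factor is non-trivial;
subjects map to stages as in a biopsy cohort spanning NAG → CAG → IM →
EGC. Defaults (2000 genes, six populations, ~1100 cells, nine subjects)
are a desk-scale emulation of a droplet reference; because the data are
3'-tag-like, no gene-length structure is simulated, and dropout beyond
what the negative binomial provides is not modelled. Subject assignment
within each type is Dirichlet-weighted so biopsies genuinely differ in
composition (a composition-free design would make artificial-bulk truths
degenerate).

`simulate_mixtures()` forms signature-weighted combinations with known
simplex weights and multiplicative log-normal noise, so the noiseless
case is exactly linear. `simulate_survival()` draws event times from a
proportional-hazards model with exponential baseline (Weibull behind the
`shape` parameter) and hazard `exp(beta_stem · (score − mean))`, plus
independent exponential censoring; the exponential default keeps
closed-form sanity checks available.

What passing tests on these data do **not** show: robustness to
cross-platform shifts between signature and mixture, to correlated
marker blocks between closely related populations, to ambient RNA or
doublets, or to informative censoring. Those belong to the real-data
regime the pipeline's simplifications explicitly set aside.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by design:
600–2000 genes, 3–6 populations, 50-sample mixture batches, cohorts of
200–1000 for survival recovery, 100 replicates for null coverage. Key
tolerances: noiseless deconvolution 1e-3 (achieved ~1e-5), ANOVA versus
oracle 1e-8, Cox partial-likelihood versus a brute-force scan 1e-3 on the
coefficient. Ties are broken deterministically everywhere (marker
ranking: fold change, then p, then gene id; cutoff: smaller quantile;
choose_M: smaller M), so repeated runs are identical under a fixed seed.

## Known limitations

- The $1 - r^2$ tree distance conflates correlation and anti-correlation;
  retained as the reference behaviour, with $1 - r$ one flag away.
- Relative fractions are compositional: ratio scores are the supported
  cross-sample currency, and absolute abundances are out of scope.
- The optimal-cutoff p-value is not corrected for the grid search; treat
  it as a selection criterion, not an inference.
- The four-index k panel is a proxy for the original 26-index majority
  rule; with ambiguous structure, fix k = 3 explicitly.
- Proportionality diagnostics, time-varying covariates and competing
  risks are not implemented.
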