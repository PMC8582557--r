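# tmescore

Digital cytometry and prognostic scoring of the gastric-cancer tumor
microenvironment (TME).

Bulk tumor expression profiles mix epithelial, stromal and immune signals.
`tmescore` dissects them: it builds a cell-population signature matrix from
an annotated single-cell reference, estimates each bulk sample's relative
population fractions by ν-support-vector regression with non-negativity and
sum-to-one constraints, and summarises every sample by ratio scores — above
all the **STEM score**,

    STEM = f_EMEC / f_Stromal  +  f_Tadaptive / f_Monocytes ,

the sum of the early-malignant-epithelial-to-stromal fraction ratio
(non-immune compartment) and the adaptive-T-to-monocyte ratio (immune
compartment). Higher STEM scores mark an epithelial/lymphocyte-dominated
microenvironment and longer overall survival; lower scores mark
stromal/monocyte dominance and shorter survival. On top of the score the
package provides survival-optimal cutoff search over a quantile grid,
spectral clustering of patients into TME subtypes (H/M/L) on the four STEM
populations, Kaplan–Meier/log-rank and Cox analyses with FDR control,
inverse-variance fixed-effects meta-analysis across cohorts, and a
prognostic marker-gene screen.

The intended users are computational biologists studying tumor composition
from bulk RNA-seq or microarray cohorts with outcome data. Because the
original cohorts cannot be redistributed, the package includes
synthetic-data generators (single-cell counts with planted markers, bulk
mixtures with known proportions, survival with a planted score effect) so
the entire pipeline is testable end to end; the methods vignette
(`vignettes/tmescore-methods.Rmd`) describes the model, every tunable
parameter and the design decisions.

## Worked example

```r
library(tmescore)

# 1. synthetic single-cell reference, QC'd
sim <- simulate_sc_dataset(sim_sc_config(seed = 7))
ref <- qc_filter(sim$data, qc_config(min_genes_per_cell = 100))
ref
#> annotated_counts: 2000 genes x 1080 cells; 6 cell types, 9 subjects, 4 stages

# 2. markers and the signature matrix
pb  <- tpm_normalize(pseudobulk_summarize(ref, c("cell_type", "subject")))
sel <- select_markers(pb, marker_config(M_per_population = 50))
sig <- build_signature(pb, sel, name = "demo")
sig
#> signature_matrix 'demo': 300 genes x 6 populations

# 3. bulk mixtures with known composition, deconvolved
P <- matrix(rexp(20 * 6), 20); P <- P / rowSums(P)
colnames(P) <- colnames(sig$values)
mx <- simulate_mixtures(sig, sim_mixture_config(P, noise_sd = 0.2, seed = 8))
fr <- deconvolve(sig, mx$bulk, compartment = "nonimmune")
mean(abs(fr$fractions - P))       # mean fraction error against the truth
#> [1] 0.0123

# 4. survival: planted protective effect, recovered by Cox and the cutoff
set.seed(1)
scores <- rgamma(300, shape = 8, rate = 2)          # STEM-like scores
sv <- simulate_survival(scores, sim_survival_config(beta_stem = -0.4,
                                                    censor_rate = 0.02,
                                                    seed = 9))
cox_fit(sv, "stem_score", fdr = FALSE)[, c("term", "HR", "CI_low", "CI_high", "p")]
#>         term    HR CI_low CI_high        p
#> 1 stem_score 0.672  0.606   0.746 9.04e-14     # exp(-0.4) = 0.67 recovered
optimal_cutoff(sv$stem_score, sv)
#> optimal cutoff 3.945 at quantile 0.54 (p = 1.68e-12)

# 5. fixed-effects meta-analysis of per-cohort log hazard ratios
meta_fixed(c(-0.105, -0.062, -0.117, -0.151),
           c(0.036, 0.019, 0.044, 0.036),
           c("training", "valA", "valB", "valC"))
#> fixed-effects meta: HR 0.915 (95% CI 0.889-0.941), z = -6.18, p = 6.28e-10 (4 studies)
```

The numbers mean: deconvolution recovers the planted composition to about
one percentage point per population under realistic log-normal noise; the
Cox model recovers the planted per-unit hazard ratio; the quantile-grid
search finds the survival-optimal score cutoff; and pooling four cohorts'
adjusted log hazard ratios gives the overall effect of the score with its
z-test.

## Analysis workflow

The `analysis/` directory holds the numbered drivers that run the whole
study pipeline on synthetic cohorts and write their tables under
`results/`:

1. `01_simulate_reference.R` — simulate + QC the single-cell reference,
   write counts (MTX/TSV) and TPM pseudobulk.
2. `02_build_signature.R` — ANOVA gene ranking, population tree (Newick),
   marker selection, marker-depth sweep on artificial bulk, signature TSV.
3. `03_deconvolve_and_score.R` — four synthetic bulk cohorts, non-immune +
   immune deconvolution, lineage merging, ratio and STEM scores.
4. `04_survival_analysis.R` — per-cohort Cox models, optimal cutoff,
   Kaplan–Meier comparisons, STEM meta-analysis, TME subtyping, and the
   prognostic gene screen.

Run them in order from the repository root: `Rscript analysis/01_...`.

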