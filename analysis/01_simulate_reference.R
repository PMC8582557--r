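#!/usr/bin/env Rscript
# Step 1: simulate the annotated single-cell reference (the stand-in for a
# gastric biopsy scRNA-seq cohort spanning NAG -> CAG -> IM -> EGC), apply
# the QC filters, and write the filtered counts plus the (population,
# subject) pseudobulk used by every later step.

suppressPackageStartupMessages(library(tmescore))
dir.create("results", showWarnings = FALSE)

cfg <- sim_sc_config(seed = 101)
sim <- simulate_sc_dataset(cfg)
cat(sprintf("simulated reference: %d genes x %d cells (%d populations, %d subjects)\n",
            nrow(sim$data$counts), ncol(sim$data$counts),
            length(cfg$cell_types), length(cfg$subjects)))

filtered <- qc_filter(sim$data, qc_config(min_genes_per_cell = 100))
cat(sprintf("after QC: %d genes x %d cells\n",
            nrow(filtered$counts), ncol(filtered$counts)))

write_annotated_counts(filtered, "results/reference")

pb <-tpm_normalize(pseudobulk_summarize(filtered, c("cell_type", "subject")))
utils::write.table(
  data.frame(gene = rownames(pb$values), pb$values, check.names = FALSE),
  "results/pseudobulk_tpm.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

# ground-truth marker sets, for the precision check in step 2
mk <- data.frame(population = rep(names(sim$markers),
                                  lengths(sim$markers)),
                 gene = unlist(sim$markers, use.names = FALSE))
utils::write.table(mk, "results/planted_markers.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote results/reference.*, results/pseudobulk_tpm.tsv, results/planted_markers.tsv\n")
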