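#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-species snRNA-seq study.
#
# The default design plants the four conserved GABAergic subclasses (PVALB,
# SST, LAMP5, VIP) in human and mouse plus the mouse-private Meis2 type,
# two batches per species, three 50-gene co-expression modules (module M1
# doubles as the AD-risk module, up-regulated 2-fold in disease cells), and
# ten regulons spanning conserved, species-specific and silent activation
# archetypes. Everything downstream is measured against this planted truth.

suppressPackageStartupMessages(library(crossneuro))

seed <- 1L
out <- "results/01_data"
design <- sim_design(seed = seed)
sim <- simulate_species(design)

for (sp in names(sim$tables))
  write_cell_table(sim$tables[[sp]], file.path(out, sp))
for (sp in names(sim$homology))
  write_homology(sim$homology[[sp]],
                 file.path(out, paste0("homology_", sp, ".tsv")))
write_gmt(sim$truth$regulons, file.path(out, "regulons.gmt"))
write_gmt(list(gene_set("risk", sim$truth$risk_genes)),
          file.path(out, "risk.gmt"))
write_truth(sim$truth, file.path(out, "truth"))

rep <- truth_report(sim$truth)
cat("cells per species x subtype:\n")
print(rep$subtypes)
cat(sprintf("\nplanted: %d modules (%d risk genes), %d regulons, %d one-to-one homologs (mouse)\n",
            length(unique(rep$modules$module)), length(sim$truth$risk_genes),
            nrow(rep$regulons), nrow(sim$homology$mouse$pairs)))
cat("written under", out, "\n")
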