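#!/usr/bin/env Rscript
# Stage 2: cross-species integration and subtype conservation scoring.
#
# Mouse genes are renamed to their one-to-one human orthologs, inhibitory
# (GAD1/GAD2-positive) cells are extracted and subsampled to 100 per
# subtype, batches are merged within species, and the two species are
# aligned by reciprocal-PCA anchor correction into a common 30-dimensional
# space, clustered into at least 31 joint clusters. The conservation score
# of a (mouse subtype, human subtype) pair is the summed minimum of their
# cluster-proportion vectors (1 minus total-variation distance).

suppressPackageStartupMessages(library(crossneuro))

seed <- 1L
cfg <- run_config(seed = seed)
data_dir <- "results/01_data"
out <- "results/02_conservation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

human <- read_cell_table_dir(file.path(data_dir, "human"))
mouse <- read_cell_table_dir(file.path(data_dir, "mouse"))
hmap <- read_homology(file.path(data_dir, "homology_mouse.tsv"), "mouse")
mouse <- map_to_reference(mouse, hmap)

inhib_h <- extract_inhibitory(human, cfg$inhib_markers, scale = cfg$scale_factor)
inhib_m <- extract_inhibitory(mouse, cfg$inhib_markers, scale = cfg$scale_factor)
rt <- subsample_subtypes(inhib_h, cfg$subsample_n, derive_seed(seed, "sub_h"))
qt <- subsample_subtypes(inhib_m, cfg$subsample_n, derive_seed(seed, "sub_m"))
shared <- intersect(rt$gene_ids, qt$gene_ids)
rt <- subset_cells(rt, genes = shared)
qt <- subset_cells(qt, genes = shared)

rn <- correct_batches(normalize_log1p(rt, cfg$scale_factor), rt$annot$batch)
qn <- correct_batches(normalize_log1p(qt, cfg$scale_factor), qt$annot$batch)
hvg <- names(select_hvg(rbind(rn, qn), min(cfg$hvg_n_cross, length(shared))))
corr <- anchor_correct(rn[, hvg], qn[, hvg], d = cfg$pcs_cross,
                       k_anchor = cfg$k_anchor)
cl <- cluster_cells(corr$coords, cfg$target_k, derive_seed(seed, "cluster"))
annot <- rbind(rt$annot, qt$annot)

overlap <- conservation_matrix(cl, annot, "mouse", "human")
utils::write.table(data.frame(subtype = rownames(overlap), overlap),
                   file.path(out, "overlap_mouse_human.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
for (sp in c("human", "mouse")) {
  tab <- if (sp == "human") human else mouse
  r <- subtype_correlation(tab, scale = cfg$scale_factor)
  utils::write.table(data.frame(subtype = rownames(r), round(r, 6)),
                     file.path(out, paste0("subtype_correlation_", sp, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

cat(sprintf("joint clusters: %d (target >= %d); anchors: %d\n",
            cl$k, cfg$target_k, corr$n_anchors))
cat("\nconservation matrix (mouse rows x human columns):\n")
print(round(overlap, 2))
conserved <- diag(overlap[colnames(overlap), colnames(overlap)])
cat(sprintf("\nconserved-pair overlap: %.2f-%.2f; Meis2 (mouse-private) max: %.2f\n",
            min(conserved), max(conserved), max(overlap["Meis2", ])))
cat("written under", out, "\n")
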