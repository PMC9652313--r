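#!/usr/bin/env Rscript
# Stage 4: co-expression modules, risk-gene enrichment and DEGs.
#
# Human cells are aggregated into 10-cell pseudocells within
# subtype x condition x batch strata, genes are filtered by median absolute
# deviation (< 0.1 dropped), and modules are detected from the topological
# overlap of the |Pearson|^6 adjacency, merged at eigengene correlation
# >= 0.75. Modules are scored for risk-gene enrichment with an upper-tail
# hypergeometric test on a 20,000-gene background, disease-vs-control DEGs
# are called per subtype (Wilcoxon, BH, min.pct and logFC filters at 0.25),
# and the high-confidence risk genes are the per-subtype intersection
# DEGs x risk set x top module, finally correlated across species.

suppressPackageStartupMessages(library(crossneuro))

seed <- 1L
cfg <- run_config(seed = seed)
data_dir <- "results/01_data"
out <- "results/04_modules"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

human <- read_cell_table_dir(file.path(data_dir, "human"))
mouse <- map_to_reference(read_cell_table_dir(file.path(data_dir, "mouse")),
                          read_homology(file.path(data_dir, "homology_mouse.tsv"),
                                        "mouse"))
risk <- read_gmt(file.path(data_dir, "risk.gmt"))[[1]]$genes

norm <- normalize_log1p(human, cfg$scale_factor)
cond <- human$annot$condition
genes_used <- select_wgcna_genes(norm[cond == "control", ],
                                 norm[cond == "disease", ],
                                 n = cfg$hvg_n_cross)
pm <- make_pseudocells(human, size = cfg$pseudocell_size,
                       seed = derive_seed(seed, "pseudo"), norm = norm)
kept <- intersect(genes_used, mad_filter(pm, cfg$mad_threshold))
pm$values <- pm$values[, kept]
fit <- tom_modules(pm, power = cfg$power,
                   min_module_size = cfg$min_module_size,
                   merge_cut_height = cfg$merge_cut_height)
utils::write.table(data.frame(gene = names(fit$modules), module = fit$modules),
                   file.path(out, "gene_module.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

enr <- module_risk_enrichment(fit, risk, N = cfg$background_n)
utils::write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("module risk enrichment:\n")
print(enr, row.names = FALSE)

top_module <- enr$module[which.min(enr$p)]
top_genes <- names(fit$modules)[fit$modules == top_module]
degs <- lapply(split(seq_len(n_cells(human)), human$annot$subtype),
               function(idx) deg_wilcoxon(subset_cells(human, idx),
                                          min_pct = cfg$min_pct,
                                          logfc_threshold = cfg$logfc_threshold,
                                          scale = cfg$scale_factor))
hc <- high_confidence_risk_genes(degs, risk, top_genes)
cat(sprintf("\nhigh-confidence risk genes per subtype: %s\n",
            paste(names(hc), attr(hc, "sizes"), sep = "=", collapse = ", ")))
hc_genes <- sort(unique(unlist(hc)))
writeLines(hc_genes, file.path(out, "high_confidence_risk_genes.txt"))

if (length(hc_genes) >= 3) {
  xc <- crossspecies_gene_correlation(human, list(mouse = mouse), hc_genes,
                                      scale = cfg$scale_factor)
  utils::write.table(xc, file.path(out, "crossspecies_correlation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("cross-species expression correlation of those genes: r = %.2f-%.2f\n",
              min(xc$r), max(xc$r)))
}
cat("written under", out, "\n")
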