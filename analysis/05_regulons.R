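#!/usr/bin/env Rscript
# Stage 5: regulon activity, binarisation and activation grouping.
#
# Both species are merged on shared homologous genes; each regulon's
# activity per cell is the normalised area under the recovery curve of its
# targets within the top 5% of the cell's expression ranking. Activities
# are binarised with a two-component Gaussian mixture per regulon, regulons
# active in at least one cell are kept, activation fractions per
# species x subtype form the activity profile, and k-means (k = 8) groups
# the profiles into activation archetypes.

suppressPackageStartupMessages(library(crossneuro))

seed <- 1L
cfg <- run_config(seed = seed)
data_dir <- "results/01_data"
out <- "results/05_regulons"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

human <- read_cell_table_dir(file.path(data_dir, "human"))
mouse <- map_to_reference(read_cell_table_dir(file.path(data_dir, "mouse")),
                          read_homology(file.path(data_dir, "homology_mouse.tsv"),
                                        "mouse"))
regulons <- read_gmt(file.path(data_dir, "regulons.gmt"), regulon = TRUE)

shared <- intersect(human$gene_ids, mouse$gene_ids)
counts <- rbind(human$counts[, shared], mouse$counts[, shared])
annot <- rbind(human$annot, mouse$annot)

scores <- activity_scores(counts, regulons, top_fraction = cfg$top_fraction)
bin <- binarize_activity(scores, seed = derive_seed(seed, "binarize"))
active <- filter_active(bin$binarized)
prof <- activation_profile(bin$binarized[, active, drop = FALSE],
                           paste(annot$species, annot$subtype, sep = ":"))
groups <- group_regulons(prof, k = min(cfg$kmeans_k, nrow(prof)),
                         seed = derive_seed(seed, "groups"))

utils::write.table(data.frame(regulon = rownames(prof), round(prof, 4),
                              group = groups[rownames(prof)],
                              check.names = FALSE),
                   file.path(out, "activation_profile.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
export_regulon_network(Filter(function(r) r$name %in% active, regulons), out)

cat(sprintf("%d of %d regulons active in at least one cell\n",
            length(active), length(regulons)))
cat("\nactivation fractions (rows: regulons; columns: species:subtype):\n")
print(round(prof, 2))
cat("\ngroups:\n")
print(groups)
cat(sprintf("\nconserved (R_all, group %d) and species-specific (R_human %d / R_mouse %d) programs separate\n",
            groups[["R_all"]], groups[["R_human"]], groups[["R_mouse"]]))
cat("written under", out, "\n")
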