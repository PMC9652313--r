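#' Planted-truth validation experiments
#'
#' Self-contained experiments that exercise whole pipeline stages on
#' synthetic designs with known ground truth and summarise how well the
#' planted structure is recovered. They back both the test suite and the
#' analysis scripts.
#'
#' @name experiments
NULL

#' Cross-species conservation recovery on the default design
#'
#' Simulates the default two-species design (four conserved GABAergic
#' subclasses plus one mouse-private type), runs homolog mapping, 100-cell
#' subtype subsampling, batch correction, reciprocal-PCA anchor integration,
#' joint clustering into at least `target_k` clusters, and the
#' cluster-overlap conservation matrix.
#'
#' @param seed integer seed
#' @param config a `run_config`
#' @return list: `overlap` (matrix), `conserved_min`, `specific_max`, `k`
#' @export
experiment_conservation <- function(seed, config = run_config(seed = seed)) {
  design <- sim_design(seed = derive_seed(seed, "cons_design"))
  sim <- simulate_species(design)
  ref <- design$species[1]
  sp <- setdiff(design$species, ref)[1]
  mapped <- map_to_reference(sim$tables[[sp]], sim$homology[[sp]])
  rt <- subsample_subtypes(sim$tables[[ref]], config$subsample_n,
                           derive_seed(seed, "cons_sub_ref"))
  qt <- subsample_subtypes(mapped, config$subsample_n,
                           derive_seed(seed, "cons_sub_query"))
  shared <- intersect(rt$gene_ids, qt$gene_ids)
  rt <- subset_cells(rt, genes = shared)
  qt <- subset_cells(qt, genes = shared)
  # batch merging keeps its own tight neighborhood (k = 5): wide mutual
  # neighborhoods are only appropriate for the cross-species step
  rn <- correct_batches(suppressWarnings(normalize_log1p(rt, config$scale_factor)),
                        rt$annot$batch, d = config$pcs_cross)
  qn <- correct_batches(suppressWarnings(normalize_log1p(qt, config$scale_factor)),
                        qt$annot$batch, d = config$pcs_cross)
  hvg <- names(select_hvg(rbind(rn, qn), min(config$hvg_n_cross, length(shared))))
  corr <- anchor_correct(rn[, hvg, drop = FALSE], qn[, hvg, drop = FALSE],
                         d = config$pcs_cross, k_anchor = config$k_anchor)
  cl <- cluster_cells(corr$coords, target_k = config$target_k,
                      seed = derive_seed(seed, "cons_cluster"))
  annot <- rbind(rt$annot, qt$annot)
  overlap <- conservation_matrix(cl, annot, sp, ref)
  shared_types <- design$shared_subtypes
  specific <- unlist(design$specific_subtypes, use.names = FALSE)
  conserved <- diag(overlap[shared_types, shared_types])
  list(overlap = overlap,
       conserved_min = min(conserved),
       specific_max = if (length(specific)) max(overlap[specific, ]) else NA_real_,
       k = cl$k)
}

# the dedicated co-expression design: one subtype, three 50-gene modules
# with unit loading, enough cells for 500 pseudocells of size 10
module_recovery_design <- function(seed) {
  sim_design(species = "human", shared_subtypes = "T1",
             specific_subtypes = list(), n_markers = 5,
             cells_per_subtype = 5000, n_batches = 1,
             n_genes = 600, module_sizes = c(50L, 50L, 50L),
             module_lambda = c(1, 1, 1), regulons = list(),
             seed = seed)
}

#' Co-expression module recovery and risk enrichment
#'
#' Simulates three 50-gene modules (latent loading 1) in a 5000-cell
#' dataset, aggregates 500 pseudocells of 10 cells, filters genes by MAD,
#' detects topological-overlap modules, and scores risk enrichment against
#' the planted risk module.
#'
#' @param seed integer seed
#' @param config a `run_config`
#' @return list: `ari` (gene-module ARI over planted module genes),
#'   `n_modules`, `risk_is_top` (planted risk module attains the smallest
#'   enrichment p), `min_p`, `enrichment` (data.frame)
#' @export
experiment_module_recovery <- function(seed, config = run_config(seed = seed)) {
  design <- module_recovery_design(derive_seed(seed, "mod_design"))
  sim <- simulate_species(design)
  tab <- sim$tables$human
  pm <- make_pseudocells(tab, size = config$pseudocell_size,
                         seed = derive_seed(seed, "mod_pseudo"))
  kept <- mad_filter(pm, threshold = config$mad_threshold)
  pm$values <- pm$values[, kept, drop = FALSE]
  fit <- tom_modules(pm, power = config$power,
                     min_module_size = config$min_module_size,
                     merge_cut_height = config$merge_cut_height)
  truth <- stats::setNames(sim$truth$modules$module, sim$truth$modules$gene)
  common <- intersect(names(truth), names(fit$modules))
  ari_val <- ari_index(fit$modules[common], truth[common])
  enr <- module_risk_enrichment(fit, sim$truth$risk_genes,
                                N = config$background_n)
  top <- enr$module[which.min(enr$p)]
  top_genes <- names(fit$modules)[fit$modules == top]
  risk_recall <- mean(sim$truth$risk_genes %in% top_genes)
  list(ari = ari_val, n_modules = nrow(enr),
       risk_is_top = risk_recall > 0.5, min_p = min(enr$p), enrichment = enr)
}

#' Differential-expression calibration and power
#'
#' Null: a dataset simulated with zero disease effect is tested
#' disease-vs-control; reports the fraction of tested genes that reach BH
#' significance. Power: the same design with a 2-fold (one log2 unit)
#' disease effect on the risk module; reports whether a planted DE gene is
#' recovered.
#'
#' @param seed integer seed
#' @param effect log2 fold change (0 for the null)
#' @param config a `run_config`
#' @return list: `fpr` (null fraction at BH 0.05 over tested genes),
#'   `n_tested`, `hit` (planted gene detected; NA for the null)
#' @export
experiment_deg <- function(seed, effect = 0,
                           config = run_config(seed = seed)) {
  design <- sim_design(species = "human", shared_subtypes = "T1",
                       specific_subtypes = list(), n_markers = 5,
                       cells_per_subtype = 400, n_batches = 1,
                       n_genes = 300, module_sizes = 50L, module_lambda = 0,
                       regulons = list(), disease_effect = effect,
                       seed = derive_seed(seed, "deg_design"))
  sim <- simulate_species(design)
  res <- deg_wilcoxon(sim$tables$human, group_by = "condition",
                      min_pct = config$min_pct,
                      logfc_threshold = config$logfc_threshold,
                      scale = config$scale_factor)
  gene <- sim$truth$risk_genes[1]
  list(fpr = if (nrow(res)) mean(res$p_adj < 0.05) else 0,
       n_tested = nrow(res),
       hit = if (effect == 0) NA else
         gene %in% res$gene[res$p_adj < 0.05])
}

#' MetaNeighbor AUROC of an informative vs a random gene set
#'
#' Simulates one species with inhibitory (GAD-positive) and other subtypes,
#' then scores (a) the inhibitory program (GAD markers plus the inhibitory
#' subtypes' marker blocks) and (b) a size-matched random gene set with the
#' supervised 20-cell / 10-iteration protocol.
#'
#' @param seed integer seed
#' @param config a `run_config`
#' @return list: `marker` and `random`, each with `mean` and `sd`
#' @export
experiment_metaneighbor <- function(seed, config = run_config(seed = seed)) {
  design <- sim_design(species = "human",
                       shared_subtypes = c("I1", "I2", "E1", "E2"),
                       specific_subtypes = list(),
                       inhibitory_subtypes = c("I1", "I2"),
                       cells_per_subtype = 150, n_genes = 800, n_markers = 15,
                       module_sizes = integer(0), module_lambda = numeric(0),
                       regulons = list(),
                       seed = derive_seed(seed, "mn_design"))
  sim <- simulate_species(design)
  tab <- sim$tables$human
  mk <- sim$truth$markers
  marker_set <- c("GAD1", "GAD2", mk$gene[mk$subtype %in% c("I1", "I2")])
  set.seed(derive_seed(seed, "mn_random"))
  random_set <- sample(setdiff(tab$gene_ids, c(marker_set, mk$gene)),
                       length(marker_set))
  run <- function(genes)
    run_supervised(tab, genes, positive_subtypes = c("I1", "I2"),
                   n_cells = config$mn_cells, n_iter = config$mn_iter,
                   seed = derive_seed(seed, "mn_run"),
                   scale = config$scale_factor)
  list(marker = run(marker_set), random = run(random_set))
}

#' Recovery of archetypal regulon activation patterns
#'
#' Builds 8 activation archetypes (conserved in all species, absent,
#' single-species, subtype-restricted, broad) over 2 species x 4 subtypes,
#' draws 5 regulons per archetype with binomial sampling noise at
#' `n_cells` cells per column, and groups them by k-means.
#'
#' @param seed integer seed
#' @param n_cells cells per (species, subtype) column
#' @return list: `ari` vs the archetype labels, `groups`, `truth`
#' @export
experiment_regulon_archetypes <- function(seed, n_cells = 200) {
  arch <- rbind(
    conserved_all   = rep(0.8, 8),
    absent          = rep(0.02, 8),
    human_only      = c(rep(0.8, 4), rep(0.02, 4)),
    mouse_only      = c(rep(0.02, 4), rep(0.8, 4)),
    pvalb_conserved = rep(c(0.8, 0.02, 0.02, 0.02), 2),
    sst_vip         = rep(c(0.02, 0.8, 0.02, 0.8), 2),
    human_pvalb     = c(0.8, rep(0.02, 7)),
    broad_medium    = rep(0.45, 8))
  truth <- rep(rownames(arch), each = 5)
  set.seed(derive_seed(seed, "regulon_arch"))
  prof <- t(vapply(seq_along(truth), function(i)
    stats::rbinom(8, n_cells, arch[truth[i], ]) / n_cells, numeric(8)))
  rownames(prof) <- paste0("r", seq_along(truth))
  groups <- group_regulons(prof, k = 8,
                           seed = derive_seed(seed, "regulon_kmeans"))
  list(ari = ari_index(groups, truth), groups = groups, truth = truth)
}

#' End-to-end separation of conserved vs species-specific regulons
#'
#' Runs the regulon stage of the default design (activity scoring,
#' binarisation, per species-x-subtype activation profile, k-means into 8
#' groups) and checks that the regulon planted as active in all species
#' lands in a different group from each single-species regulon.
#'
#' @param seed integer seed
#' @param config a `run_config`
#' @return list: `separated` (logical), `groups`, `active`
#' @export
experiment_regulon_separation <- function(seed,
                                          config = run_config(seed = seed)) {
  design <- sim_design(seed = derive_seed(seed, "regsep_design"))
  sim <- simulate_species(design)
  ref <- design$species[1]
  mapped <- lapply(names(sim$homology), function(sp)
    map_to_reference(sim$tables[[sp]], sim$homology[[sp]]))
  names(mapped) <- names(sim$homology)
  shared <- Reduce(intersect, c(list(sim$tables[[ref]]$gene_ids),
                                lapply(mapped, `[[`, "gene_ids")))
  counts <- do.call(rbind, c(
    list(sim$tables[[ref]]$counts[, shared, drop = FALSE]),
    lapply(mapped, function(t) t$counts[, shared, drop = FALSE])))
  annot <- do.call(rbind, c(list(sim$tables[[ref]]$annot),
                            lapply(mapped, `[[`, "annot")))
  scores <- activity_scores(counts, sim$truth$regulons,
                            top_fraction = config$top_fraction)
  bin <- binarize_activity(scores, seed = derive_seed(seed, "regsep_bin"))
  active <- filter_active(bin$binarized)
  prof <- activation_profile(bin$binarized[, active, drop = FALSE],
                             paste(annot$species, annot$subtype, sep = ":"))
  groups <- group_regulons(prof, k = min(config$kmeans_k, nrow(prof)),
                           seed = derive_seed(seed, "regsep_kmeans"))
  singles <- intersect(c("R_human", "R_mouse"), names(groups))
  separated <- "R_all" %in% names(groups) && length(singles) > 0 &&
    all(groups[singles] != groups[["R_all"]])
  list(separated = separated, groups = groups, active = active)
}

# adjusted Rand index of two label vectors (contingency-table closed form)
ari_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Byte-level comparison of two pipeline run directories
#'
#' @param dir_a,dir_b run directories
#' @return TRUE iff both contain the same files with identical bytes
#' @export
runs_identical <- function(dir_a, dir_b) {
  fa <- sort(list.files(dir_a, recursive = TRUE))
  fb <- sort(list.files(dir_b, recursive = TRUE))
  if (!identical(fa, fb)) return(FALSE)
  for (f in fa) {
    a <- readBin(file.path(dir_a, f), "raw", file.info(file.path(dir_a, f))$size)
    b <- readBin(file.path(dir_b, f), "raw", file.info(file.path(dir_b, f))$size)
    if (!identical(a, b)) return(FALSE)
  }
  TRUE
}
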