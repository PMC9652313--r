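#' Score every regulon's activity with one ranking pass per cell
#'
#' Same contract as [activity_score()] but amortises the per-cell expression
#' ranking over all regulons.
#'
#' @param table a `cell_table` or cells x genes matrix
#' @param regulons list of `gene_set`s (or character vectors)
#' @param top_fraction fraction of the ranking integrated
#' @return cells x regulons score matrix
#' @export
activity_scores <- function(table, regulons, top_fraction = 0.05) {
  expr <- if (inherits(table, "cell_table")) table$counts else table
  gene_ids <- colnames(expr)
  G <- ncol(expr)
  cutoff <- ceiling(top_fraction * G)
  id_rank <- rank(gene_ids, ties.method = "first")
  target_idx <- lapply(regulons, function(r) {
    targets <- if (inherits(r, "gene_set")) r$genes else r
    which(gene_ids %in% targets)
  })
  names(target_idx) <- vapply(seq_along(regulons), function(i) {
    r <- regulons[[i]]
    if (inherits(r, "gene_set")) r$name else paste0("set", i)
  }, character(1))
  if (any(!lengths(target_idx)))
    stop("regulon(s) with no target in the gene universe: ",
         paste(names(target_idx)[!lengths(target_idx)], collapse = ", "))
  max_area <- vapply(target_idx, function(t) {
    m <- min(length(t), cutoff)
    m * (m + 1) / 2 + (cutoff - m) * m
  }, numeric(1))
  out <- matrix(0, nrow(expr), length(regulons),
                dimnames = list(rownames(expr), names(target_idx)))
  flag <- logical(G)
  for (i in seq_len(nrow(expr))) {
    ord <- order(-expr[i, ], id_rank)[seq_len(cutoff)]
    for (j in seq_along(target_idx)) {
      flag[] <- FALSE; flag[target_idx[[j]]] <- TRUE
      out[i, j] <- sum(cumsum(flag[ord])) / max_area[j]
    }
  }
  out
}

# FNV-1a 32-bit hash of a character scalar, hex string; the xor only touches
# the low byte, so it is done in double arithmetic to stay within 2^32
fnv1a <- function(txt) {
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

#' Hash of a configuration/design pair
#' @param config a `run_config`
#' @param design a `sim_design` (optional)
#' @return 8-hex-digit string; changes whenever any parameter changes
#' @export
config_hash <- function(config, design = NULL) {
  d <- if (is.null(design)) NULL else design[setdiff(names(design), "layout")]
  fnv1a(paste(deparse(c(unclass(config), d)), collapse = ""))
}

write_tsv <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    x <- data.frame(rn = rownames(x), as.data.frame(x), check.names = FALSE,
                    stringsAsFactors = FALSE)
    colnames(x)[1] <- rownames_as
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pipeline_stages <- c("simulate", "integrate", "conserve", "metaneighbor",
                     "modules", "enrich", "regulons", "report")

#' Run the full synthetic cross-species pipeline
#'
#' Executes every stage end to end on a simulated design: data generation,
#' homolog mapping and cross-species anchor integration of the inhibitory
#' neurons, joint clustering and conservation scoring, MetaNeighbor AUROC of
#' a marker set against a size-matched random set, pseudocell co-expression
#' modules, risk-gene enrichment with DEGs and high-confidence risk genes,
#' regulon activity grouping, and a manifest. All randomness derives from
#' `config$seed`; rerunning with the same design and config reproduces every
#' output byte for byte.
#'
#' @param design a `sim_design`
#' @param config a `run_config`
#' @param out_dir output directory (one subdirectory per stage)
#' @return invisibly, a list with the in-memory stage results
#' @export
run_pipeline <- function(design, config = run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in pipeline_stages)
    dir.create(file.path(out_dir, s), showWarnings = FALSE)
  writeLines(c(config_hash(config, design), as.character(config$seed)),
             file.path(out_dir, "run_id.txt"))
  ref <- design$species[1]

  ## simulate ---------------------------------------------------------------
  design$seed <- derive_seed(config$seed, "simulate")
  sim <- simulate_species(design)
  sim_dir <- file.path(out_dir, "simulate")
  for (sp in names(sim$tables))
    write_cell_table(sim$tables[[sp]], file.path(sim_dir, sp))
  for (sp in names(sim$homology))
    write_homology(sim$homology[[sp]],
                   file.path(sim_dir, paste0("homology_", sp, ".tsv")))
  write_gmt(sim$truth$regulons, file.path(sim_dir, "regulons.gmt"))
  write_gmt(list(gene_set("risk", sim$truth$risk_genes)),
            file.path(sim_dir, "risk.gmt"))
  write_truth(sim$truth, file.path(sim_dir, "truth"))

  ## integrate: per non-reference species, joint space with the reference ---
  mapped <- lapply(names(sim$homology), function(sp)
    map_to_reference(sim$tables[[sp]], sim$homology[[sp]]))
  names(mapped) <- names(sim$homology)
  inhib <- lapply(c(stats::setNames(list(sim$tables[[ref]]), ref), mapped),
                  extract_inhibitory, markers = config$inhib_markers,
                  scale = config$scale_factor)
  integrations <- list()
  for (sp in names(mapped)) {
    rt <- subsample_subtypes(inhib[[ref]], config$subsample_n,
                             derive_seed(config$seed, paste0("subsample_", ref, "_", sp)))
    qt <- subsample_subtypes(inhib[[sp]], config$subsample_n,
                             derive_seed(config$seed, paste0("subsample_", sp)))
    shared <- intersect(rt$gene_ids, qt$gene_ids)
    rt <- subset_cells(rt, genes = shared)
    qt <- subset_cells(qt, genes = shared)
    rn <- suppressWarnings(normalize_log1p(rt, config$scale_factor))
    qn <- suppressWarnings(normalize_log1p(qt, config$scale_factor))
    # within-species batch merge before the cross-species step; the batch
    # merge keeps its own tight default neighborhood (k = 5)
    rn <- correct_batches(rn, rt$annot$batch, d = config$pcs_cross)
    qn <- correct_batches(qn, qt$annot$batch, d = config$pcs_cross)
    hvg <- names(select_hvg(rbind(rn, qn),
                            min(config$hvg_n_cross, length(shared))))
    corr <- anchor_correct(rn[, hvg, drop = FALSE], qn[, hvg, drop = FALSE],
                           d = config$pcs_cross, k_anchor = config$k_anchor)
    cl <- cluster_cells(corr$coords, target_k = config$target_k,
                        seed = derive_seed(config$seed, paste0("cluster_", sp)))
    annot <- rbind(rt$annot, qt$annot)
    integrations[[sp]] <- list(coords = corr$coords, clustering = cl,
                               annot = annot, n_anchors = corr$n_anchors)
    emb <- data.frame(cell_id = rownames(corr$coords),
                      species = annot$species, subtype = annot$subtype,
                      corr$coords, check.names = FALSE)
    write_tsv(emb, file.path(out_dir, "integrate",
                             paste0("embedding_", sp, ".tsv")))
    write_tsv(data.frame(cell_id = rownames(corr$coords),
                         cluster = cl$labels),
              file.path(out_dir, "integrate", paste0("clusters_", sp, ".tsv")))
  }

  ## conserve ---------------------------------------------------------------
  overlaps <- list()
  for (sp in names(integrations)) {
    it <- integrations[[sp]]
    overlaps[[sp]] <- conservation_matrix(it$clustering, it$annot, sp, ref)
    write_tsv(overlaps[[sp]],
              file.path(out_dir, "conserve", paste0("overlap_", sp, ".tsv")),
              rownames_as = "subtype")
  }
  correlations <- lapply(sim$tables, subtype_correlation,
                         scale = config$scale_factor)
  for (sp in names(correlations))
    write_tsv(correlations[[sp]],
              file.path(out_dir, "conserve", paste0("correlation_", sp, ".tsv")),
              rownames_as = "subtype")

  ## metaneighbor: marker set vs size-matched random set --------------------
  # the informative set mixes all subtype marker blocks: a set whose genes
  # differ across subtypes carries within-set rank structure, which is what
  # the Spearman voting network sees
  focus <- design$shared_subtypes[1]
  marker_set <- sim$truth$markers$gene
  set.seed(derive_seed(config$seed, "metaneighbor_null"))
  null_set <- sample(setdiff(sim$tables[[ref]]$gene_ids,
                             sim$truth$markers$gene), length(marker_set))
  mn <- lapply(list(markers = marker_set, random = null_set), function(gs)
    run_supervised(sim$tables[[ref]], gs, positive_subtypes = focus,
                   n_cells = config$mn_cells, n_iter = config$mn_iter,
                   seed = derive_seed(config$seed, "metaneighbor"),
                   scale = config$scale_factor))
  mn_tab <- data.frame(set = names(mn),
                       mean_auroc = vapply(mn, `[[`, numeric(1), "mean"),
                       sd_auroc = vapply(mn, `[[`, numeric(1), "sd"))
  write_tsv(mn_tab, file.path(out_dir, "metaneighbor", "auroc.tsv"))

  ## modules ----------------------------------------------------------------
  ref_tab <- sim$tables[[ref]]
  norm_ref <- suppressWarnings(normalize_log1p(ref_tab, config$scale_factor))
  cond <- ref_tab$annot$condition
  genes_wgcna <- select_wgcna_genes(
    norm_ref[cond == "control", , drop = FALSE],
    norm_ref[cond == "disease", , drop = FALSE],
    n = config$hvg_n_cross)
  pm <- make_pseudocells(ref_tab, size = config$pseudocell_size,
                         seed = derive_seed(config$seed, "pseudocells"),
                         norm = norm_ref)
  kept <- mad_filter(pm, threshold = config$mad_threshold)
  genes_used <- intersect(genes_wgcna, kept)
  pm_used <- pm
  pm_used$values <- pm$values[, genes_used, drop = FALSE]
  assignment <- tom_modules(pm_used, power = config$power,
                            min_module_size = config$min_module_size,
                            merge_cut_height = config$merge_cut_height)
  write_tsv(data.frame(gene = names(assignment$modules),
                       module = assignment$modules),
            file.path(out_dir, "modules", "gene_module.tsv"))
  if (nrow(assignment$eigengenes))
    write_tsv(assignment$eigengenes,
              file.path(out_dir, "modules", "eigengenes.tsv"),
              rownames_as = "module")
  profile_mat <- module_celltype_profile(assignment, ref_tab,
                                         scale = config$scale_factor)
  write_tsv(round(profile_mat, 10),
            file.path(out_dir, "modules", "module_profile.tsv"),
            rownames_as = "module")

  ## enrich -----------------------------------------------------------------
  enr <- module_risk_enrichment(assignment, sim$truth$risk_genes,
                                N = config$background_n)
  write_tsv(enr, file.path(out_dir, "enrich", "enrichment.tsv"))
  top_module <- enr$module[which.min(enr$p)]
  top_module_genes <- names(assignment$modules)[assignment$modules == top_module]
  degs <- list()
  for (st in unique(ref_tab$annot$subtype)) {
    sub <- subset_cells(ref_tab, cells = which(ref_tab$annot$subtype == st))
    degs[[st]] <- deg_wilcoxon(sub, group_by = "condition",
                               min_pct = config$min_pct,
                               logfc_threshold = config$logfc_threshold,
                               scale = config$scale_factor)
    write_tsv(degs[[st]],
              file.path(out_dir, "enrich", paste0("deg_", st, ".tsv")))
  }
  hc <- high_confidence_risk_genes(degs, sim$truth$risk_genes,
                                   top_module_genes)
  hc_tab <- do.call(rbind, lapply(names(hc), function(ct)
    if (length(hc[[ct]])) data.frame(celltype = ct, gene = hc[[ct]]) else NULL))
  if (is.null(hc_tab))
    hc_tab <- data.frame(celltype = character(0), gene = character(0))
  write_tsv(hc_tab, file.path(out_dir, "enrich", "high_confidence.tsv"))
  hc_genes <- sort(unique(hc_tab$gene))
  if (length(hc_genes) >= 3 && length(mapped)) {
    xcor <- crossspecies_gene_correlation(ref_tab, mapped, hc_genes,
                                          scale = config$scale_factor)
    write_tsv(xcor, file.path(out_dir, "enrich", "crossspecies_correlation.tsv"))
    flags <- do.call(rbind, lapply(names(mapped), function(sp) {
      f <- crossspecies_deg_flags(ref_tab, mapped[[sp]], hc_genes,
                                  scale = config$scale_factor)
      cbind(species = sp, f)
    }))
    write_tsv(flags, file.path(out_dir, "enrich", "crossspecies_flags.tsv"))
  } else {
    xcor <- NULL; flags <- NULL
  }

  ## regulons ---------------------------------------------------------------
  shared_all <- Reduce(intersect, c(list(ref_tab$gene_ids),
                                    lapply(mapped, `[[`, "gene_ids")))
  merged_counts <- do.call(rbind, c(
    list(ref_tab$counts[, shared_all, drop = FALSE]),
    lapply(mapped, function(t) t$counts[, shared_all, drop = FALSE])))
  merged_annot <- do.call(rbind, c(list(ref_tab$annot),
                                   lapply(mapped, `[[`, "annot")))
  scores <- activity_scores(merged_counts, sim$truth$regulons,
                            top_fraction = config$top_fraction)
  bin <- binarize_activity(scores,
                           seed = derive_seed(config$seed, "binarize"))
  active <- filter_active(bin$binarized)
  grouping_cols <- paste(merged_annot$species, merged_annot$subtype, sep = ":")
  profile <- activation_profile(bin$binarized[, active, drop = FALSE],
                                grouping_cols)
  k_use <- min(config$kmeans_k, nrow(profile))
  groups <- group_regulons(profile, k = k_use,
                           seed = derive_seed(config$seed, "group_regulons"))
  reg_dir <- file.path(out_dir, "regulons")
  write_tsv(round(scores, 10), file.path(reg_dir, "scores.tsv"),
            rownames_as = "cell_id")
  write_tsv(bin$binarized, file.path(reg_dir, "binarized.tsv"),
            rownames_as = "cell_id")
  write_tsv(round(profile, 10), file.path(reg_dir, "profile.tsv"),
            rownames_as = "regulon")
  write_tsv(data.frame(regulon = names(groups), group = groups),
            file.path(reg_dir, "groups.tsv"))
  export_regulon_network(
    Filter(function(r) r$name %in% active, sim$truth$regulons), reg_dir)

  ## report -----------------------------------------------------------------
  manifest <- build_report(out_dir)

  invisible(list(sim = sim, integrations = integrations, overlaps = overlaps,
                 correlations = correlations, metaneighbor = mn,
                 assignment = assignment, module_profile = profile_mat,
                 enrichment = enr, degs = degs, high_confidence = hc,
                 crossspecies_correlation = xcor, crossspecies_flags = flags,
                 activity = list(scores = scores, binarized = bin$binarized,
                                 thresholds = bin$thresholds,
                                 active = active, profile = profile,
                                 groups = groups),
                 manifest = manifest))
}

#' Build the run manifest
#'
#' Lists every artifact of a completed run with the run's config hash and
#' seed; errors if a stage directory is missing or empty, naming the stage
#' that still has to run.
#'
#' @param run_dir directory written by [run_pipeline()]
#' @return the manifest data.frame (also written to `report/manifest.tsv`)
#' @export
build_report <- function(run_dir) {
  id_path <- file.path(run_dir, "run_id.txt")
  if (!file.exists(id_path))
    stop("no run_id.txt under ", run_dir, "; run the simulate stage first")
  id <- readLines(id_path)
  rows <- list()
  for (s in setdiff(pipeline_stages, "report")) {
    d <- file.path(run_dir, s)
    files <- sort(list.files(d, recursive = TRUE))
    if (!length(files))
      stop("stage '", s, "' has no outputs; run it before building the report")
    rows[[s]] <- data.frame(stage = s, artifact = files,
                            config_hash = id[1], seed = id[2],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  manifest <- rbind(manifest,
                    data.frame(stage = "report", artifact = "manifest.tsv",
                               config_hash = id[1], seed = id[2]))
  write_tsv(manifest, file.path(run_dir, "report", "manifest.tsv"))
  manifest
}
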