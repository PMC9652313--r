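#' Pipeline run configuration
#'
#' Bundles every tunable stage parameter with its default. Defaults follow
#' the study protocol this pipeline implements: library-size normalisation
#' with scale factor
#' 10,000; top 3000 variable genes within species and 2000 for the
#' inhibitory-neuron cross-species integration; 50 principal components within
#' species and 30 after integration; 100-cell subtype subsampling; clustering
#' into at least 31 clusters; MetaNeighbor with 20 cells per cluster and 10
#' iterations; pseudocells of 10 cells; MAD filter at 0.1; soft-threshold
#' power 6, minimum module size 10, merge cut height 0.25; hypergeometric
#' background of 20,000 genes; Wilcoxon DE with min.pct and log-FC thresholds
#' of 0.25; 8 k-means regulon groups.
#'
#' @param seed master integer seed; all stage seeds derive from it
#' @param scale_factor library-size normalisation scale factor
#' @param hvg_n,hvg_n_cross variable genes kept within species / cross-species
#' @param pcs_within,pcs_cross PCA dimensions within species / after integration
#' @param k_anchor mutual-nearest-neighbor count for anchor finding (the
#'   pipeline default 20 keeps enough anchors alive after the strict
#'   reciprocal filter at the few-hundred-cell scale; [anchor_correct()]
#'   itself defaults to 5)
#' @param subsample_n cells sampled per subtype before cross-species integration
#' @param target_k minimum number of joint clusters
#' @param mn_cells,mn_iter MetaNeighbor cells per cluster and iterations
#' @param pseudocell_size cells averaged into one pseudocell
#' @param mad_threshold minimum median absolute deviation for module genes
#' @param power,min_module_size,merge_cut_height co-expression network settings
#' @param background_n hypergeometric background gene count
#' @param min_pct,logfc_threshold DE pre-filters
#' @param kmeans_k number of regulon activation groups
#' @param top_fraction fraction of the ranking used by the regulon activity score
#' @param inhib_markers marker genes defining inhibitory neurons
#' @return object of class `run_config`
#' @export
run_config <- function(seed = 1L,
                       scale_factor = 1e4,
                       hvg_n = 3000L, hvg_n_cross = 2000L,
                       pcs_within = 50L, pcs_cross = 30L,
                       k_anchor = 20L,
                       subsample_n = 100L,
                       target_k = 31L,
                       mn_cells = 20L, mn_iter = 10L,
                       pseudocell_size = 10L,
                       mad_threshold = 0.1,
                       power = 6, min_module_size = 10L,
                       merge_cut_height = 0.25,
                       background_n = 20000L,
                       min_pct = 0.25, logfc_threshold = 0.25,
                       kmeans_k = 8L,
                       top_fraction = 0.05,
                       inhib_markers = c("GAD1", "GAD2")) {
  cfg <- list(seed = as.integer(seed), scale_factor = scale_factor,
              hvg_n = as.integer(hvg_n), hvg_n_cross = as.integer(hvg_n_cross),
              pcs_within = as.integer(pcs_within), pcs_cross = as.integer(pcs_cross),
              k_anchor = as.integer(k_anchor), subsample_n = as.integer(subsample_n),
              target_k = as.integer(target_k), mn_cells = as.integer(mn_cells),
              mn_iter = as.integer(mn_iter),
              pseudocell_size = as.integer(pseudocell_size),
              mad_threshold = mad_threshold, power = power,
              min_module_size = as.integer(min_module_size),
              merge_cut_height = merge_cut_height,
              background_n = as.integer(background_n),
              min_pct = min_pct, logfc_threshold = logfc_threshold,
              kmeans_k = as.integer(kmeans_k), top_fraction = top_fraction,
              inhib_markers = inhib_markers)
  stopifnot(cfg$scale_factor > 0, cfg$hvg_n > 0, cfg$hvg_n_cross > 0,
            cfg$pcs_within > 0, cfg$pcs_cross > 0, cfg$k_anchor > 0,
            cfg$subsample_n > 0, cfg$target_k >= 1, cfg$mn_cells > 0,
            cfg$mn_iter > 0, cfg$pseudocell_size > 0,
            cfg$mad_threshold >= 0, cfg$power > 0, cfg$min_module_size > 0,
            cfg$merge_cut_height >= 0, cfg$merge_cut_height <= 1,
            cfg$background_n > 0, cfg$min_pct >= 0, cfg$min_pct <= 1,
            cfg$logfc_threshold >= 0, cfg$kmeans_k >= 1,
            cfg$top_fraction > 0, cfg$top_fraction <= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Derive a stage seed from a master seed and a stage tag
#'
#' Deterministic 32-bit hash so that every source of randomness in the
#' pipeline flows from one master seed but stages remain decoupled: changing
#' the master seed changes every stage seed, while two stages never share a
#' stream. Result is in `[1, 2^31 - 2]`.
#'
#' @param seed master integer seed
#' @param tag stage name (string)
#' @return integer seed
#' @export
derive_seed <- function(seed, tag) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(tag)) h <- (h * 131 + b) %% m
  as.integer(h %% (m - 2) + 1)
}
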