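#' Subsample cells per subtype
#'
#' For each subtype, up to `n` cells are drawn without replacement; subtypes
#' with fewer than `n` cells are retained in full.
#'
#' @param table a `cell_table` with subtype annotation
#' @param n cells per subtype (default 100)
#' @param seed integer seed
#' @return a `cell_table`
#' @export
subsample_subtypes <- function(table, n = 100, seed = 1) {
  set.seed(seed)
  keep <- unlist(lapply(split(seq_len(n_cells(table)), table$annot$subtype),
                        function(idx)
                          if (length(idx) <= n) idx else sample(idx, n)),
                 use.names = FALSE)
  subset_cells(table, cells = sort(keep))
}

#' Extract inhibitory neurons by marker expression
#'
#' Keeps cells whose normalised expression of at least one inhibitory marker
#' (GAD1/GAD2 by default) exceeds `min_norm_expr`.
#'
#' @param table a `cell_table`
#' @param markers marker gene ids
#' @param min_norm_expr threshold on normalised expression (default 0, i.e.
#'   any nonzero count)
#' @param scale normalisation scale factor
#' @return a `cell_table` of the retained cells
#' @export
extract_inhibitory <- function(table, markers = c("GAD1", "GAD2"),
                               min_norm_expr = 0, scale = 1e4) {
  present <- intersect(markers, table$gene_ids)
  if (!length(present))
    stop("none of the marker genes (", paste(markers, collapse = ", "),
         ") is in the gene universe")
  norm <- suppressWarnings(normalize_log1p(table, scale))
  hit <- apply(norm[, present, drop = FALSE] > min_norm_expr, 1, any)
  subset_cells(table, cells = which(hit))
}

#' Cluster-proportion distribution of one subtype
#'
#' @param labels integer cluster labels of all cells
#' @param cells indices of the subtype's cells
#' @param universe cluster ids over which the distribution is expressed
#' @return named numeric vector summing to 1
#' @export
subtype_distribution <- function(labels, cells, universe = sort(unique(labels))) {
  if (!length(cells)) stop("subtype has no cells")
  tab <- table(factor(labels[cells], levels = universe))
  as.numeric(tab) / length(cells) -> p
  names(p) <- as.character(universe)
  p
}

#' Cluster-overlap conservation score between two subtypes
#'
#' The sum over clusters of the minimum of two subtypes' cluster-proportion
#' vectors; clusters missing from one vector contribute 0. The score lies in
#' `[0, 1]`, is symmetric, and equals one minus the total-variation distance
#' between the two distributions.
#'
#' @param pa,pb named probability vectors (cluster -> proportion)
#' @return numeric in `[0, 1]`
#' @export
overlap_score <- function(pa, pb) {
  for (p in list(pa, pb)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
      stop("inputs must be probability vectors (non-negative, summing to 1)")
  }
  universe <- union(names(pa), names(pb))
  if (is.null(universe)) {
    if (length(pa) != length(pb))
      stop("unnamed distributions must have equal length")
    return(sum(pmin(pa, pb)))
  }
  a <- ifelse(universe %in% names(pa), pa[universe], 0)
  b <- ifelse(universe %in% names(pb), pb[universe], 0)
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  sum(pmin(a, b))
}

#' Cross-species subtype conservation matrix
#'
#' For every (query subtype, reference subtype) pair, computes the
#' cluster-overlap score of their cluster-proportion distributions under a
#' joint clustering of the integrated cells. Row and column order is the
#' first-appearance order of subtypes in the annotation.
#'
#' @param clustering a `clustering` (or integer label vector) over all cells
#' @param annot data.frame with `species` and `subtype` per cell, aligned to
#'   the clustering
#' @param query_species,ref_species species names
#' @return matrix (query subtypes x reference subtypes) of overlap scores
#' @export
conservation_matrix <- function(clustering, annot, query_species, ref_species) {
  labels <- if (inherits(clustering, "clustering")) clustering$labels else clustering
  if (length(labels) != nrow(annot))
    stop("clustering and annotation are not aligned")
  universe <- sort(unique(labels))
  sub_of <- function(sp) unique(annot$subtype[annot$species == sp])
  qs <- sub_of(query_species); rs <- sub_of(ref_species)
  if (!length(qs)) stop("no cells for species ", query_species)
  if (!length(rs)) stop("no cells for species ", ref_species)
  dist_of <- function(sp, st) {
    cells <- which(annot$species == sp & annot$subtype == st)
    if (!length(cells))
      stop(sprintf("subtype '%s' of species '%s' is absent from the clustering",
                   st, sp))
    subtype_distribution(labels, cells, universe)
  }
  pq <- lapply(qs, dist_of, sp = query_species)
  pr <- lapply(rs, dist_of, sp = ref_species)
  out <- matrix(0, length(qs), length(rs), dimnames = list(qs, rs))
  for (i in seq_along(qs)) for (j in seq_along(rs))
    out[i, j] <- overlap_score(pq[[i]], pr[[j]])
  out
}

#' Pearson correlation of subtype average expression
#'
#' Computes per-subtype mean normalised expression vectors and their Pearson
#' correlation matrix. A subtype with a zero-variance mean vector yields NA
#' correlations and a warning.
#'
#' @param table a `cell_table` with at least two subtypes
#' @param scale normalisation scale factor
#' @return symmetric correlation matrix (subtypes x subtypes), diagonal 1
#' @export
subtype_correlation <- function(table, scale = 1e4) {
  sts <- unique(table$annot$subtype)
  if (length(sts) < 2) stop("at least two subtypes are required")
  norm <- suppressWarnings(normalize_log1p(table, scale))
  means <- vapply(sts, function(s)
    colMeans(norm[table$annot$subtype == s, , drop = FALSE]),
    numeric(ncol(norm)))
  sds <- apply(means, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance mean profile for subtype(s): ",
            paste(sts[sds == 0], collapse = ", "),
            "; correlations recorded as NA")
  r <- suppressWarnings(stats::cor(means))
  diag(r) <- 1
  r
}
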