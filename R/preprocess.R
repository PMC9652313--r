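#' Library-size log-normalisation
#'
#' Per cell, counts are scaled to `scale` total and log-transformed:
#' `x -> ln(1 + scale * x / total)`. Cells with zero total counts yield an
#' all-zero row and a warning.
#'
#' @param table a `cell_table`, or a cells x genes count matrix
#' @param scale scale factor (default 10,000)
#' @return cells x genes matrix of normalised expression
#' @export
normalize_log1p <- function(table, scale = 1e4) {
  counts <- if (inherits(table, "cell_table")) table$counts else table
  totals <- rowSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf("%d cell(s) with zero total counts; returning zero rows",
                    sum(zero)))
    totals[zero] <- 1
  }
  log1p(counts * (scale / totals))
}

#' Select highly variable genes by mean-binned standardised dispersion
#'
#' Dispersion is variance/mean of the normalised expression; genes are binned
#' by mean expression (20 equal-frequency bins) and dispersions z-scored
#' within each bin so that selection is not driven by the mean-variance
#' trend. Constant genes have dispersion 0 and rank last. Ties are broken by
#' lexicographic gene id.
#'
#' @param norm cells x genes normalised matrix with gene column names
#' @param n number of genes to keep
#' @return integer gene indices (named by gene id) in decreasing rank order
#' @export
select_hvg <- function(norm, n) {
  if (n <= 0) stop("`n` must be positive")
  if (n > ncol(norm)) stop("`n` exceeds the number of genes")
  mu <- colMeans(norm)
  v <- colSums(norm^2) / nrow(norm) - mu^2
  v <- v * nrow(norm) / max(1, nrow(norm) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  nb <- min(20L, max(1L, floor(ncol(norm) / 5)))
  bins <- cut(rank(mu, ties.method = "first"), breaks = nb, labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    i <- bins == b
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  z[disp == 0] <- -Inf  # constant genes always last
  ids <- colnames(norm)
  if (is.null(ids)) ids <- sprintf("g%06d", seq_len(ncol(norm)))
  ord <- order(-z, ids)
  out <- ord[seq_len(n)]
  names(out) <- ids[out]
  out
}

# Column z-scoring with variance clipping; constant columns map to 0.
scale_clip <- function(m, center = NULL, scale = NULL, clip = 10) {
  if (is.null(center)) center <- colMeans(m)
  if (is.null(scale)) {
    scale <- apply(m, 2, stats::sd)
    scale[scale == 0 | is.na(scale)] <- 1
  }
  s <- sweep(sweep(m, 2, center, "-"), 2, scale, "/")
  s[s > clip] <- clip
  s[s < -clip] <- -clip
  attr(s, "center") <- center
  attr(s, "scale") <- scale
  s
}

#' Principal-component embedding
#'
#' Columns are centred, unit-variance scaled and clipped at +/-10 before a
#' truncated SVD. The sign of each component is fixed by making its
#' largest-magnitude loading positive, so embeddings are deterministic.
#'
#' @param norm cells x genes normalised matrix
#' @param d number of components
#' @return object of class `embedded_cells`: `coords` (cells x d scores),
#'   `rotation` (genes x d loadings), `center`, `scale`, `cell_ids`, `d`
#' @export
pca_embed <- function(norm, d) {
  if (d < 1 || d > min(dim(norm)))
    stop("`d` must be between 1 and min(cells, genes)")
  s <- scale_clip(norm)
  sv <- svd(s, nu = d, nv = d)
  rot <- sv$v
  flip <- vapply(seq_len(d), function(j) {
    l <- rot[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  rot <- sweep(rot, 2, flip, "*")
  coords <- sweep(sv$u[, seq_len(d), drop = FALSE], 2,
                  sv$d[seq_len(d)] * flip, "*")
  rownames(coords) <- rownames(norm)
  structure(list(coords = coords, rotation = rot,
                 center = attr(s, "center"), scale = attr(s, "scale"),
                 cell_ids = rownames(norm), d = d,
                 sdev = sv$d[seq_len(d)] / sqrt(max(1, nrow(norm) - 1))),
            class = "embedded_cells")
}

# Project new data into an existing embedding's basis.
project_embedding <- function(emb, norm) {
  s <- scale_clip(norm, center = emb$center, scale = emb$scale)
  coords <- s %*% emb$rotation
  rownames(coords) <- rownames(norm)
  coords
}

#' Mutual-nearest-neighbor anchor pairs between two coordinate sets
#'
#' A pair (i, j) is an anchor iff j is among the `k` nearest b-points of
#' a-point i AND i is among the `k` nearest a-points of b-point j, so the
#' anchor relation is symmetric by construction.
#'
#' @param xa,xb coordinate matrices (rows are points) in a shared space
#' @param k neighborhood size
#' @return two-column integer matrix of (row in `xa`, row in `xb`) pairs
#' @export
anchor_pairs <- function(xa, xb, k = 5) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  k <- min(k, nrow(xa), nrow(xb))
  nn_ab <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  nn_ba <- t(apply(d2, 2, function(r) order(r)[seq_len(k)]))
  pairs <- cbind(rep(seq_len(nrow(xa)), each = k), as.vector(t(nn_ab)))
  mutual <- vapply(seq_len(nrow(pairs)), function(p)
    pairs[p, 1] %in% nn_ba[pairs[p, 2], ], logical(1))
  pairs[mutual, , drop = FALSE]
}

# Shift query points by a Gaussian-kernel-weighted average of the anchors'
# displacement vectors (ref anchor position minus query anchor position).
# The kernel is local: each cell's bandwidth is its mean squared distance to
# its k_local nearest anchors, so corrections follow the neighborhood
# structure instead of a single global smoothing scale.
apply_anchor_shift <- function(query, ref, anchors, k_local = 10) {
  disp <- ref[anchors[, 2], , drop = FALSE] - query[anchors[, 1], , drop = FALSE]
  w <- anchor_kernel_weights(query, query[anchors[, 1], , drop = FALSE],
                             k_local = k_local)
  query + w %*% disp
}

#' Reciprocal-PCA anchor correction of two datasets
#'
#' Each dataset is embedded in its own PCA space and projected into the
#' other's; mutual-nearest-neighbor pairs (`k_anchor`) found in BOTH
#' reciprocal projections are the anchors, reduced to each query cell's
#' closest reciprocal partner. The anchors' displacement vectors, taken in
#' normalised expression space, are smoothed over query cells with a local
#' Gaussian kernel and applied to the query expression; the corrected joint
#' data is then re-embedded by PCA into a common `d`-dimensional space (so
#' populations private to one dataset keep their own variance axes), where
#' an optional second pass (`refine = TRUE`, recomputed anchors,
#' coordinate-space shift) tightens the alignment. When the query equals the
#' reference every anchor matches a cell with itself, so the correction is
#' exactly zero.
#'
#' @param ref_norm,query_norm normalised matrices on a shared gene space
#'   (columns aligned)
#' @param d dimensionality of the common space (default 30)
#' @param k_anchor mutual neighborhood size (default 5)
#' @param refine run the coordinate-space refinement pass (default TRUE)
#' @return list: `coords` ((n_ref + n_query) x d matrix, reference cells
#'   first), `ref_idx`, `query_idx`, `anchors` (pair matrix,
#'   query row / ref row), `n_anchors`
#' @export
anchor_correct <- function(ref_norm, query_norm, d = 30, k_anchor = 5,
                           refine = TRUE) {
  if (!identical(colnames(ref_norm), colnames(query_norm)))
    stop("reference and query must share an aligned gene space")
  d <- min(d, min(dim(ref_norm)), min(dim(query_norm)))
  emb_ref <- pca_embed(ref_norm, d)
  emb_query <- pca_embed(query_norm, d)
  # reference space
  r_in_r <- emb_ref$coords
  q_in_r <- project_embedding(emb_ref, query_norm)
  # query space
  q_in_q <- emb_query$coords
  r_in_q <- project_embedding(emb_query, ref_norm)
  a1 <- anchor_pairs(q_in_r, r_in_r, k_anchor)   # (query, ref) in ref space
  a2 <- anchor_pairs(q_in_q, r_in_q, k_anchor)   # (query, ref) in query space
  key1 <- paste(a1[, 1], a1[, 2])
  key2 <- paste(a2[, 1], a2[, 2])
  anchors <- a1[key1 %in% key2, , drop = FALSE]
  if (!nrow(anchors))
    stop("no anchors survived the reciprocal mutual-neighborhood filter; ",
         "try a larger k_anchor")
  anchors <- best_anchor_per_query(anchors, q_in_r, r_in_r)
  # expression-space correction, weights from reference-space proximity
  disp <- ref_norm[anchors[, 2], , drop = FALSE] -
    query_norm[anchors[, 1], , drop = FALSE]
  w <- anchor_kernel_weights(q_in_r, q_in_r[anchors[, 1], , drop = FALSE])
  q_expr <- query_norm + w %*% disp
  # common space: PCA of the corrected joint data, so dataset-specific
  # populations keep their own variance axes
  emb_joint <- pca_embed(rbind(ref_norm, q_expr), d)
  r_coords <- emb_joint$coords[seq_len(nrow(ref_norm)), , drop = FALSE]
  q_corr <- emb_joint$coords[nrow(ref_norm) + seq_len(nrow(query_norm)), ,
                             drop = FALSE]
  if (refine) {
    a3 <- anchor_pairs(q_corr, r_coords, k_anchor)
    a3 <- best_anchor_per_query(a3, q_corr, r_coords)
    q_corr <- apply_anchor_shift(q_corr, r_coords, a3)
  }
  coords <- rbind(r_coords, q_corr)
  rownames(coords) <- c(rownames(ref_norm), rownames(query_norm))
  list(coords = coords,
       ref_idx = seq_len(nrow(ref_norm)),
       query_idx = nrow(ref_norm) + seq_len(nrow(query_norm)),
       anchors = anchors, n_anchors = nrow(anchors), d = d)
}

# keep, for each query cell, only its closest reciprocal partner
best_anchor_per_query <- function(anchors, q_coords, r_coords) {
  pd <- rowSums((q_coords[anchors[, 1], , drop = FALSE] -
                   r_coords[anchors[, 2], , drop = FALSE])^2)
  ord <- order(anchors[, 1], pd)
  a <- anchors[ord, , drop = FALSE]
  a[!duplicated(a[, 1]), , drop = FALSE]
}

# local Gaussian kernel weights of each row of `x` against anchor locations
anchor_kernel_weights <- function(x, anchor_loc, k_local = 10) {
  d2 <- outer(rowSums(x^2), rowSums(anchor_loc^2), "+") - 2 * x %*% t(anchor_loc)
  d2[d2 < 0] <- 0
  k_local <- min(k_local, ncol(d2))
  sigma2 <- apply(d2, 1, function(r) mean(sort(r)[seq_len(k_local)]))
  pos <- sigma2 > 0
  sigma2[!pos] <- if (any(pos)) mean(sigma2[pos]) else 1
  w <- exp(-d2 / (2 * sigma2))
  w / rowSums(w)
}

#' Within-species batch correction in expression space
#'
#' Merges the batches of one dataset before cross-dataset integration:
#' batches are processed in decreasing size order, and each batch is shifted
#' onto the accumulating reference by mutual-nearest-neighbor anchors found
#' in the reference PCA space, with the displacement applied to the
#' normalised expression itself (Gaussian-kernel smoothing of the anchors'
#' expression-space displacement vectors). Because the output is a corrected
#' expression matrix, the result can feed a further anchor-based
#' integration step unchanged.
#'
#' @param norm cells x genes normalised matrix
#' @param batches batch label per cell
#' @param d PCA dimensionality used for anchor finding (default 30)
#' @param k_anchor mutual neighborhood size (default 5)
#' @param iterations correction passes per batch (default 1). Mutual
#'   neighbors concentrate where batches already overlap, so a single pass
#'   under-corrects a large shift; that is acceptable here because this
#'   merge only pre-conditions the data for [anchor_correct()], which
#'   finishes the alignment.
#' @return corrected normalised matrix, same shape and row order as `norm`
#' @export
correct_batches <- function(norm, batches, d = 30, k_anchor = 5,
                            iterations = 1) {
  tab <- sort(table(batches), decreasing = TRUE)
  if (length(tab) < 2) return(norm)
  out <- norm
  ref_rows <- which(batches == names(tab)[1])
  for (b in names(tab)[-1]) {
    q_rows <- which(batches == b)
    ref_norm <- out[ref_rows, , drop = FALSE]
    dd <- min(d, nrow(ref_norm) - 1, length(q_rows) - 1, ncol(norm))
    emb <- pca_embed(ref_norm, dd)
    r_in_r <- emb$coords
    for (it in seq_len(iterations)) {
      q_norm <- out[q_rows, , drop = FALSE]
      q_in_r <- project_embedding(emb, q_norm)
      anchors <- anchor_pairs(q_in_r, r_in_r, k_anchor)
      if (!nrow(anchors)) break
      anchors <- best_anchor_per_query(anchors, q_in_r, r_in_r)
      # expression-space displacement, split into the global translation
      # (the batch shift proper) and kernel-smoothed local residuals
      disp <- ref_norm[anchors[, 2], , drop = FALSE] -
        q_norm[anchors[, 1], , drop = FALSE]
      global <- colMeans(disp)
      resid <- sweep(disp, 2, global, "-")
      w <- anchor_kernel_weights(q_in_r, q_in_r[anchors[, 1], , drop = FALSE])
      out[q_rows, ] <- sweep(q_norm + w %*% resid, 2, global, "+")
    }
    ref_rows <- c(ref_rows, q_rows)
  }
  out
}

#' Graph-based clustering of embedded cells
#'
#' Builds a shared-nearest-neighbor (Jaccard) graph on the embedding and runs
#' Louvain modularity clustering, raising the resolution by bisection until
#' at least `target_k` communities are found. A deterministic k-means
#' fallback (`method = "kmeans"`) is available.
#'
#' @param coords cells x d embedding matrix
#' @param target_k minimum number of clusters (default 31)
#' @param seed integer seed
#' @param k_nn neighborhood size of the SNN graph; by default scales with
#'   the dataset (n/15, clipped to 15..60). A dense graph makes the
#'   high-resolution partition follow shared expression structure rather
#'   than neighborhood sampling noise.
#' @param method `"snn"` (default) or `"kmeans"`
#' @return object of class `clustering`: `labels` (integer per cell), `k`,
#'   `method`
#' @export
cluster_cells <- function(coords, target_k = 31, seed = 1, k_nn = NULL,
                          method = c("snn", "kmeans")) {
  method <- match.arg(method)
  n <- nrow(coords)
  if (is.null(k_nn)) k_nn <- max(15, min(60, round(n / 15)))
  if (n < target_k)
    stop(sprintf("cannot form %d clusters from %d cells", target_k, n))
  if (method == "kmeans") {
    set.seed(seed)
    km <- stats::kmeans(coords, centers = max(target_k, 35), nstart = 10,
                        iter.max = 100)
    labels <- km$cluster
  } else {
    k_nn <- min(k_nn, n - 1)
    d2 <- as.matrix(stats::dist(coords))
    nn <- t(apply(d2, 1, function(r) order(r)[2:(k_nn + 1)]))
    adj <- matrix(0L, n, n)
    for (i in seq_len(n)) adj[i, nn[i, ]] <- 1L
    shared <- adj %*% t(adj)
    deg <- rowSums(adj)
    uni <- outer(deg, deg, "+") - shared
    snn <- shared / pmax(uni, 1)
    snn[snn < 1 / 15] <- 0
    diag(snn) <- 0
    g <- igraph::graph_from_adjacency_matrix(snn, mode = "undirected",
                                             weighted = TRUE)
    run_louvain <- function(res) {
      set.seed(seed)
      igraph::membership(igraph::cluster_louvain(g, resolution = res))
    }
    lo <- 0.5; hi <- 1
    labels <- run_louvain(hi)
    tries <- 0
    while (max(labels) < target_k && tries < 25) {
      hi <- hi * 2
      labels <- run_louvain(hi)
      tries <- tries + 1
    }
    if (max(labels) < target_k)
      stop("could not reach the target cluster count; data may be degenerate")
    # bisect toward the smallest resolution still meeting target_k
    for (i in seq_len(8)) {
      mid <- (lo + hi) / 2
      lm <- run_louvain(mid)
      if (max(lm) >= target_k) {
        hi <- mid; labels <- lm
      } else lo <- mid
    }
  }
  labels <- as.integer(labels)
  names(labels) <- rownames(coords)
  structure(list(labels = labels, k = length(unique(labels)), method = method),
            class = "clustering")
}
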