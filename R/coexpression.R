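#' Aggregate cells into pseudocells
#'
#' Within each subtype x condition x batch stratum, cells are randomly
#' partitioned (seeded) into consecutive groups of `size`; the remainder
#' group with fewer than `size` members is dropped, so a 25-cell stratum at
#' size 10 yields exactly 2 pseudocells and a 9-cell stratum yields none.
#' Each pseudocell is the mean normalised expression of its members.
#'
#' @param table a `cell_table` with subtype annotation
#' @param size cells per pseudocell (default 10)
#' @param seed integer seed
#' @param scale normalisation scale factor
#' @param norm optional pre-computed normalised matrix aligned to `table`
#' @return object of class `pseudocell_matrix`: `values` (pseudocells x
#'   genes), `subtype`, `condition`, `batch` (per pseudocell)
#' @export
make_pseudocells <- function(table, size = 10, seed = 1, scale = 1e4,
                             norm = NULL) {
  if (is.null(norm)) norm <- suppressWarnings(normalize_log1p(table, scale))
  annot <- table$annot
  cond <- if (is.null(annot$condition)) rep("control", nrow(annot)) else
    annot$condition
  strata <- paste(annot$subtype, cond, annot$batch, sep = "\r")
  set.seed(seed)
  rows <- list(); meta <- list()
  for (st in unique(strata)) {
    idx <- which(strata == st)
    if (length(idx) < size) next
    idx <- sample(idx)
    ngrp <- length(idx) %/% size
    for (g in seq_len(ngrp)) {
      members <- idx[((g - 1) * size + 1):(g * size)]
      rows[[length(rows) + 1]] <- colMeans(norm[members, , drop = FALSE])
      meta[[length(meta) + 1]] <- c(annot$subtype[members[1]],
                                    cond[members[1]], annot$batch[members[1]])
    }
  }
  if (!length(rows))
    stop("no stratum reached the pseudocell size; nothing to aggregate")
  values <- do.call(rbind, rows)
  m <- do.call(rbind, meta)
  structure(list(values = values, subtype = m[, 1], condition = m[, 2],
                 batch = m[, 3]),
            class = "pseudocell_matrix")
}

#' Filter genes by median absolute deviation
#'
#' Keeps genes whose MAD across pseudocells is at least `threshold`. The
#' default applies the usual consistency constant 1.4826 (the R `mad`
#' default); set `constant = 1` for the raw median absolute deviation.
#'
#' @param pmatrix a `pseudocell_matrix` or a numeric matrix (rows = samples)
#' @param threshold minimum MAD (default 0.1)
#' @param constant MAD scale constant (default 1.4826)
#' @return character vector of retained gene ids (or indices if unnamed)
#' @export
mad_filter <- function(pmatrix, threshold = 0.1, constant = 1.4826) {
  m <- if (inherits(pmatrix, "pseudocell_matrix")) pmatrix$values else pmatrix
  mads <- apply(m, 2, stats::mad, constant = constant)
  keep <- which(mads >= threshold)
  if (!is.null(colnames(m))) colnames(m)[keep] else keep
}

#' Co-expression gene universe for two condition groups
#'
#' The union of the two groups' top-`n` variable genes, intersected with the
#' genes shared by both groups.
#'
#' @param norm_a,norm_b normalised matrices of the two groups (gene columns
#'   named)
#' @param n variable genes per group (default 2000)
#' @return character vector of gene ids
#' @export
select_wgcna_genes <- function(norm_a, norm_b, n = 2000) {
  shared <- intersect(colnames(norm_a), colnames(norm_b))
  if (!length(shared)) stop("the two groups share no genes")
  n_a <- min(n, ncol(norm_a)); n_b <- min(n, ncol(norm_b))
  top_a <- names(select_hvg(norm_a, n_a))
  top_b <- names(select_hvg(norm_b, n_b))
  out <- intersect(union(top_a, top_b), shared)
  if (!length(out)) stop("no gene survived the variable-gene intersection")
  out
}

#' Topological overlap matrix from an adjacency matrix
#'
#' `tom[i,j] = (sum_u a[i,u] a[u,j] + a[i,j]) / (min(k_i, k_j) + 1 - a[i,j])`
#' with connectivity `k_i = sum_{u != i} a[i,u]`; the diagonal is 1.
#'
#' @param a symmetric adjacency matrix with entries in `[0, 1]`
#' @return topological overlap matrix, same dimension
#' @export
tom_from_adjacency <- function(a) {
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

# First principal component of column-standardised gene profiles, sign
# aligned with the mean profile.
module_eigengene <- function(values, genes) {
  x <- values[, genes, drop = FALSE]
  x <- scale(x)
  x[is.na(x)] <- 0
  e <- svd(x, nu = 1, nv = 0)$u[, 1]
  if (stats::cor(e, rowMeans(x)) < 0) e <- -e
  e
}

#' Detect co-expression modules via topological overlap
#'
#' Pearson adjacency raised to a soft-threshold power (unsigned `|r|^power`
#' by default, signed `((1 + r)/2)^power` with `signed = TRUE`), converted to
#' a topological overlap matrix, clustered by average-linkage hierarchical
#' clustering of `1 - TOM` with a static cut at `cut_height`, size-filtered
#' at `min_module_size`, and iteratively merged while two module eigengenes
#' correlate at least `1 - merge_cut_height`. Genes in undersized clusters
#' are labelled `"unassigned"`. Module labels `M1, M2, ...` are ordered by
#' decreasing size.
#'
#' @param pmatrix a `pseudocell_matrix` or samples x genes matrix
#' @param power soft-threshold power (default 6)
#' @param min_module_size minimum module size (default 10)
#' @param merge_cut_height eigengene-merge cut height (default 0.25)
#' @param signed use the signed adjacency transform
#' @param cut_height static tree-cut height on `1 - TOM` (default 0.997;
#'   with a soft power of 6, genuine co-expression sits at topological
#'   overlap around 1e-3 while the background is orders of magnitude below,
#'   so any cut inside that gap separates them)
#' @param kme_min minimum absolute eigengene correlation for the
#'   reassignment pass that rescues unassigned genes into the module they
#'   best match (default 0.3; 0 disables)
#' @return object of class `module_assignment`: `modules` (named character,
#'   gene -> label incl. `"unassigned"`), `eigengenes` (modules x samples),
#'   `tom`
#' @export
tom_modules <- function(pmatrix, power = 6, min_module_size = 10,
                        merge_cut_height = 0.25, signed = FALSE,
                        cut_height = 0.997, kme_min = 0.3) {
  values <- if (inherits(pmatrix, "pseudocell_matrix")) pmatrix$values else pmatrix
  genes <- colnames(values)
  if (is.null(genes)) genes <- sprintf("g%06d", seq_len(ncol(values)))
  colnames(values) <- genes
  if (ncol(values) < min_module_size)
    stop("fewer genes than the minimum module size")
  sds <- apply(values, 2, stats::sd)
  usable <- sds > 0
  if (!any(usable)) stop("all genes are constant; correlations are undefined")
  r <- stats::cor(values[, usable, drop = FALSE])
  a <- if (signed) ((1 + r) / 2)^power else abs(r)^power
  tom <- tom_from_adjacency(a)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep_cl <- names(sizes)[sizes >= min_module_size]
  labels <- rep("unassigned", length(genes))
  names(labels) <- genes
  mods <- list()
  for (cid in keep_cl)
    mods[[length(mods) + 1]] <- genes[usable][cl == as.integer(cid)]
  if (length(mods)) {
    eig <- lapply(mods, function(g) module_eigengene(values, g))
    # merge near-duplicate modules by eigengene correlation
    repeat {
      if (length(mods) < 2) break
      em <- do.call(cbind, eig)
      cc <- stats::cor(em)
      diag(cc) <- -Inf
      mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      if (cc[mx[1], mx[2]] < 1 - merge_cut_height) break
      i <- min(mx); j <- max(mx)
      mods[[i]] <- c(mods[[i]], mods[[j]])
      mods[[j]] <- NULL
      eig <- lapply(mods, function(g) module_eigengene(values, g))
    }
    # module-membership (kME) pass: rescue unassigned genes whose profile
    # correlates strongly with an eigengene
    if (kme_min > 0) {
      assigned <- unlist(mods)
      loose <- setdiff(genes[usable], assigned)
      if (length(loose)) {
        em <- do.call(cbind, eig)
        kme <- suppressWarnings(stats::cor(values[, loose, drop = FALSE], em))
        kme[is.na(kme)] <- 0
        # require both the membership floor and correlation significance
        # (alpha 1e-6), so small sample sizes cannot rescue noise genes
        q <- stats::qt(1e-6, df = max(1, nrow(values) - 2),
                       lower.tail = FALSE)
        r_sig <- sqrt(q^2 / (q^2 + max(1, nrow(values) - 2)))
        thr <- max(kme_min, r_sig)
        best <- max.col(abs(kme), ties.method = "first")
        take <- abs(kme[cbind(seq_along(loose), best)]) >= thr
        for (i in which(take))
          mods[[best[i]]] <- c(mods[[best[i]]], loose[i])
        if (any(take)) eig <- lapply(mods, function(g) module_eigengene(values, g))
      }
    }
    ord <- order(-vapply(mods, length, integer(1)))
    mods <- mods[ord]; eig <- eig[ord]
    for (i in seq_along(mods)) labels[mods[[i]]] <- paste0("M", i)
    eigengenes <- do.call(rbind, eig)
    rownames(eigengenes) <- paste0("M", seq_along(mods))
  } else {
    eigengenes <- matrix(numeric(0), 0, nrow(values))
  }
  structure(list(modules = labels, eigengenes = eigengenes, tom = tom),
            class = "module_assignment")
}

#' Module-by-cell-type expression profile
#'
#' Mean normalised expression of each module's genes in each cell type,
#' z-scored per module across cell types — the matrix behind a
#' module/cell-type heatmap in which each module column is scaled.
#'
#' @param assignment a `module_assignment` (or named gene -> module vector)
#' @param table a `cell_table`
#' @param scale normalisation scale factor
#' @return modules x cell types matrix with zero-mean unit-variance columns
#' @export
module_celltype_profile <- function(assignment, table, scale = 1e4) {
  labels <- if (inherits(assignment, "module_assignment")) assignment$modules else assignment
  labels <- labels[names(labels) %in% table$gene_ids]
  mods <- setdiff(unique(labels), "unassigned")
  if (!length(mods)) stop("no assigned module overlaps the table's genes")
  norm <- suppressWarnings(normalize_log1p(table, scale))
  cts <- unique(table$annot$subtype)
  ct_means <- vapply(cts, function(ct)
    colMeans(norm[table$annot$subtype == ct, , drop = FALSE]),
    numeric(ncol(norm)))
  prof <- t(vapply(mods, function(m) {
    g <- names(labels)[labels == m]
    if (!length(g)) stop("module ", m, " is empty")
    colMeans(ct_means[g, , drop = FALSE])
  }, numeric(length(cts))))
  dimnames(prof) <- list(mods, cts)
  out <- t(scale(t(prof)))
  out[is.nan(out)] <- 0  # module flat across cell types
  out
}
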