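#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, M, n)` — drawing `n` genes from a
#' background of `N` of which `M` are in the risk set — computed as a
#' log-space tail sum for numerical stability. Vectorised over `k`.
#'
#' @param k observed overlap(s)
#' @param M risk-set size
#' @param n draw (module) size
#' @param N background size (default 20,000)
#' @return probability in `[0, 1]`, one per `k`
#' @export
hypergeom_upper <- function(k, M, n, N = 20000) {
  if (M > N || n > N) stop("M and n must not exceed N")
  if (any(k < 0) || any(k > pmin(M, n)))
    stop("k must lie in [0, min(M, n)]")
  kmax <- min(M, n)
  kmin <- max(0L, n - (N - M))
  j <- kmin:kmax
  lp <- lchoose(M, j) + lchoose(N - M, n - j) - lchoose(N, n)
  # reverse cumulative logsumexp: tail[i] = log sum_{u >= i} exp(lp[u])
  tail <- numeric(length(lp))
  acc <- -Inf
  for (i in rev(seq_along(lp))) {
    acc <- if (acc == -Inf) lp[i] else {
      mx <- max(acc, lp[i]); mx + log(exp(acc - mx) + exp(lp[i] - mx))
    }
    tail[i] <- acc
  }
  out <- numeric(length(k))
  for (i in seq_along(k)) {
    out[i] <- if (k[i] <= kmin) 1 else exp(min(0, tail[k[i] - kmin + 1]))
  }
  out
}

# significance tier string for an enrichment p-value
stars_for <- function(p) {
  if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*" else ""
}

#' Risk-gene enrichment of co-expression modules
#'
#' Per module, the overlap with the risk set is scored by the upper-tail
#' hypergeometric probability against a fixed background of `N` genes, with
#' significance tiers `*` (0.01-0.05], `**` (0.001-0.01] and `***`
#' (<= 0.001).
#'
#' @param modules named list of gene vectors, or a gene -> module label
#'   vector (labels `"unassigned"` ignored), or a `module_assignment`
#' @param risk_genes character vector of risk genes
#' @param N background size (default 20,000)
#' @return data.frame: `module`, `k` (overlap), `n` (module size), `M`
#'   (risk-set size), `p`, `stars`
#' @export
module_risk_enrichment <- function(modules, risk_genes, N = 20000) {
  if (!length(risk_genes)) stop("the risk set is empty")
  risk_genes <- unique(risk_genes)
  if (inherits(modules, "module_assignment")) modules <- modules$modules
  if (!is.list(modules)) {
    labels <- modules
    mods <- setdiff(unique(labels), "unassigned")
    modules <- lapply(mods, function(m) names(labels)[labels == m])
    names(modules) <- mods
  }
  M <- length(risk_genes)
  rows <- lapply(names(modules), function(nm) {
    g <- unique(modules[[nm]])
    k <- length(intersect(g, risk_genes))
    p <- hypergeom_upper(k, M = M, n = length(g), N = N)
    data.frame(module = nm, k = k, n = length(g), M = M, p = p,
               stars = stars_for(p), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Seurat-convention average log fold change on the normalised scale:
# natural log of (mean expm1(normalised) + 1) difference.
avg_logfc <- function(norm_in, norm_out) {
  log(mean(expm1(norm_in)) + 1) - log(mean(expm1(norm_out)) + 1)
}

#' Wilcoxon rank-sum differential expression between two groups
#'
#' Genes are pre-filtered to those detected (count > 0) in at least
#' `min_pct` of cells in one of the groups and with absolute average natural-
#' log fold change (pseudocount 1 on expm1-normalised means) at least
#' `logfc_threshold`; surviving genes are tested by a two-sided Wilcoxon
#' rank-sum test (normal approximation with tie correction) on normalised
#' expression and BH-adjusted.
#'
#' @param table a `cell_table`
#' @param group_by annotation column defining the two groups (default
#'   `"condition"`)
#' @param group_in level treated as the in-group (default `"disease"` when
#'   grouping by condition, else the first level)
#' @param min_pct detection-fraction filter (default 0.25)
#' @param logfc_threshold absolute log-FC filter (default 0.25)
#' @param scale normalisation scale factor
#' @param norm optional pre-computed normalised matrix
#' @return data.frame: `gene`, `avg_logFC`, `pct_in`, `pct_out`, `p`,
#'   `p_adj`, ordered by `p`
#' @export
deg_wilcoxon <- function(table, group_by = "condition", group_in = NULL,
                         min_pct = 0.25, logfc_threshold = 0.25,
                         scale = 1e4, norm = NULL) {
  g <- table$annot[[group_by]]
  if (is.null(g)) stop("grouping column '", group_by, "' is absent")
  if (is.null(group_in))
    group_in <- if (group_by == "condition" && "disease" %in% g) "disease" else
      unique(g)[1]
  in_idx <- which(g == group_in)
  out_idx <- which(g != group_in)
  if (!length(in_idx)) stop("group '", group_in, "' is absent")
  if (!length(out_idx)) stop("the comparison group is empty")
  if (length(in_idx) < 3 || length(out_idx) < 3)
    stop("both groups need at least 3 cells")
  if (is.null(norm)) norm <- suppressWarnings(normalize_log1p(table, scale))
  detected <- table$counts > 0
  pct_in <- colMeans(detected[in_idx, , drop = FALSE])
  pct_out <- colMeans(detected[out_idx, , drop = FALSE])
  lfc <- vapply(seq_len(ncol(norm)), function(j)
    avg_logfc(norm[in_idx, j], norm[out_idx, j]), numeric(1))
  tested <- which(pmax(pct_in, pct_out) >= min_pct &
                    abs(lfc) >= logfc_threshold)
  if (!length(tested))
    return(data.frame(gene = character(0), avg_logFC = numeric(0),
                      pct_in = numeric(0), pct_out = numeric(0),
                      p = numeric(0), p_adj = numeric(0)))
  p <- vapply(tested, function(j)
    suppressWarnings(stats::wilcox.test(norm[in_idx, j], norm[out_idx, j],
                                        exact = FALSE)$p.value),
    numeric(1))
  p[is.na(p)] <- 1
  res <- data.frame(gene = table$gene_ids[tested], avg_logFC = lfc[tested],
                    pct_in = pct_in[tested], pct_out = pct_out[tested],
                    p = p, p_adj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  res[order(res$p, res$gene), , drop = FALSE]
}

#' High-confidence risk genes per cell type
#'
#' The intersection, per cell type, of its differentially expressed genes
#' with the risk set and the genes of the enriched module.
#'
#' @param degs_by_celltype named list: cell type -> DEG gene vector (or
#'   [deg_wilcoxon()] data.frame)
#' @param risk_genes risk-gene vector
#' @param module_genes module-gene vector
#' @return named list of gene vectors, with an attribute `sizes`
#' @export
high_confidence_risk_genes <- function(degs_by_celltype, risk_genes,
                                       module_genes) {
  out <- lapply(degs_by_celltype, function(d) {
    g <- if (is.data.frame(d)) d$gene else d
    sort(intersect(intersect(g, risk_genes), module_genes))
  })
  attr(out, "sizes") <- vapply(out, length, integer(1))
  out
}

#' Cross-species expression correlation of a gene list
#'
#' Per shared cell type: Pearson correlation (and least-squares slope and
#' intercept) between the reference species' and the other species' mean
#' normalised expression over the gene list. Genes absent from the other
#' species (not homologous) are excluded.
#'
#' @param ref_table reference-species `cell_table` (reference gene ids)
#' @param other_tables named list of `cell_table`s already mapped to
#'   reference gene ids
#' @param genes gene list (reference ids)
#' @param scale normalisation scale factor
#' @return data.frame: `species`, `celltype`, `r`, `slope`, `intercept`,
#'   `n_genes`
#' @export
crossspecies_gene_correlation <- function(ref_table, other_tables, genes,
                                          scale = 1e4) {
  norm_ref <- suppressWarnings(normalize_log1p(ref_table, scale))
  rows <- list()
  for (sp in names(other_tables)) {
    tab <- other_tables[[sp]]
    shared_genes <- intersect(intersect(genes, ref_table$gene_ids),
                              tab$gene_ids)
    if (length(shared_genes) < 3)
      stop("fewer than 3 shared genes with species ", sp)
    norm_sp <- suppressWarnings(normalize_log1p(tab, scale))
    cts <- intersect(unique(ref_table$annot$subtype),
                     unique(tab$annot$subtype))
    for (ct in cts) {
      x <- colMeans(norm_ref[ref_table$annot$subtype == ct, shared_genes,
                             drop = FALSE])
      y <- colMeans(norm_sp[tab$annot$subtype == ct, shared_genes,
                            drop = FALSE])
      fit <- stats::lm.fit(cbind(1, x), y)
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, celltype = ct,
        r = suppressWarnings(stats::cor(x, y)),
        slope = fit$coefficients[2], intercept = fit$coefficients[1],
        n_genes = length(shared_genes), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-species differential-expression flags for selected genes
#'
#' Per gene and shared cell type, a Wilcoxon rank-sum test of reference vs
#' other species on normalised expression, BH-adjusted within cell type; a
#' gene is starred iff `p_adj < 0.05` and `|avg_logFC| > 1`.
#'
#' @param ref_table reference-species `cell_table`
#' @param other_table other-species `cell_table` mapped to reference ids
#' @param genes genes to flag
#' @param scale normalisation scale factor
#' @return data.frame: `gene`, `celltype`, `avg_logFC`, `p`, `p_adj`,
#'   `starred`
#' @export
crossspecies_deg_flags <- function(ref_table, other_table, genes,
                                   scale = 1e4) {
  genes <- intersect(intersect(genes, ref_table$gene_ids),
                     other_table$gene_ids)
  if (!length(genes)) stop("no shared gene to flag")
  norm_ref <- suppressWarnings(normalize_log1p(ref_table, scale))
  norm_oth <- suppressWarnings(normalize_log1p(other_table, scale))
  cts <- intersect(unique(ref_table$annot$subtype),
                   unique(other_table$annot$subtype))
  rows <- list()
  for (ct in cts) {
    ri <- ref_table$annot$subtype == ct
    oi <- other_table$annot$subtype == ct
    p <- numeric(length(genes)); lfc <- numeric(length(genes))
    for (gi in seq_along(genes)) {
      x <- norm_ref[ri, genes[gi]]; y <- norm_oth[oi, genes[gi]]
      lfc[gi] <- avg_logfc(x, y)
      p[gi] <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
    }
    p[is.na(p)] <- 1
    p_adj <- stats::p.adjust(p, method = "BH")
    rows[[length(rows) + 1]] <- data.frame(
      gene = genes, celltype = ct, avg_logFC = lfc, p = p, p_adj = p_adj,
      starred = p_adj < 0.05 & abs(lfc) > 1, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
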