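#' Rank-standardised Spearman voting network
#'
#' Computes Spearman correlations between cells on a gene-set submatrix,
#' ranks all similarities (average ranks on ties), standardises them to
#' `(0, 1]` by dividing by the maximum rank, and symmetrises by the mean of
#' the matrix and its transpose. The diagonal is retained in the matrix but
#' excluded from voting by construction of the cross-batch scheme.
#'
#' @param norm cells x genes normalised matrix, already restricted to the
#'   gene set of interest
#' @return cells x cells symmetric network with entries in `(0, 1]`
#' @export
build_network <- function(norm) {
  if (nrow(norm) < 2 || ncol(norm) < 2)
    stop("need at least 2 cells and 2 genes to build a voting network")
  s <- suppressWarnings(stats::cor(t(norm), method = "spearman"))
  s[is.na(s)] <- 0
  # snap floating-point 1s so duplicate cells tie exactly with the diagonal
  s[s > 1 - 1e-12] <- 1
  r <- matrix(rank(s, ties.method = "average"), nrow(s), nrow(s))
  r <- r / max(r)
  net <- (r + t(r)) / 2
  dimnames(net) <- dimnames(s)
  net
}

#' Cross-batch neighbor-voting AUROC
#'
#' For each batch, its cells are held out and scored by the degree-normalised
#' sum of network weights to the labelled cells of all other batches; the
#' AUROC of these scores against the held-out labels is the Mann-Whitney U
#' statistic scaled to `[0, 1]`. Batches containing a single class are
#' skipped with a warning.
#'
#' @param network cells x cells voting network from [build_network()]
#' @param labels01 binary vector (1 = positive class) per cell
#' @param batches batch label per cell (at least 2 batches)
#' @return named numeric vector of per-batch AUROCs (skipped batches absent)
#' @export
neighbor_vote_auroc <- function(network, labels01, batches) {
  n <- nrow(network)
  stopifnot(length(labels01) == n, length(batches) == n)
  if (length(unique(batches)) < 2) stop("at least 2 batches are required")
  labels01 <- as.numeric(labels01)
  out <- c()
  for (b in unique(batches)) {
    test <- which(batches == b)
    train <- which(batches != b)
    y <- labels01[test]
    if (length(unique(y)) < 2) {
      warning(sprintf("batch '%s' has a single class; skipped", b))
      next
    }
    w <- network[test, train, drop = FALSE]
    scores <- as.vector(w %*% labels01[train]) / rowSums(w)
    out[as.character(b)] <- auroc_u(scores, y)
  }
  out
}

# AUROC as the Mann-Whitney U statistic scaled to [0,1] (rank formulation,
# average ranks on ties).
auroc_u <- function(scores, y) {
  pos <- y == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Supervised MetaNeighbor-style AUROC of a gene set
#'
#' Per iteration: subsample up to `n_cells` cells from each cluster
#' (subtype), restrict to the gene set, build the voting network, run
#' cross-batch neighbor voting with the inhibitory/other binary label, and
#' record the mean per-batch AUROC. Returns the mean and standard deviation
#' over iterations.
#'
#' @param table a `cell_table` with subtype and batch annotation
#' @param genes character vector (or `gene_set`) of genes defining the network
#' @param positive_subtypes subtypes labelled 1 (e.g. the inhibitory ones)
#' @param n_cells cells sampled per cluster per iteration (default 20)
#' @param n_iter iterations (default 10)
#' @param seed integer seed
#' @param scale normalisation scale factor
#' @return list: `mean`, `sd`, `auroc` (per-iteration means)
#' @export
run_supervised <- function(table, genes, positive_subtypes,
                           n_cells = 20, n_iter = 10, seed = 1, scale = 1e4) {
  if (inherits(genes, "gene_set")) genes <- genes$genes
  genes <- intersect(genes, table$gene_ids)
  if (length(genes) < 2)
    stop("fewer than 2 genes of the set are present in the table")
  norm <- suppressWarnings(normalize_log1p(table, scale))[, genes, drop = FALSE]
  labels01 <- as.numeric(table$annot$subtype %in% positive_subtypes)
  aur <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    set.seed(derive_seed(seed, paste0("metaneighbor_", it)))
    idx <- unlist(lapply(split(seq_len(nrow(norm)), table$annot$subtype),
                         function(i)
                           if (length(i) <= n_cells) i else sample(i, n_cells)),
                  use.names = FALSE)
    idx <- sort(idx)
    net <- build_network(norm[idx, , drop = FALSE])
    per_batch <- neighbor_vote_auroc(net, labels01[idx],
                                     table$annot$batch[idx])
    aur[it] <- mean(per_batch)
  }
  list(mean = mean(aur), sd = stats::sd(aur), auroc = aur)
}
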