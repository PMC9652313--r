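#' AUCell-style regulon activity score
#'
#' Per cell, genes are ranked by decreasing expression (ties broken by gene
#' id); the score is the area under the recovery curve of the regulon's
#' targets within the top `ceiling(top_fraction * G)` ranks, normalised so
#' that a cell with every target at the very top scores 1. The score depends
#' only on within-cell expression ranks.
#'
#' @param table a `cell_table` (or a cells x genes matrix with gene column
#'   names)
#' @param regulon a `gene_set` (targets; the TF itself is not added) or a
#'   character vector of target genes
#' @param top_fraction fraction of the ranking integrated (default 0.05)
#' @return numeric vector of per-cell scores in `[0, 1]`
#' @export
activity_score <- function(table, regulon, top_fraction = 0.05) {
  expr <- if (inherits(table, "cell_table")) table$counts else table
  gene_ids <- colnames(expr)
  targets <- if (inherits(regulon, "gene_set")) regulon$genes else regulon
  targets <- intersect(targets, gene_ids)
  if (!length(targets))
    stop("no regulon target is present in the gene universe")
  G <- ncol(expr)
  cutoff <- ceiling(top_fraction * G)
  is_target <- gene_ids %in% targets
  m <- min(length(targets), cutoff)
  max_area <- m * (m + 1) / 2 + (cutoff - m) * m
  # deterministic tie-break: gene ids ascending within equal expression
  id_rank <- rank(gene_ids, ties.method = "first")
  apply(expr, 1, function(x) {
    ord <- order(-x, id_rank)[seq_len(cutoff)]
    hits <- cumsum(is_target[ord])
    sum(hits) / max_area
  })
}

#' Bimodal binarisation threshold for regulon activity scores
#'
#' Fits a two-component Gaussian mixture (unequal variances) to the score
#' distribution and places the threshold where the posterior responsibility
#' switches between the two components, searched between the component
#' means. If the fit degenerates (component means closer than `min_sep` or a
#' component weight below `min_weight`, or the fit fails), the threshold
#' falls back to the midpoint of the deepest interior valley of a 30-bin
#' histogram. Constant scores give `Inf` (no cell active) with a warning.
#'
#' @param scores numeric vector of per-cell scores (at least 20 cells)
#' @param seed integer seed (kept for interface symmetry; the fit is
#'   deterministic)
#' @param min_sep,min_weight degeneracy guards for the mixture fit
#' @return scalar threshold; cells with `score >= threshold` are active
#' @importFrom mclust Mclust mclustBIC
#' @export
binarize_bimodal <- function(scores, seed = 1, min_sep = 0.05,
                             min_weight = 0.01) {
  if (length(scores) < 20) stop("at least 20 cells are required")
  if (stats::sd(scores) == 0) {
    warning("constant scores; regulon marked inactive everywhere")
    return(Inf)
  }
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(scores, G = 2, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    mu <- fit$parameters$mean
    sig <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sig) == 1) sig <- rep(sig, 2)
    pro <- fit$parameters$pro
    o <- order(mu)
    mu <- mu[o]; sig <- sig[o]; pro <- pro[o]
    if (diff(mu) >= min_sep && min(pro) >= min_weight) {
      f <- function(x)
        log(pro[1]) + stats::dnorm(x, mu[1], sig[1], log = TRUE) -
        log(pro[2]) - stats::dnorm(x, mu[2], sig[2], log = TRUE)
      lo <- mu[1]; hi <- mu[2]
      if (f(lo) > 0 && f(hi) < 0)
        return(stats::uniroot(f, c(lo, hi))$root)
      return((mu[1] + mu[2]) / 2)
    }
  }
  # histogram-valley fallback: midpoint of the deepest interior valley
  h <- graphics::hist(scores, breaks = 30, plot = FALSE)
  cnt <- h$counts
  mids <- h$mids
  interior <- which(vapply(seq_along(cnt), function(i)
    i > 1 && i < length(cnt) &&
      any(cnt[1:(i - 1)] > cnt[i]) && any(cnt[(i + 1):length(cnt)] > cnt[i]),
    logical(1)))
  if (!length(interior)) {
    warning("no bimodal structure found; regulon marked inactive everywhere")
    return(Inf)
  }
  valley <- interior[cnt[interior] == min(cnt[interior])]
  mids[valley[ceiling(length(valley) / 2)]]
}

#' Binarise an activity matrix regulon by regulon
#'
#' @param scores cells x regulons activity matrix
#' @param seed integer seed
#' @return list: `binarized` (cells x regulons 0/1), `thresholds` (per
#'   regulon)
#' @export
binarize_activity <- function(scores, seed = 1) {
  thr <- vapply(seq_len(ncol(scores)), function(j)
    suppressWarnings(binarize_bimodal(scores[, j], seed = seed)), numeric(1))
  names(thr) <- colnames(scores)
  bin <- sweep(scores, 2, thr, ">=") * 1L
  dimnames(bin) <- dimnames(scores)
  list(binarized = bin, thresholds = thr)
}

#' Regulons active in at least one cell
#'
#' @param binarized cells x regulons 0/1 matrix
#' @return character vector (or indices if unnamed) of retained regulons
#' @export
filter_active <- function(binarized) {
  keep <- which(colSums(binarized) >= 1)
  if (!is.null(colnames(binarized))) colnames(binarized)[keep] else keep
}

#' Fraction of activated cells per regulon and subtype
#'
#' @param binarized cells x regulons 0/1 matrix
#' @param subtypes subtype label per cell (a grouping such as
#'   species x subtype may be passed directly)
#' @return regulons x subtypes matrix of exact activation fractions
#' @export
activation_profile <- function(binarized, subtypes) {
  stopifnot(length(subtypes) == nrow(binarized))
  levels <- unique(subtypes)
  counts <- table(factor(subtypes, levels = levels))
  if (any(counts == 0)) stop("empty subtype: ",
                             paste(levels[counts == 0], collapse = ", "))
  prof <- vapply(levels, function(s)
    colSums(binarized[subtypes == s, , drop = FALSE]) / sum(subtypes == s),
    numeric(ncol(binarized)))
  if (is.null(dim(prof))) prof <- matrix(prof, ncol = length(levels))
  dimnames(prof) <- list(colnames(binarized), levels)
  prof
}

#' Group regulons by their activation profiles
#'
#' k-means (50 random restarts, seeded, squared Euclidean) on the profile
#' rows; groups are relabelled `1..k` by decreasing size (ties by original
#' label) for deterministic reporting.
#'
#' @param profile regulons x subtypes activation-fraction matrix
#' @param k number of groups (default 8)
#' @param seed integer seed
#' @return named integer vector: regulon -> group in `1..k`
#' @export
group_regulons <- function(profile, k = 8, seed = 1) {
  if (nrow(profile) < k)
    stop(sprintf("cannot form %d groups from %d regulons", k, nrow(profile)))
  set.seed(seed)
  km <- stats::kmeans(profile, centers = k, nstart = 50, iter.max = 100)
  sizes <- table(km$cluster)
  new_id <- integer(k)
  new_id[order(-as.numeric(sizes), as.integer(names(sizes)))] <- seq_len(k)
  out <- new_id[km$cluster]
  names(out) <- rownames(profile)
  out
}
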