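#' Read gene sets from a GMT file
#'
#' One set per line: `name <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' When `regulon = TRUE` the second column is parsed as the transcription
#' factor of the set.
#'
#' @param path GMT path
#' @param regulon logical; treat the second field as the regulon's TF
#' @return list of `gene_set` objects (fields `name`, `genes`, and `tf` for
#'   regulons)
#' @export
read_gmt <- function(path, regulon = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d fields; at least 3 required", i, length(f)))
    out[[i]] <- gene_set(name = f[1], genes = f[-(1:2)],
                         tf = if (regulon) f[2] else NULL)
  }
  out
}

#' Construct a named gene set (optionally a regulon)
#'
#' @param name set name
#' @param genes character vector of gene ids (duplicates removed, order kept)
#' @param tf optional transcription factor gene id; present iff the set is a
#'   regulon
#' @return object of class `gene_set`
#' @export
gene_set <- function(name, genes, tf = NULL) {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("a gene set must contain at least one gene")
  structure(list(name = name, genes = genes, tf = tf), class = "gene_set")
}

#' Write gene sets to a GMT file
#' @param sets list of `gene_set`
#' @param path output path
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    desc <- if (is.null(s$tf)) "na" else s$tf
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export regulons as a Cytoscape-style edge list
#'
#' Writes `edges.tsv` (columns `tf`, `target`) and `nodes.tsv` (columns
#' `node`, `role`). A node that is both a TF of one regulon and a target of
#' another is labelled `TF` (TF status wins).
#'
#' @param regulons list of `gene_set` objects with `tf` set
#' @param dir output directory
#' @return invisibly, the two paths
#' @export
export_regulon_network <- function(regulons, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edge_path <- file.path(dir, "edges.tsv")
  node_path <- file.path(dir, "nodes.tsv")
  if (length(regulons) && any(vapply(regulons, function(r) is.null(r$tf), logical(1))))
    stop("every regulon must have a TF")
  edges <- do.call(rbind, lapply(regulons, function(r)
    data.frame(tf = r$tf, target = r$genes, stringsAsFactors = FALSE)))
  if (is.null(edges))
    edges <- data.frame(tf = character(0), target = character(0))
  tfs <- unique(vapply(regulons, `[[`, character(1), "tf"))
  targets <- setdiff(unique(edges$target), tfs)
  nodes <- data.frame(node = c(tfs, targets),
                      role = c(rep("TF", length(tfs)),
                               rep("target", length(targets))),
                      stringsAsFactors = FALSE)
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(edge_path, node_path))
}
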