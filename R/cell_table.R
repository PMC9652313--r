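#' Cell-by-gene count table with per-cell annotation
#'
#' The central data container of the pipeline: a non-negative integer count
#' matrix with cells in rows and genes in columns, plus a per-cell annotation
#' frame carrying at least `species`, `batch` and `subtype` (and optionally
#' `condition`, one of `"control"`/`"disease"`).
#'
#' @param counts numeric matrix (cells x genes), non-negative, integer-valued.
#'   A sparse `Matrix` is accepted and densified.
#' @param annot data.frame with one row per cell; must contain a `cell_id`
#'   column plus `species`, `batch`, `subtype` and optionally `condition`.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `colnames(counts)`.
#'
#' @return an object of class `cell_table` with elements `counts`, `gene_ids`,
#'   `cell_ids`, `annot`.
#' @export
cell_table <- function(counts, annot, gene_ids = colnames(counts)) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if (is.null(gene_ids)) stop("gene identifiers are required")
  cell_ids <- annot$cell_id
  if (is.null(cell_ids)) stop("`annot` must have a `cell_id` column")
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != ncol(counts))
    stop(sprintf("gene ids (%d) do not match matrix columns (%d)",
                 length(gene_ids), ncol(counts)))
  if (nrow(annot) != nrow(counts))
    stop(sprintf("annotation rows (%d) do not match matrix rows (%d)",
                 nrow(annot), nrow(counts)))
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (any(counts < 0)) stop("negative entries in count matrix")
  if (any(counts != round(counts))) stop("non-integer entries in count matrix")
  for (col in c("species", "batch", "subtype")) {
    if (is.null(annot[[col]])) stop(sprintf("`annot` must have a `%s` column", col))
    annot[[col]] <- as.character(annot[[col]])
  }
  if (!is.null(annot$condition)) {
    annot$condition <- as.character(annot$condition)
    bad <- setdiff(unique(annot$condition), c("control", "disease"))
    if (length(bad))
      stop("`condition` must be 'control' or 'disease'; found: ",
           paste(bad, collapse = ", "))
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  rownames(annot) <- NULL
  structure(
    list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
         annot = annot),
    class = "cell_table"
  )
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("cell_table: %d cells x %d genes\n", nrow(x$counts), ncol(x$counts)))
  cat("  species:", paste(unique(x$annot$species), collapse = ", "), "\n")
  cat("  subtypes:", paste(unique(x$annot$subtype), collapse = ", "), "\n")
  invisible(x)
}

#' Number of cells / genes in a cell_table
#' @param table a `cell_table`
#' @return integer count
#' @export
n_cells <- function(table) nrow(table$counts)

#' @rdname n_cells
#' @export
n_genes <- function(table) ncol(table$counts)

#' Subset a cell_table by cells and/or genes
#'
#' @param table a `cell_table`
#' @param cells logical/integer/character index over cells (optional)
#' @param genes logical/integer/character index over genes (optional)
#' @return a `cell_table`
#' @export
subset_cells <- function(table, cells = NULL, genes = NULL) {
  counts <- table$counts
  annot <- table$annot
  if (!is.null(cells)) {
    if (is.character(cells)) cells <- match(cells, table$cell_ids)
    counts <- counts[cells, , drop = FALSE]
    annot <- annot[cells, , drop = FALSE]
  }
  if (!is.null(genes)) {
    if (is.character(genes)) genes <- match(genes, table$gene_ids)
    counts <- counts[, genes, drop = FALSE]
  }
  cell_table(counts, annot, gene_ids = colnames(counts))
}

#' Read a cell table from a Matrix Market bundle
#'
#' Reads a coordinate Matrix Market file plus TSV sidecars (one gene id per
#' line, one cell id per line) and a per-cell annotation TSV. The on-disk
#' matrix may be stored either genes x cells (10x convention) or
#' cells x genes; orientation is resolved against the sidecar lengths and an
#' error is raised for a square, ambiguous matrix.
#'
#' @param matrix_path path to the `.mtx` file
#' @param genes_path path to the gene-id TSV (one id per line)
#' @param cells_path path to the cell-id TSV (one id per line)
#' @param annot_path path to the annotation TSV with header
#'   `cell_id, species, batch, subtype[, condition]`
#' @return a `cell_table`, oriented cells x genes
#' @export
read_cell_table <- function(matrix_path, genes_path, cells_path, annot_path) {
  m <- as.matrix(Matrix::readMM(matrix_path))
  genes <- readLines(genes_path)
  genes <- genes[nzchar(genes)]
  cells <- readLines(cells_path)
  cells <- cells[nzchar(cells)]
  ng <- length(genes); nc <- length(cells)
  if (nrow(m) == nc && ncol(m) == ng) {
    # already cells x genes
  } else if (nrow(m) == ng && ncol(m) == nc) {
    if (ng == nc)
      stop("square matrix with equal sidecar lengths: orientation is ambiguous")
    m <- t(m)
  } else {
    stop(sprintf(
      "matrix dimensions %d x %d match neither %d cells x %d genes nor its transpose",
      nrow(m), ncol(m), nc, ng))
  }
  annot <- utils::read.delim(annot_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  if (is.null(annot$cell_id)) stop("annotation file lacks a `cell_id` column")
  idx <- match(cells, annot$cell_id)
  if (anyNA(idx))
    stop("annotation file is missing cells: ",
         paste(utils::head(cells[is.na(idx)], 5), collapse = ", "))
  annot <- annot[idx, , drop = FALSE]
  if (!is.null(annot$condition) && all(annot$condition == ""))
    annot$condition <- NULL
  cell_table(m, annot, gene_ids = genes)
}

#' Write a cell table as a Matrix Market bundle
#'
#' Inverse of [read_cell_table()]; writes `matrix.mtx`, `features.tsv`,
#' `barcodes.tsv` and `annotations.tsv` under `dir`.
#'
#' @param table a `cell_table`
#' @param dir output directory (created if absent)
#' @return invisibly, the paths written
#' @export
write_cell_table <- function(table, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv",
                            "annotations.tsv"))
  # genes x cells on disk, 10x convention
  sp <- Matrix::Matrix(t(table$counts), sparse = TRUE)
  Matrix::writeMM(sp, paths[1])
  writeLines(table$gene_ids, paths[2])
  writeLines(table$cell_ids, paths[3])
  annot <- table$annot
  utils::write.table(annot, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a cell table from a bundle directory written by [write_cell_table()]
#' @param dir bundle directory
#' @return a `cell_table`
#' @export
read_cell_table_dir <- function(dir) {
  read_cell_table(file.path(dir, "matrix.mtx"), file.path(dir, "features.tsv"),
                  file.path(dir, "barcodes.tsv"), file.path(dir, "annotations.tsv"))
}
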