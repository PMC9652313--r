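#' One-to-one ortholog map between a source species and the reference
#'
#' Constructs a strict one-to-one gene correspondence from a raw pair list.
#' Pairs in which either the source gene or the reference gene appears more
#' than once (many-to-one, one-to-many or many-to-many orthology) are dropped
#' entirely rather than resolved, so every retained source gene maps to a
#' unique reference gene and vice versa. Gene identifiers are opaque,
#' case-sensitive strings.
#'
#' @param pairs data.frame with columns `source_gene`, `reference_gene`
#' @param source_species name of the non-reference species
#' @return object of class `homology_map` with elements `pairs` (the filtered
#'   data.frame) and `source_species`
#' @export
homology_map <- function(pairs, source_species) {
  if (is.null(pairs$source_gene) || is.null(pairs$reference_gene))
    stop("`pairs` needs `source_gene` and `reference_gene` columns")
  pairs$source_gene <- as.character(pairs$source_gene)
  pairs$reference_gene <- as.character(pairs$reference_gene)
  pairs <- unique(pairs[, c("source_gene", "reference_gene")])
  dup_src <- pairs$source_gene %in% pairs$source_gene[duplicated(pairs$source_gene)]
  dup_ref <- pairs$reference_gene %in% pairs$reference_gene[duplicated(pairs$reference_gene)]
  pairs <- pairs[!(dup_src | dup_ref), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, source_species = source_species),
            class = "homology_map")
}

#' @export
print.homology_map <- function(x, ...) {
  cat(sprintf("homology_map: %s -> reference, %d one-to-one pairs\n",
              x$source_species, nrow(x$pairs)))
  invisible(x)
}

#' Rename a table's genes to reference-species identifiers
#'
#' Genes with a one-to-one ortholog are renamed to the reference id; genes
#' without one are dropped. Column order follows the input order of the
#' retained genes and count values are untouched.
#'
#' @param table a `cell_table` of the map's source species
#' @param hmap a `homology_map`
#' @return a `cell_table` on reference gene ids
#' @export
map_to_reference <- function(table, hmap) {
  sp <- unique(table$annot$species)
  if (length(sp) == 1 && !identical(sp, hmap$source_species))
    stop(sprintf("table species '%s' does not match map source species '%s'",
                 sp, hmap$source_species))
  idx <- match(table$gene_ids, hmap$pairs$source_gene)
  keep <- which(!is.na(idx))
  if (!length(keep))
    stop(sprintf(
      "no gene of the table is covered by the homology map (table ids like %s; map source ids like %s)",
      paste(utils::head(table$gene_ids, 3), collapse = ","),
      paste(utils::head(hmap$pairs$source_gene, 3), collapse = ",")))
  counts <- table$counts[, keep, drop = FALSE]
  colnames(counts) <- hmap$pairs$reference_gene[idx[keep]]
  cell_table(counts, table$annot, gene_ids = colnames(counts))
}

#' Read / write a homology TSV (columns source_gene, reference_gene)
#' @param path TSV path
#' @param source_species species name for the resulting map
#' @return a `homology_map`
#' @export
read_homology <- function(path, source_species) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  homology_map(df, source_species)
}

#' @rdname read_homology
#' @param hmap a `homology_map` to write
#' @export
write_homology <- function(hmap, path) {
  utils::write.table(hmap$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
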