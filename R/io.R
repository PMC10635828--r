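#' Read an expression matrix from disk
#'
#' Supports two on-disk representations: a 10x-style MatrixMarket triplet
#' directory (`matrix.mtx` plus `genes.tsv` and `barcodes.tsv` name files) and
#' a dense TSV with gene identifiers in the first column and column
#' identifiers in the header row. Both yield the same in-memory object; the
#' result always carries `layer = "raw"` and is validated (unique identifiers,
#' no negative values).
#'
#' @param path directory (for `format = "mtx_dir"`) or file (for `"tsv"`).
#' @param format `"mtx_dir"` or `"tsv"`; default guesses from `path`.
#' @return An [expr_matrix()] with `layer = "raw"`.
#' @export
read_expression <- function(path, format = c("auto", "mtx_dir", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (dir.exists(path)) "mtx_dir" else "tsv"
  if (format == "mtx_dir") {
    mtx <- file.path(path, "matrix.mtx")
    genes <- file.path(path, "genes.tsv")
    bcs <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, genes, bcs))
      if (!file.exists(f)) stop("missing file: ", f)
    m <- as.matrix(Matrix::readMM(mtx))
    gene_ids <- utils::read.table(genes, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE)[[1L]]
    col_ids <- utils::read.table(bcs, sep = "\t", header = FALSE,
                                 stringsAsFactors = FALSE)[[1L]]
    if (length(gene_ids) != nrow(m))
      stop("gene name file lists ", length(gene_ids),
           " genes but matrix has ", nrow(m), " rows")
    if (length(col_ids) != ncol(m))
      stop("barcode file lists ", length(col_ids),
           " columns but matrix has ", ncol(m), " columns")
    out <- expr_matrix(m, gene_ids = gene_ids, column_ids = col_ids, layer = "raw")
  } else {
    if (!file.exists(path)) stop("missing file: ", path)
    tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE, quote = "", comment.char = "")
    gene_ids <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    out <- expr_matrix(m, gene_ids = gene_ids, column_ids = colnames(tab)[-1L],
                       layer = "raw")
  }
  validate_expr_matrix(out, paste0("expression matrix at '", path, "'"))
}

#' Write an expression matrix as a dense TSV
#'
#' First column `gene`, then one column per cell/spot; the format
#' [read_expression()] reads back.
#'
#' @param m an [expr_matrix()].
#' @param path output file.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cell-type annotations
#'
#' Two-column TSV `(cell_id, cell_type)`. Labels are whitespace-trimmed; cell
#' ids must be unique and type labels non-empty.
#'
#' @param path file path.
#' @param header logical; does the file carry a header row?
#' @return data.frame with columns `cell_id`, `cell_type`.
#' @export
read_cell_annotations <- function(path, header = TRUE) {
  tab <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (ncol(tab) < 2L) stop("annotation table needs two columns (cell_id, cell_type)")
  ann <- data.frame(cell_id = trimws(as.character(tab[[1L]])),
                    cell_type = trimws(as.character(tab[[2L]])),
                    stringsAsFactors = FALSE)
  validate_annotations(ann)
}

validate_annotations <- function(ann) {
  if (anyDuplicated(ann$cell_id)) {
    dup <- unique(ann$cell_id[duplicated(ann$cell_id)])
    stop("duplicated cell_id in annotations: ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (any(!nzchar(ann$cell_type))) stop("empty cell_type label in annotations")
  ann
}

#' Read spot coordinates
#'
#' Three-column TSV `(spot_id, x, y)`.
#'
#' @param path file path.
#' @param header logical header flag.
#' @return data.frame with columns `spot_id`, `x`, `y`.
#' @export
read_coordinates <- function(path, header = TRUE) {
  tab <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (ncol(tab) < 3L) stop("coordinate table needs three columns (spot_id, x, y)")
  geo <- data.frame(spot_id = trimws(as.character(tab[[1L]])),
                    x = as.numeric(tab[[2L]]), y = as.numeric(tab[[3L]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(geo$spot_id)) stop("duplicated spot_id in coordinates")
  if (any(!is.finite(geo$x)) || any(!is.finite(geo$y)))
    stop("non-finite coordinates")
  geo
}

#' Read global cell-type fractions
#'
#' Two-column TSV `(cell_type, fraction)`. Fractions must be nonnegative.
#' A total deviating from 1 (beyond numerical noise) by at most 0.05 is
#' rescaled to unit sum with a warning; a larger deviation is an error.
#'
#' @param path file path.
#' @param header logical header flag.
#' @return named numeric vector of fractions summing to 1.
#' @export
read_fractions <- function(path, header = TRUE) {
  tab <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE, quote = "", comment.char = "")
  f <- as.numeric(tab[[2L]])
  names(f) <- trimws(as.character(tab[[1L]]))
  validate_fractions(f)
}

#' Validate (and if needed rescale) a fraction vector
#'
#' @param f named numeric vector of per-cell-type fractions.
#' @return the validated vector, rescaled to unit sum (with a warning) if
#'   its total deviated from 1 by no more than 0.05.
#' @export
validate_fractions <- function(f) {
  if (is.null(names(f)) || any(!nzchar(names(f))))
    stop("fractions must be a named vector")
  if (anyDuplicated(names(f))) stop("duplicated cell_type in fractions")
  if (any(f < 0)) stop("negative fraction for type: ",
                       paste(names(f)[f < 0], collapse = ", "))
  s <- sum(f)
  if (abs(s - 1) > 0.05)
    stop("fractions sum to ", format(s), "; more than 0.05 from 1")
  if (abs(s - 1) > 1e-9) {
    warning("fractions sum to ", format(s), "; rescaling to 1")
    f <- f / s
  }
  f
}

# Fixed column order of the mapping table on disk.
.mapping_cols <- c("query_cell_id", "assigned_spot_id", "sub_spot_index",
                   "cell_type", "provenance", "confidence")

#' Write / read a cell-to-spot mapping table
#'
#' The mapping table is a TSV with fixed column order
#' `(query_cell_id, assigned_spot_id, sub_spot_index, cell_type, provenance,
#' confidence)`; a missing confidence is emitted as `NA`. `read_mapping()`
#' round-trips `write_mapping()` output exactly.
#'
#' @param table data.frame mapping table (see [map_cells()]).
#' @param path output file.
#' @export
write_mapping <- function(table, path) {
  table <- validate_mapping(table)
  utils::write.table(table[, .mapping_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "", comment.char = "")
  tab$sub_spot_index <- as.integer(tab$sub_spot_index)
  tab$confidence <- as.numeric(tab$confidence)
  validate_mapping(tab)
}

validate_mapping <- function(table) {
  missing_cols <- setdiff(.mapping_cols, names(table))
  if ("confidence" %in% missing_cols) {
    table$confidence <- NA_real_
    missing_cols <- setdiff(missing_cols, "confidence")
  }
  if (length(missing_cols))
    stop("mapping table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(table$sub_spot_index))
    stop("sub_spot_index not unique in mapping table")
  if (!all(table$provenance %in% c("original", "duplicated", "generated")))
    stop("invalid provenance value in mapping table")
  ok <- is.na(table$confidence) | (table$confidence >= 0 & table$confidence <= 1)
  if (!all(ok)) stop("confidence outside [0,1] in mapping table")
  table
}

#' Write a simulated tissue to a directory
#'
#' Emits the tissue as the same plain-text files real data would arrive in:
#' atlas and query count matrices (dense TSV), annotations, spot counts, spot
#' coordinates (grid centers), true per-spot cell numbers, and the ground
#' truth `(cell_id, spot_id)` table, so the mapping pipeline can consume a
#' simulation like any other dataset.
#'
#' @param tissue a `sim_tissue` from [lay_out_and_pool()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_tissue <- function(tissue, dir) {
  stopifnot(inherits(tissue, "sim_tissue"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(tissue$atlas, file.path(dir, "atlas.tsv"))
  write_expression_tsv(tissue$query, file.path(dir, "query.tsv"))
  write_expression_tsv(tissue$spot_counts, file.path(dir, "st.tsv"))
  utils::write.table(tissue$annotation, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tissue$spot_geometry, file.path(dir, "coordinates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(cell_id = names(tissue$truth),
                                spot_id = unname(tissue$truth)),
                     file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(spot_id = colnames(tissue$spot_counts),
                                n_cells = as.integer(table(factor(tissue$truth,
                                  levels = colnames(tissue$spot_counts))))),
                     file.path(dir, "cells_per_spot.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fr <- prop.table(table(tissue$annotation$cell_type))
  utils::write.table(data.frame(cell_type = names(fr), fraction = as.numeric(fr)),
                     file.path(dir, "fractions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
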