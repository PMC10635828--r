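#' Construct an expression matrix
#'
#' The package's container for gene-by-column expression data: a dense numeric
#' matrix with unique gene and column identifiers and a `layer` tag recording
#' the normalization state (`"raw"` counts, `"cpm"` counts-per-million, or
#' `"log2cpm"` log2(CPM + 1)).
#'
#' @param values numeric matrix, genes in rows, cells or spots in columns.
#'   Row and column names are taken as identifiers unless `gene_ids` /
#'   `column_ids` are given.
#' @param gene_ids,column_ids optional character vectors of identifiers.
#' @param layer one of `"raw"`, `"cpm"`, `"log2cpm"`.
#' @return An object of class `expr_matrix`: the numeric matrix with dimnames
#'   set and a `layer` attribute.
#' @examples
#' m <- expr_matrix(matrix(c(1, 2, 0, 0, 3, 4), nrow = 3,
#'                         dimnames = list(paste0("g", 1:3), c("c1", "c2"))))
#' em_layer(m)
#' @export
expr_matrix <- function(values, gene_ids = NULL, column_ids = NULL,
                        layer = c("raw", "cpm", "log2cpm")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(column_ids)) colnames(values) <- column_ids
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expr_matrix requires gene and column identifiers")
  structure(values, layer = layer, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
em_layer <- function(x) attr(x, "layer")

`em_layer<-` <- function(x, value) {
  attr(x, "layer") <- value
  x
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d columns, layer = %s\n",
              nrow(x), ncol(x), em_layer(x)))
  if (nrow(x) > 0L && ncol(x) > 0L) {
    show <- unclass(x)[seq_len(min(5L, nrow(x))), seq_len(min(5L, ncol(x))), drop = FALSE]
    print(show)
    if (nrow(x) > 5L || ncol(x) > 5L) cat("...\n")
  }
  invisible(x)
}

# Validates the class invariants; returns x invisibly or stops.
validate_expr_matrix <- function(x, what = "expression matrix") {
  if (!inherits(x, "expr_matrix")) stop(what, " is not an expr_matrix")
  g <- rownames(x)
  cl <- colnames(x)
  if (anyDuplicated(g)) {
    dup <- unique(g[duplicated(g)])
    stop(what, ": duplicated gene ids: ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (anyDuplicated(cl)) {
    dup <- unique(cl[duplicated(cl)])
    stop(what, ": duplicated column ids: ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (anyNA(x) || any(!is.finite(x)))
    stop(what, ": non-finite values present")
  lay <- em_layer(x)
  if (identical(lay, "raw") && any(x < 0)) {
    bad <- which(unclass(x) < 0, arr.ind = TRUE)[1L, ]
    stop(what, ": negative raw count at gene '", g[bad[1L]],
         "', column '", cl[bad[2L]], "'")
  }
  if (identical(lay, "cpm")) {
    cs <- colSums(x)
    nz <- cs > 0
    if (any(abs(cs[nz] - 1e6) > 1e6 * 1e-6))
      stop(what, ": cpm layer columns must sum to 1e6")
  }
  invisible(x)
}

# Coerce a plain named matrix into an expr_matrix, inferring nothing.
as_expr_matrix <- function(values, layer) {
  expr_matrix(values, layer = layer)
}
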