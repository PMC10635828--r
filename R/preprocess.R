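#' Counts-per-million normalization
#'
#' Scales every nonzero column of a raw count matrix to total 1e6. All-zero
#' columns are left at zero with a warning.
#'
#' @param m an [expr_matrix()] with `layer = "raw"`.
#' @return an `expr_matrix` with `layer = "cpm"`.
#' @export
normalize_cpm <- function(m) {
  if (!identical(em_layer(m), "raw"))
    stop("normalize_cpm expects layer 'raw', got '", em_layer(m), "'")
  cs <- colSums(m)
  zero <- cs == 0
  if (any(zero))
    warning(sum(zero), " all-zero column(s) left unscaled: ",
            paste(utils::head(colnames(m)[zero], 5L), collapse = ", "))
  out <- sweep(unclass(m), 2L, ifelse(zero, 1, cs / 1e6), "/")
  out[, zero] <- 0
  expr_matrix(out, layer = "cpm")
}

#' Log2 transform of CPM values
#'
#' Applies `log2(x + 1)` entrywise so zero counts map to zero.
#'
#' @param m an [expr_matrix()] with `layer = "cpm"`.
#' @return an `expr_matrix` with `layer = "log2cpm"`.
#' @export
log2_transform <- function(m) {
  if (!identical(em_layer(m), "cpm"))
    stop("log2_transform expects layer 'cpm', got '", em_layer(m), "'")
  expr_matrix(log2(unclass(m) + 1), layer = "log2cpm")
}

# CPM + log2 in one step, tolerating an already-normalized input.
normalize_log2cpm <- function(m) {
  switch(em_layer(m),
         raw = log2_transform(normalize_cpm(m)),
         cpm = log2_transform(m),
         log2cpm = m)
}

#' Restrict two expression matrices to their shared genes
#'
#' Both matrices are row-subset and reordered to the lexicographically sorted
#' intersection of their gene sets, the full shared gene space the cost
#' computation operates on (no variable-gene selection, no dimension
#' reduction).
#'
#' @param a,b [expr_matrix()] objects on the same layer.
#' @return list with elements `a`, `b` (reordered matrices) and `genes`.
#' @export
intersect_genes <- function(a, b) {
  if (!identical(em_layer(a), em_layer(b)))
    stop("intersect_genes requires both matrices on the same layer")
  g <- sort(intersect(rownames(a), rownames(b)))
  if (length(g) == 0L) stop("no shared genes between the two matrices")
  list(a = expr_matrix(unclass(a)[g, , drop = FALSE], layer = em_layer(a)),
       b = expr_matrix(unclass(b)[g, , drop = FALSE], layer = em_layer(b)),
       genes = g)
}
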