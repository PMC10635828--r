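#' Spot model: integer cells per spot and the sub-spot expansion
#'
#' A `spot_model` records, for every ST spot, the (estimated or supplied)
#' integer number of cells `n_s >= 1` it contains, the total `L = sum(n_s)`,
#' and the sub-spot-to-spot map used to replicate spot columns into sub-spot
#' columns.
#'
#' @param spot_ids character vector of spot identifiers.
#' @param n integer vector of cells per spot, parallel to `spot_ids`.
#' @return An object of class `spot_model` with fields `spot_ids`, `n`, `L`,
#'   `subspot_to_spot` (character vector of length `L`, contiguous per spot).
#' @export
spot_model <- function(spot_ids, n) {
  spot_ids <- as.character(spot_ids)
  n <- as.integer(round(n))
  if (anyDuplicated(spot_ids)) stop("duplicated spot ids")
  if (length(n) != length(spot_ids)) stop("n and spot_ids differ in length")
  if (any(n < 1L)) stop("every spot must hold at least one cell")
  names(n) <- spot_ids
  structure(list(spot_ids = spot_ids, n = n, L = sum(n),
                 subspot_to_spot = rep(spot_ids, times = n)),
            class = "spot_model")
}

#' @export
print.spot_model <- function(x, ...) {
  cat(sprintf("spot_model: %d spots, L = %d sub-spots, cells/spot %d-%d (mean %.2f)\n",
              length(x$spot_ids), x$L, min(x$n), max(x$n), mean(x$n)))
  invisible(x)
}

#' Fit cells-per-spot from log2 UMI totals
#'
#' The two-point linear rule: the spot with the minimum log2 UMI total is
#' anchored at 1 cell, the mean log2 UMI total is anchored at `mean_cells`,
#' and the line through those two points is evaluated at every spot, rounded
#' to the nearest integer and clamped below at 1. If all spots have the same
#' total, every spot receives `round(mean_cells)`.
#'
#' @param u numeric vector of per-spot log2 UMI totals (named by spot).
#' @param mean_cells assumed mean number of cells per spot (>= 1); typical
#'   choices are 5 for Visium, 10-20 for larger-spot legacy ST arrays.
#' @return integer vector of estimated cells per spot, named like `u`.
#' @export
fit_cells_per_spot <- function(u, mean_cells) {
  stopifnot(is.numeric(u), length(u) >= 2L, mean_cells >= 1)
  umin <- min(u)
  umean <- mean(u)
  if (umean == umin) {
    est <- rep(round(mean_cells), length(u))
  } else {
    slope <- (mean_cells - 1) / (umean - umin)
    est <- round(1 + slope * (u - umin))
  }
  out <- as.integer(pmax(1, est))
  names(out) <- names(u)
  out
}

#' Estimate the number of cells per ST spot from UMI content
#'
#' Total captured RNA per spot tracks the number of cells it contains, so the
#' per-spot sum of UMIs, taken to log2 space to blunt outliers, is used as the
#' predictor in the two-point fit of [fit_cells_per_spot()]. The predictor is
#' `u_s = log2(1 + total raw UMI of spot s)` (the +1 guards empty spots).
#' Callers with segmentation-derived counts should build a [spot_model()]
#' directly and skip this estimate.
#'
#' @param st_raw raw-count [expr_matrix()] of the ST sample (genes x spots).
#' @param mean_cells assumed mean cells per spot; see [fit_cells_per_spot()].
#' @return a [spot_model()].
#' @export
estimate_cells_per_spot <- function(st_raw, mean_cells = 5) {
  if (!identical(em_layer(st_raw), "raw"))
    stop("estimate_cells_per_spot expects raw counts")
  if (ncol(st_raw) < 2L) stop("need at least 2 spots")
  u <- log2(colSums(st_raw) + 1)
  spot_model(colnames(st_raw), fit_cells_per_spot(u, mean_cells))
}

#' Integer per-type cell targets from global fractions
#'
#' Converts global cell-type fractions into integer per-type counts summing
#' exactly to `L` by largest-remainder (Hamilton) apportionment. Remainder
#' seats are awarded by descending fractional remainder, ties broken by
#' descending fraction and then lexicographic type name. Types with zero
#' fraction receive zero cells and are never mapped.
#'
#' @param f named fraction vector (see [validate_fractions()]).
#' @param L total number of sub-spots to fill.
#' @return named integer vector summing to `L`.
#' @export
type_targets_from_fractions <- function(f, L) {
  f <- validate_fractions(f)
  L <- as.integer(L)
  stopifnot(L >= 1L)
  q <- f * L
  base <- floor(q + 1e-9)          # guard exact quotas against FP noise
  rem <- q - base
  shortfall <- L - sum(base)
  tgt <- as.integer(base)
  names(tgt) <- names(f)
  if (shortfall > 0L) {
    eligible <- which(f > 0)
    ord <- eligible[order(-rem[eligible], -f[eligible], names(f)[eligible])]
    add <- ord[seq_len(shortfall)]
    tgt[add] <- tgt[add] + 1L
  }
  stopifnot(sum(tgt) == L)
  tgt
}

#' Replicate spot columns into sub-spot columns
#'
#' Builds the genes x L sub-spot matrix by repeating each spot's expression
#' column `n_s` times. Sub-spot column ids are `"<spot_id>::<replicate>"`.
#'
#' @param st_norm [expr_matrix()] whose columns match `sm$spot_ids`.
#' @param sm a [spot_model()].
#' @return an `expr_matrix` with `sm$L` columns, same layer as the input.
#' @export
expand_subspots <- function(st_norm, sm) {
  if (!setequal(colnames(st_norm), sm$spot_ids) ||
      length(colnames(st_norm)) != length(sm$spot_ids))
    stop("spot ids of the matrix do not match the spot model")
  m <- unclass(st_norm)[, sm$spot_ids, drop = FALSE]
  idx <- rep(seq_along(sm$spot_ids), times = sm$n)
  out <- m[, idx, drop = FALSE]
  repl <- sequence(sm$n)
  colnames(out) <- paste0(sm$subspot_to_spot, "::", repl)
  expr_matrix(out, layer = em_layer(st_norm))
}
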