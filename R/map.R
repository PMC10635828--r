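#' Map single cells onto spatial transcriptomics spots
#'
#' The end-to-end alignment pipeline. Raw scRNA-seq and ST count matrices are
#' CPM-normalized and log2-transformed, restricted to their shared genes,
#' the number of cells per spot is estimated from UMI content (or taken from
#' `cells_per_spot`), global cell-type fractions are converted to integer
#' per-type targets, the scRNA-seq data are resampled to exactly those
#' targets, each spot is replicated into one sub-spot per contained cell,
#' and the resulting balanced assignment problem (one cell per sub-spot,
#' one sub-spot per cell) is solved to global optimality over a
#' correlation- or distance-based cost.
#'
#' @param sc raw-count [expr_matrix()] of the scRNA-seq reference
#'   (genes x cells).
#' @param ann annotation data.frame `(cell_id, cell_type)` for `sc`.
#' @param st raw-count [expr_matrix()] of the ST sample (genes x spots).
#' @param fractions named vector of global cell-type fractions for the ST
#'   sample (from any external deconvolution tool); see
#'   [validate_fractions()].
#' @param mean_cells assumed mean cells per spot for the UMI-based estimate
#'   (ignored when `cells_per_spot` is given). 5 suits Visium-sized spots,
#'   20 legacy ST arrays.
#' @param cells_per_spot optional externally supplied counts: a
#'   [spot_model()] or a named integer vector over the spots (e.g. from
#'   image segmentation).
#' @param metric cost metric, see [build_cost_matrix()].
#' @param mode `"duplication"` (default, real data) or `"generation"`
#'   (benchmarking); see [sample_duplication()].
#' @param solver `"exact"` ([solve_exact()]) or `"integer"`
#'   ([solve_integer_approx()]).
#' @param scale integer scale for `solver = "integer"`.
#' @param seed integer master seed for the resampling step.
#' @return An object of class `cellmap` with components
#'   \describe{
#'     \item{table}{the mapping table: one row per placed cell with
#'       `query_cell_id`, `assigned_spot_id`, `sub_spot_index` (1..L),
#'       `cell_type`, `provenance`, `confidence` (`NA` until
#'       [confidence_scores()] is run).}
#'     \item{assignment}{the solved [solve_exact()] object (duals included).}
#'     \item{spot_model}{the [spot_model()] used.}
#'     \item{targets}{integer per-type targets.}
#'     \item{pool}{the `sampled_pool` metadata (without the expression).}
#'     \item{metric, mode, solver, seed, genes}{run configuration.}
#'   }
#' @examples
#' sim <- generate_atlas(n_types = 3, n_genes = 60, cells_per_type = 20, seed = 1)
#' tis <- lay_out_and_pool(sim$expr, sim$annotation, layout = "blocks",
#'                         target_mean_cells_per_spot = 5, seed = 1)
#' fr <- prop.table(table(sim$annotation$cell_type))
#' fit <- map_cells(sim$expr, sim$annotation, tis$spot_counts,
#'                  fractions = fr, cells_per_spot = true_spot_model(tis),
#'                  mode = "generation", seed = 1)
#' print(fit)
#' precision(fit, tis$truth)$overall
#' @export
map_cells <- function(sc, ann, st, fractions,
                      mean_cells = 5, cells_per_spot = NULL,
                      metric = c("neg_pearson", "neg_spearman", "euclidean"),
                      mode = c("duplication", "generation"),
                      solver = c("exact", "integer"),
                      scale = 1e6, seed = 1) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  solver <- match.arg(solver)
  validate_expr_matrix(sc, "scRNA-seq matrix")
  validate_expr_matrix(st, "ST matrix")
  ann <- validate_annotations(ann)
  fractions <- validate_fractions(fractions)

  sm <- if (is.null(cells_per_spot)) {
    estimate_cells_per_spot(st, mean_cells)
  } else if (inherits(cells_per_spot, "spot_model")) {
    cells_per_spot
  } else {
    if (is.null(names(cells_per_spot)))
      stop("cells_per_spot must be named by spot id")
    spot_model(colnames(st), cells_per_spot[colnames(st)])
  }
  if (!setequal(sm$spot_ids, colnames(st)))
    stop("spot model does not cover the ST matrix spots")

  sc_n <- normalize_log2cpm(sc)
  st_n <- normalize_log2cpm(st)
  shared <- intersect_genes(sc_n, st_n)

  targets <- type_targets_from_fractions(fractions, sm$L)
  pool <- sample_pool(shared$a, ann, targets, seed, scheme = mode)
  subspots <- expand_subspots(shared$b, sm)
  cost <- build_cost_matrix(pool, subspots, metric)
  assign <- if (solver == "exact") solve_exact(cost)
            else solve_integer_approx(cost, scale = scale)

  sub_idx <- assign$perm
  table <- data.frame(query_cell_id = pool$query_id,
                      assigned_spot_id = sm$subspot_to_spot[sub_idx],
                      sub_spot_index = as.integer(sub_idx),
                      cell_type = pool$cell_type,
                      provenance = pool$provenance,
                      confidence = NA_real_,
                      stringsAsFactors = FALSE)
  structure(list(table = validate_mapping(table),
                 assignment = assign,
                 spot_model = sm,
                 targets = targets,
                 pool = pool[c("cell_type", "provenance", "source_cell_id", "seed")],
                 metric = metric, mode = mode, solver = solver, seed = seed,
                 genes = shared$genes,
                 call = match.call()),
            class = "cellmap")
}

#' @export
print.cellmap <- function(x, ...) {
  cat("Cell-to-spot mapping (balanced assignment)\n")
  cat(sprintf("  %d cells -> %d spots (%d sub-spots), %d shared genes\n",
              nrow(x$table), length(x$spot_model$spot_ids), x$spot_model$L,
              length(x$genes)))
  cat(sprintf("  metric %s, mode %s, solver %s, objective %.6g\n",
              x$metric, x$mode, x$solver, x$assignment$total_cost))
  invisible(x)
}

#' @export
summary.cellmap <- function(object, ...) {
  census <- table(object$table$cell_type)
  prov <- table(object$table$provenance)
  per_spot <- table(object$table$assigned_spot_id)
  out <- list(n_cells = nrow(object$table),
              n_spots = length(object$spot_model$spot_ids),
              L = object$spot_model$L,
              objective = object$assignment$total_cost,
              metric = object$metric, mode = object$mode,
              solver = object$solver,
              type_census = census, provenance = prov,
              cells_per_spot = summary(as.integer(per_spot)))
  class(out) <- "summary.cellmap"
  out
}

#' @export
print.summary.cellmap <- function(x, ...) {
  cat(sprintf("cellmap: %d cells over %d spots (L = %d), objective %.6g\n",
              x$n_cells, x$n_spots, x$L, x$objective))
  cat(sprintf("  metric %s | mode %s | solver %s\n", x$metric, x$mode, x$solver))
  cat("  cells per type:\n")
  print(x$type_census)
  cat("  provenance:\n")
  print(x$provenance)
  invisible(x)
}

#' @export
as.data.frame.cellmap <- function(x, ...) x$table

#' Plot a mapped tissue
#'
#' Scatter plot of mapped cells at their assigned spot coordinates (jittered
#' within a spot), colored by cell type.
#'
#' @param x a `cellmap`.
#' @param geometry coordinate data.frame `(spot_id, x, y)`.
#' @param jitter jitter radius as a fraction of the median spot spacing.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cellmap <- function(x, geometry, jitter = 0.3, ...) {
  idx <- match(x$table$assigned_spot_id, geometry$spot_id)
  if (anyNA(idx)) stop("geometry does not cover all assigned spots")
  spacing <- stats::median(stats::dist(cbind(geometry$x, geometry$y)))
  px <- geometry$x[idx] + stats::runif(nrow(x$table), -1, 1) * jitter * spacing / 10
  py <- geometry$y[idx] + stats::runif(nrow(x$table), -1, 1) * jitter * spacing / 10
  types <- factor(x$table$cell_type)
  pal <- grDevices::hcl.colors(nlevels(types), "Dark 3")
  graphics::plot(px, py, col = pal[as.integer(types)], pch = 16, cex = 0.6,
                 xlab = "x", ylab = "y", ...)
  graphics::legend("topright", legend = levels(types), col = pal, pch = 16,
                   cex = 0.7, bty = "n")
  invisible(x)
}

#' Naive per-cell argmax baseline
#'
#' Assigns every query cell independently to the single most similar spot
#' (maximum correlation or minimum Euclidean distance), ignoring spot
#' capacities — the naive baseline balanced assignment is compared against.
#' Many cells may share one spot.
#'
#' @inheritParams map_cells
#' @return a mapping data.frame in the same column layout as
#'   `map_cells()$table` (all cells `provenance = "original"`).
#' @export
baseline_argmax <- function(sc, ann, st,
                            metric = c("neg_pearson", "neg_spearman", "euclidean")) {
  metric <- match.arg(metric)
  ann <- validate_annotations(ann)
  sc_n <- normalize_log2cpm(sc)
  st_n <- normalize_log2cpm(st)
  shared <- intersect_genes(sc_n, st_n)
  d <- pairwise_cost(unclass(shared$a), unclass(shared$b), metric)
  best <- apply(d, 1L, which.min)
  data.frame(query_cell_id = colnames(shared$a),
             assigned_spot_id = colnames(shared$b)[best],
             sub_spot_index = seq_len(ncol(shared$a)),
             cell_type = ann$cell_type[match(colnames(shared$a), ann$cell_id)],
             provenance = "original",
             confidence = NA_real_,
             stringsAsFactors = FALSE)
}

# Rectangular dissimilarity used by the baseline (no balance requirement).
pairwise_cost <- function(a, b, metric) {
  switch(metric,
    neg_pearson = {
      cc <- suppressWarnings(stats::cor(a, b)); cc[is.na(cc)] <- 0; -cc
    },
    neg_spearman = {
      cc <- suppressWarnings(stats::cor(a, b, method = "spearman"))
      cc[is.na(cc)] <- 0; -cc
    },
    euclidean = sqrt(pmax(outer(colSums(a^2), colSums(b^2), "+") -
                            2 * crossprod(a, b), 0)))
}

#' Binned mapping for single-cell-resolution ST
#'
#' For ST data at single-cell resolution (one cell per spot), the spots are
#' randomly partitioned without replacement into bins of up to `bin_size`
#' cells. Each bin is mapped independently: query cells are resampled per
#' the duplication scheme against that bin's per-type targets (global
#' fractions apportioned to the bin size), the balanced problem is solved,
#' and the per-bin results are concatenated. The whole procedure is
#' reproducible from the master `seed`; the scRNA-seq data are freshly
#' resampled for every bin.
#'
#' @inheritParams map_cells
#' @param fractions global cell-type fractions; if `NULL`, the query
#'   annotation's own type proportions are used.
#' @param bin_size maximum cells per bin (default 10000).
#' @return a `cellmap` whose `sub_spot_index` is the global column index of
#'   each ST cell.
#' @export
map_cells_binned <- function(sc, ann, st, fractions = NULL, bin_size = 10000,
                             metric = c("neg_pearson", "neg_spearman", "euclidean"),
                             mode = c("duplication", "generation"),
                             seed = 1) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  ann <- validate_annotations(ann)
  if (is.null(fractions)) {
    fr <- table(ann$cell_type[ann$cell_id %in% colnames(sc)])
    fractions <- as.numeric(fr) / sum(fr)
    names(fractions) <- names(fr)
  }
  fractions <- validate_fractions(fractions)
  S <- ncol(st)
  stopifnot(bin_size >= 1)
  n_bins <- ceiling(S / bin_size)
  membership <- with_seed(derive_seed(seed, "binning"),
                          sample(rep(seq_len(n_bins), length.out = S)))

  sc_n <- normalize_log2cpm(sc)
  st_n <- normalize_log2cpm(st)
  shared <- intersect_genes(sc_n, st_n)

  tables <- vector("list", n_bins)
  total_cost <- 0
  for (b in seq_len(n_bins)) {
    cols <- which(membership == b)
    st_bin <- expr_matrix(unclass(shared$b)[, cols, drop = FALSE],
                          layer = em_layer(shared$b))
    sm <- spot_model(colnames(st_bin), rep(1L, ncol(st_bin)))
    targets <- type_targets_from_fractions(fractions, sm$L)
    # a single bin reduces exactly to the unbinned pipeline, stream included
    bin_seed <- if (n_bins == 1L) seed else derive_seed(seed, paste0("bin", b))
    pool <- sample_pool(shared$a, ann, targets, bin_seed, scheme = mode)
    subspots <- expand_subspots(st_bin, sm)
    cost <- build_cost_matrix(pool, subspots, metric)
    assign <- solve_exact(cost)
    total_cost <- total_cost + assign$total_cost
    qid <- ifelse(is.na(pool$source_cell_id),
                  paste0("b", b, "::", pool$query_id), pool$query_id)
    tables[[b]] <- data.frame(
      query_cell_id = qid,
      assigned_spot_id = sm$subspot_to_spot[assign$perm],
      sub_spot_index = cols[assign$perm],
      cell_type = pool$cell_type,
      provenance = pool$provenance,
      confidence = NA_real_,
      stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, tables)
  structure(list(table = validate_mapping(table),
                 assignment = list(total_cost = total_cost, solver = "jv_exact"),
                 spot_model = spot_model(colnames(st), rep(1L, S)),
                 n_bins = n_bins, bin_size = bin_size,
                 metric = metric, mode = mode, solver = "exact", seed = seed,
                 genes = shared$genes,
                 call = match.call()),
            class = "cellmap")
}
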