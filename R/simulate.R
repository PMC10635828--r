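#' Generate a synthetic single-cell atlas with cell-type structure
#'
#' Draws a raw count matrix with `n_types * cells_per_type` cells. Gene base
#' means follow a log-normal distribution; for each cell type a random
#' fraction `marker_frac` of genes has its mean multiplied by `effect_size`
#' (its marker program); per-cell library sizes are log-normal; counts are
#' negative binomial around the scaled means. This is a synthetic stand-in
#' for an annotated scRNA-seq atlas, used to build ground-truth tissues.
#'
#' @param n_types number of cell types.
#' @param n_genes number of genes.
#' @param cells_per_type cells drawn per type.
#' @param marker_frac fraction of genes upregulated per type (default 0.1).
#' @param effect_size fold change of marker means (default 8; 1 makes types
#'   indistinguishable in expectation).
#' @param dispersion negative-binomial size parameter (default 2).
#' @param lib_sigma sd of log library-size factors (default 0.3).
#' @param seed integer seed.
#' @return list with `expr` (raw [expr_matrix()]), `annotation`
#'   (`cell_id`, `cell_type`), and `markers` (per-type marker gene lists).
#' @export
generate_atlas <- function(n_types, n_genes, cells_per_type,
                           marker_frac = 0.1, effect_size = 8,
                           dispersion = 2, lib_sigma = 0.3, seed = 1) {
  stopifnot(n_types >= 1, n_genes >= 2, cells_per_type >= 1,
            marker_frac >= 0, marker_frac <= 1, effect_size > 0)
  with_seed(derive_seed(seed, "atlas"), {
    genes <- sprintf("g%04d", seq_len(n_genes))
    types <- paste0("type", LETTERS[seq_len(n_types)])
    base_mu <- exp(stats::rnorm(n_genes, mean = 0.5, sd = 1))
    n_mark <- max(1L, round(marker_frac * n_genes))
    markers <- lapply(seq_len(n_types), function(t)
      sort(sample_safe(genes, n_mark)))
    names(markers) <- types
    n_cells <- n_types * cells_per_type
    cell_type <- rep(types, each = cells_per_type)
    lib <- exp(stats::rnorm(n_cells, 0, lib_sigma))
    counts <- matrix(0, n_genes, n_cells, dimnames = list(genes, NULL))
    for (t in seq_len(n_types)) {
      mu <- base_mu
      mu[genes %in% markers[[t]]] <- mu[genes %in% markers[[t]]] * effect_size
      cols <- which(cell_type == types[t])
      lam <- outer(mu, lib[cols])
      counts[, cols] <- stats::rnbinom(length(lam), size = dispersion,
                                       mu = as.vector(lam))
    }
    cell_ids <- sprintf("cell%05d", seq_len(n_cells))
    colnames(counts) <- cell_ids
    list(expr = expr_matrix(counts, layer = "raw"),
         annotation = data.frame(cell_id = cell_ids, cell_type = cell_type,
                                 stringsAsFactors = FALSE),
         markers = markers)
  })
}

#' Place cells in space and pool them into pseudo-spots
#'
#' Assigns every atlas cell a planar position with the requested spatial
#' structure, overlays a square grid sized so that the mean number of cells
#' per nonempty grid spot approximates `target_mean_cells_per_spot`, and
#' sums raw counts of co-located cells into pseudo-bulk spot profiles. The
#' cell-to-spot membership is recorded as ground truth.
#'
#' Layouts: `"blocks"` gives each type a contiguous territory (types tile
#' the unit square in vertical bands); `"gradient"` makes type probability
#' vary smoothly along x; `"random"` scatters all types uniformly.
#'
#' @param atlas raw [expr_matrix()] of single cells.
#' @param ann annotation data.frame for the atlas.
#' @param layout `"blocks"`, `"gradient"`, or `"random"`.
#' @param target_mean_cells_per_spot target mean occupancy of nonempty
#'   spots (5, 15 and 30 emulate common spot resolutions).
#' @param seed integer seed.
#' @return An object of class `sim_tissue`: list with `atlas`, `annotation`,
#'   `positions` (`cell_id`, `x`, `y`), `grid` (`m`, `n`, bounding box),
#'   `spot_counts` (raw pseudo-bulk `expr_matrix`, nonempty spots only),
#'   `spot_geometry` (`spot_id`, `x`, `y` grid centers), `truth` (named
#'   character vector cell_id -> spot_id), `query` (initially identical to
#'   `atlas`; see [add_expression_noise()]), `noise_p` (0), `seed`.
#' @export
lay_out_and_pool <- function(atlas, ann,
                             layout = c("blocks", "gradient", "random"),
                             target_mean_cells_per_spot = 5, seed = 1) {
  layout <- match.arg(layout)
  validate_expr_matrix(atlas, "atlas")
  ann <- validate_annotations(ann)
  n_cells <- ncol(atlas)
  if (target_mean_cells_per_spot > n_cells)
    stop("target mean cells per spot exceeds the number of cells")
  types <- sort(unique(ann$cell_type))
  type_of <- ann$cell_type[match(colnames(atlas), ann$cell_id)]

  with_seed(derive_seed(seed, "layout"), {
    x <- numeric(n_cells); y <- stats::runif(n_cells)
    if (layout == "blocks") {
      # one vertical band per type, uniform within the band
      band <- match(type_of, types)
      w <- 1 / length(types)
      x <- (band - 1) * w + stats::runif(n_cells) * w
    } else if (layout == "gradient") {
      # type t concentrates around x = (t - 0.5)/T with heavy overlap
      center <- (match(type_of, types) - 0.5) / length(types)
      x <- clamp(stats::rnorm(n_cells, mean = center, sd = 0.35), 0, 1)
    } else {
      x <- stats::runif(n_cells)
    }

    # rectangular m x n grid with m*n as close as possible to cells/target
    n_spots <- n_cells / target_mean_cells_per_spot
    nx <- max(1L, round(sqrt(n_spots)))
    ny <- max(1L, round(n_spots / nx))
    gx <- pmin(nx, 1L + floor(x * nx))
    gy <- pmin(ny, 1L + floor(y * ny))
    spot_of <- sprintf("spot_%02d_%02d", gx, gy)

    keep <- sort(unique(spot_of))
    agg <- matrix(0, nrow(atlas), length(keep),
                  dimnames = list(rownames(atlas), keep))
    f <- factor(spot_of, levels = keep)
    # pseudo-bulk: exact integer sum of raw counts per spot
    for (s in seq_along(keep)) {
      cols <- which(f == keep[s])
      agg[, s] <- rowSums(unclass(atlas)[, cols, drop = FALSE])
    }
    geo <- data.frame(spot_id = keep,
                      x = (as.integer(sub("spot_(\\d+)_(\\d+)", "\\1", keep)) - 0.5) / nx,
                      y = (as.integer(sub("spot_(\\d+)_(\\d+)", "\\2", keep)) - 0.5) / ny,
                      stringsAsFactors = FALSE)
    truth <- spot_of
    names(truth) <- colnames(atlas)
    structure(list(atlas = atlas, annotation = ann,
                   positions = data.frame(cell_id = colnames(atlas), x = x, y = y,
                                          stringsAsFactors = FALSE),
                   grid = list(m = nx, n = ny, bbox = c(0, 0, 1, 1)),
                   spot_counts = expr_matrix(agg, layer = "raw"),
                   spot_geometry = geo,
                   truth = truth,
                   query = atlas, noise_p = 0, seed = seed),
              class = "sim_tissue")
  })
}

#' @export
print.sim_tissue <- function(x, ...) {
  cat(sprintf("sim_tissue: %d cells, %d types, %d nonempty spots (grid %dx%d), mean %.2f cells/spot, noise p = %g\n",
              ncol(x$atlas), length(unique(x$annotation$cell_type)),
              ncol(x$spot_counts), x$grid$m, x$grid$n,
              ncol(x$atlas) / ncol(x$spot_counts), x$noise_p))
  invisible(x)
}

#' True spot model of a simulated tissue
#'
#' The exact per-spot cell counts implied by the ground truth membership.
#'
#' @param tissue a `sim_tissue`.
#' @return a [spot_model()].
#' @export
true_spot_model <- function(tissue) {
  stopifnot(inherits(tissue, "sim_tissue"))
  n <- table(factor(tissue$truth, levels = colnames(tissue$spot_counts)))
  spot_model(colnames(tissue$spot_counts), as.integer(n))
}

#' Permute a fraction of each cell's transcriptome within its type
#'
#' For every cell, a random subset of `round(fraction * n_genes)` genes takes
#' its values from one randomly chosen *other* cell of the same type (the
#' donor must not be expression-identical to the recipient), making repeated
#' profiles distinct while preserving type structure. A type with a single
#' cell is left unchanged with a warning.
#'
#' @param expr [expr_matrix()] (any layer).
#' @param ann annotation data.frame covering the columns of `expr`.
#' @param fraction fraction of genes replaced per cell (default 0.2).
#' @param seed integer seed.
#' @return an `expr_matrix` of the same shape and layer.
#' @export
permute_within_type <- function(expr, ann, fraction = 0.2, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(expr)
  ann <- validate_annotations(ann)
  type_of <- ann$cell_type[match(colnames(expr), ann$cell_id)]
  out <- unclass(expr)
  g <- nrow(out)
  n_swap <- round(fraction * g)
  if (n_swap == 0L) return(expr)
  with_seed(derive_seed(seed, "permute"), {
    for (k in unique(type_of)) {
      cols <- which(type_of == k)
      if (length(cols) < 2L) {
        warning("cell type '", k, "' has a single cell; left unchanged")
        next
      }
      for (j in cols) {
        candidates <- setdiff(cols, j)
        donor <- sample_safe(candidates, 1L)
        tries <- 0L
        while (identical(out[, donor], out[, j]) && tries < 10L) {
          donor <- sample_safe(candidates, 1L)
          tries <- tries + 1L
        }
        sel <- sample.int(g, n_swap)
        out[sel, j] <- out[sel, donor]
      }
    }
  })
  expr_matrix(out, layer = em_layer(expr))
}

#' Multiplicative exponentiated-Gaussian expression noise
#'
#' Emulates technical variation between platforms: per cell, a random
#' fraction `p` of genes is selected and each selected value is multiplied
#' by an independent draw from `2^N(0,1)` (median multiplier 1, factors
#' mostly within a four-fold range). Unselected values are untouched.
#'
#' @param expr raw [expr_matrix()].
#' @param p fraction of genes perturbed per cell (the study grid is 0.05,
#'   0.10, 0.25).
#' @param seed integer seed.
#' @return an `expr_matrix` of the same shape, `layer = "raw"`.
#' @export
add_expression_noise <- function(expr, p, seed = 1) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (p == 0) return(expr)
  out <- unclass(expr)
  g <- nrow(out)
  n_sel <- round(p * g)
  if (n_sel == 0L) return(expr)
  with_seed(derive_seed(seed, "noise"), {
    for (j in seq_len(ncol(out))) {
      sel <- sample.int(g, n_sel)
      out[sel, j] <- out[sel, j] * 2^stats::rnorm(n_sel)
    }
  })
  expr_matrix(out, layer = em_layer(expr))
}

#' Simulate a noised ground-truth tissue in one call
#'
#' Convenience wrapper: [generate_atlas()] + [lay_out_and_pool()] +
#' [add_expression_noise()] on the query copy.
#'
#' @inheritParams generate_atlas
#' @inheritParams lay_out_and_pool
#' @param noise_p noise fraction for the query (see
#'   [add_expression_noise()]).
#' @return a `sim_tissue` whose `query` carries the noise.
#' @export
simulate_tissue <- function(n_types = 5, n_genes = 200, cells_per_type = 40,
                            layout = "blocks", target_mean_cells_per_spot = 5,
                            noise_p = 0, marker_frac = 0.1, effect_size = 8,
                            seed = 1) {
  atl <- generate_atlas(n_types, n_genes, cells_per_type,
                        marker_frac = marker_frac, effect_size = effect_size,
                        seed = seed)
  tis <- lay_out_and_pool(atl$expr, atl$annotation, layout = layout,
                          target_mean_cells_per_spot = target_mean_cells_per_spot,
                          seed = seed)
  tis$markers <- atl$markers
  if (noise_p > 0) {
    tis$query <- add_expression_noise(tis$atlas, noise_p, seed = seed)
    tis$noise_p <- noise_p
  }
  tis
}

#' Perturb cell-type fractions with bounded multiplicative noise
#'
#' Emulates realistic deconvolution error, with proportionally larger error
#' for rarer types. For each type with fraction `x > 0`, draw
#' `y ~ N(0, sigma^2)` with `sigma = 1 / (2 * x^(1/3))`, clamp to
#' `z = max(-2, min(2, y))`, scale `x * 2^z` (so every pre-normalization
#' ratio lies within a four-fold range), and renormalize to unit sum. Zero
#' fractions pass through unperturbed.
#'
#' @param f named fraction vector.
#' @param seed integer seed.
#' @return a named fraction vector summing to 1, with attribute
#'   `multipliers` (the pre-normalization factors `2^z`, all in `[1/4, 4]`).
#' @export
perturb_fractions <- function(f, seed = 1) {
  f <- validate_fractions(f)
  with_seed(derive_seed(seed, "fractions"), {
    pos <- f > 0
    sigma <- fraction_sigma(f[pos])
    y <- stats::rnorm(sum(pos), 0, sigma)
    z <- clamp(y, -2, 2)
    mult <- rep(1, length(f))
    mult[pos] <- 2^z
    out <- f * mult
    structure(out / sum(out), multipliers = mult)
  })
}

# Noise scale for a fraction estimate x: rarer types get larger noise.
fraction_sigma <- function(x) 1 / (2 * x^(1 / 3))

# Noise scale for a cells-per-spot estimate n at tuning parameter p.
count_sigma <- function(n, p) p / n^(1 / 3)

#' Perturb per-spot cell counts with bounded multiplicative noise
#'
#' For each spot with count `n`, draw `y ~ N(0, sigma^2)` with
#' `sigma = p / n^(1/3)`, and replace the count by
#' `max(1, min(n * round(2^y), ceiling(1.1 * M)))` where `M` is the original
#' maximum count. The tuning parameter `p` controls how far the perturbed
#' counts depart from the originals; `p = 1.4` matches the calibration used
#' for 5-cells-per-spot designs (larger spot occupancies use larger `p`, up
#' to 3.7).
#'
#' @param sm a [spot_model()].
#' @param p positive tuning parameter.
#' @param seed integer seed.
#' @return a perturbed [spot_model()].
#' @export
perturb_cell_counts <- function(sm, p = 1.4, seed = 1) {
  stopifnot(inherits(sm, "spot_model"), p > 0)
  with_seed(derive_seed(seed, "counts"), {
    M <- max(sm$n)
    cap <- ceiling(1.1 * M)
    sigma <- count_sigma(sm$n, p)
    y <- stats::rnorm(length(sm$n), 0, sigma)
    nbar <- pmax(1, pmin(sm$n * round(2^y), cap))
    spot_model(sm$spot_ids, nbar)
  })
}

#' Match columns to their most-correlated same-type columns
#'
#' For every column of `target`, find the column of `reference` with the
#' same cell type label that maximizes Pearson correlation — the
#' bead-to-cell replacement construction used to substitute low-coverage
#' spatial profiles with full transcriptomes of matching type.
#'
#' @param target [expr_matrix()] whose columns are to be replaced.
#' @param target_ann annotation for `target` columns.
#' @param reference [expr_matrix()] offering replacement columns (same gene
#'   space).
#' @param reference_ann annotation for `reference` columns.
#' @return character vector: for each target column, the id of its best
#'   same-type reference column.
#' @export
match_by_correlation <- function(target, target_ann, reference, reference_ann) {
  if (!identical(rownames(target), rownames(reference)))
    stop("matrices must share an identical gene ordering")
  t_type <- target_ann$cell_type[match(colnames(target), target_ann$cell_id)]
  r_type <- reference_ann$cell_type[match(colnames(reference), reference_ann$cell_id)]
  out <- character(ncol(target))
  cc <- suppressWarnings(stats::cor(unclass(target), unclass(reference)))
  cc[is.na(cc)] <- 0
  for (j in seq_len(ncol(target))) {
    cand <- which(r_type == t_type[j])
    if (!length(cand)) stop("no reference column of type '", t_type[j], "'")
    out[j] <- colnames(reference)[cand[which.max(cc[j, cand])]]
  }
  names(out) <- colnames(target)
  out
}
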