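# Mapping as a data.frame regardless of whether a cellmap or table is given.
mapping_table <- function(mapping) {
  if (inherits(mapping, "cellmap")) mapping$table
  else validate_mapping(mapping)
}

#' Single-cell mapping precision against ground truth
#'
#' A mapped cell is correct when its assigned spot exactly matches its
#' ground-truth spot. Precision is the number of correct unique cells over
#' the number of unique mapped cells with known ground-truth locations.
#' Duplicated copies of a cell count once: a cell mapped to its true spot by
#' at least one copy is one true positive, without inflating the
#' denominator. Generated cells have no ground-truth location and are
#' excluded from both numerator and denominator.
#'
#' @param mapping a `cellmap` or mapping data.frame.
#' @param truth named character vector `cell_id -> spot_id`.
#' @return list of class `precision_report`: `overall`, `per_type`
#'   (named vector), `TP_sc`, `denominator`.
#' @export
precision <- function(mapping, truth) {
  tab <- mapping_table(mapping)
  tab <- tab[tab$provenance != "generated", , drop = FALSE]
  tab <- tab[tab$query_cell_id %in% names(truth), , drop = FALSE]
  ids <- unique(tab$query_cell_id)
  if (length(ids) == 0L)
    stop("no mapped cells with ground-truth locations")
  correct_row <- tab$assigned_spot_id == truth[tab$query_cell_id]
  tp_ids <- unique(tab$query_cell_id[correct_row])
  type_of <- tab$cell_type[match(ids, tab$query_cell_id)]
  per_type <- vapply(split(ids %in% tp_ids, type_of), mean, numeric(1))
  structure(list(overall = length(tp_ids) / length(ids),
                 per_type = per_type,
                 TP_sc = length(tp_ids),
                 denominator = length(ids)),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("precision: %.4f (%d / %d unique cells)\n",
              x$overall, x$TP_sc, x$denominator))
  invisible(x)
}

# Pearson correlation over a shared name set; degenerate (constant) input is
# reported as 0 with attribute degenerate = TRUE.
.concordance <- function(est, true, min_n) {
  common <- intersect(names(est), names(true))
  if (length(common) < min_n)
    stop("need at least ", min_n, " shared entries")
  e <- as.numeric(est[common]); t <- as.numeric(true[common])
  if (stats::sd(e) == 0 || stats::sd(t) == 0)
    return(structure(0, degenerate = TRUE))
  structure(stats::cor(e, t), degenerate = FALSE)
}

#' Concordance between estimated and true cell-type fractions
#'
#' Pearson correlation over the shared type set (at least 3 types). A
#' constant vector makes the correlation undefined; 0 is returned with
#' attribute `degenerate = TRUE`.
#'
#' @param est,true named fraction vectors.
#' @return numeric correlation with attribute `degenerate`.
#' @export
fraction_concordance <- function(est, true) .concordance(est, true, 3L)

#' Concordance between estimated and true cells per spot
#'
#' Pearson correlation between a spot model's counts and reference counts
#' over the shared spots.
#'
#' @param est a [spot_model()] (or named numeric vector).
#' @param true named numeric vector of reference counts per spot.
#' @return numeric correlation with attribute `degenerate`.
#' @export
cells_per_spot_concordance <- function(est, true) {
  e <- if (inherits(est, "spot_model")) est$n else est
  .concordance(e, true, 3L)
}

#' Rank marker genes per cell type
#'
#' One-vs-rest two-sided Wilcoxon rank-sum test per gene on normalized
#' expression, restricted to genes detected (value > 0) in at least
#' `min_pct` of the type's cells and with positive log2 fold change
#' (difference of means in log2 space). P values are Benjamini-Hochberg
#' adjusted within each type; genes are ranked by adjusted p ascending
#' (ties by fold change descending) and truncated to `max_markers`. A type
#' yielding fewer than `min_markers` qualifying genes is skipped with a
#' warning.
#'
#' @param sc [expr_matrix()]; raw input is CPM/log2-normalized internally.
#' @param ann annotation data.frame covering the columns of `sc`.
#' @param min_pct detection fraction threshold within the type (default 0.1).
#' @param min_markers,max_markers marker count bounds (defaults 5 and 50).
#' @return named list, one data.frame per retained type with columns
#'   `gene`, `log2fc`, `p`, `p_adj`.
#' @export
find_markers <- function(sc, ann, min_pct = 0.1, min_markers = 5, max_markers = 50) {
  ann <- validate_annotations(ann)
  x <- unclass(normalize_log2cpm(sc))
  type_of <- ann$cell_type[match(colnames(x), ann$cell_id)]
  types <- sort(unique(type_of))
  if (length(types) < 2L) stop("need at least 2 cell types")
  out <- list()
  for (k in types) {
    inside <- type_of == k
    xin <- x[, inside, drop = FALSE]
    xout <- x[, !inside, drop = FALSE]
    detected <- rowMeans(xin > 0) >= min_pct
    lfc <- rowMeans(xin) - rowMeans(xout)
    candidates <- which(detected & lfc > 0)
    if (length(candidates) == 0L) {
      warning("type '", k, "' has no qualifying marker genes; skipped")
      next
    }
    p <- vapply(candidates, function(g)
      suppressWarnings(stats::wilcox.test(xin[g, ], xout[g, ],
                                          exact = FALSE)$p.value),
      numeric(1))
    p[is.na(p)] <- 1
    p_adj <- stats::p.adjust(p, method = "BH")
    ord <- order(p_adj, -lfc[candidates])
    res <- data.frame(gene = rownames(x)[candidates][ord],
                      log2fc = lfc[candidates][ord],
                      p = p[ord], p_adj = p_adj[ord],
                      stringsAsFactors = FALSE)
    res <- utils::head(res, max_markers)
    if (nrow(res) < min_markers) {
      warning("type '", k, "' has fewer than ", min_markers,
              " marker genes; skipped")
      next
    }
    out[[k]] <- res
  }
  out
}

# Per-gene z-scaling (genes with zero variance map to 0).
scale_genes <- function(x) {
  mu <- rowMeans(x)
  sd <- apply(x, 1L, stats::sd)
  sd[sd == 0] <- 1
  (x - mu) / sd
}

#' Confidence scores for mapped cells
#'
#' Post-hoc quality control asking, for each mapped cell type, how probable
#' it is that the type belongs to each spot. Per type: spots with and
#' without at least one assigned cell of the type form positive and negative
#' sets (`n_per_class` each, sampled with replacement when scarce); each
#' selected spot is reconstituted as a pseudo-bulk by averaging the
#' normalized-and-scaled profiles of its assigned cells over the type's
#' marker genes; a probabilistic linear support vector machine trained to
#' separate the two groups then scores every ST spot, and every mapped cell
#' inherits its spot's probability. Cells scoring below `threshold` are
#' flagged for removal.
#'
#' A type assigned to no spot or to every spot has no training contrast; its
#' cells receive `NA` scores and the type is listed in `skipped`.
#'
#' @param mapping a `cellmap` or mapping data.frame.
#' @param sc scRNA-seq [expr_matrix()] covering the mapped (non-generated)
#'   cells; raw input is normalized internally.
#' @param st ST [expr_matrix()] over the mapped spots.
#' @param seed integer seed for the spot sampling.
#' @param markers optional precomputed [find_markers()] result; computed
#'   from `sc` and the mapping's type labels when `NULL`.
#' @param n_per_class training spots per class (default 50).
#' @param threshold removal flag cutoff on the probability scale
#'   (default 0.10).
#' @return list of class `confidence_report`: `cell_scores` (the mapping
#'   table plus `confidence` and `flagged`), `spot_scores` (type x spot
#'   probability matrix), `markers`, `skipped`, `threshold`.
#' @export
confidence_scores <- function(mapping, sc, st, seed = 1, markers = NULL,
                              n_per_class = 50, threshold = 0.10) {
  tab <- mapping_table(mapping)
  sc_n <- normalize_log2cpm(sc)
  st_n <- normalize_log2cpm(st)
  shared <- intersect_genes(sc_n, st_n)
  sc_s <- scale_genes(unclass(shared$a))
  st_s <- scale_genes(unclass(shared$b))
  spots <- colnames(st_s)
  if (is.null(markers)) {
    ann <- unique(tab[tab$provenance != "generated",
                      c("query_cell_id", "cell_type")])
    names(ann) <- c("cell_id", "cell_type")
    markers <- find_markers(shared$a, ann)
  }

  # pseudo-bulk per spot: mean scaled profile of all assigned (non-generated)
  # cells present in the scRNA-seq matrix
  tab_known <- tab[tab$query_cell_id %in% colnames(sc_s), , drop = FALSE]
  by_spot <- split(tab_known$query_cell_id, tab_known$assigned_spot_id)
  pseudo <- matrix(NA_real_, nrow(sc_s), length(spots),
                   dimnames = list(rownames(sc_s), spots))
  for (s in names(by_spot))
    pseudo[, s] <- rowMeans(sc_s[, by_spot[[s]], drop = FALSE])

  types <- sort(unique(tab$cell_type))
  spot_scores <- matrix(NA_real_, length(types), length(spots),
                        dimnames = list(types, spots))
  skipped <- character(0)
  for (k in types) {
    mk <- markers[[k]]$gene
    mk <- mk[mk %in% rownames(st_s)]
    pos <- unique(tab$assigned_spot_id[tab$cell_type == k])
    pos <- pos[pos %in% names(by_spot)]
    neg <- setdiff(names(by_spot), pos)
    if (length(mk) < 2L || length(pos) == 0L || length(neg) == 0L) {
      skipped <- c(skipped, k)
      next
    }
    sel <- with_seed(derive_seed(seed, paste0("conf::", k)), {
      list(pos = sample_safe(pos, n_per_class, replace = length(pos) < n_per_class),
           neg = sample_safe(neg, n_per_class, replace = length(neg) < n_per_class))
    })
    xtrain <- t(pseudo[mk, c(sel$pos, sel$neg), drop = FALSE])
    ytrain <- factor(rep(c("with", "without"), each = n_per_class),
                     levels = c("with", "without"))
    fit <- e1071::svm(x = xtrain, y = ytrain, kernel = "linear",
                      probability = TRUE, scale = FALSE)
    pred <- stats::predict(fit, t(st_s[mk, , drop = FALSE]), probability = TRUE)
    spot_scores[k, ] <- attr(pred, "probabilities")[, "with"]
  }

  conf <- spot_scores[cbind(match(tab$cell_type, types),
                            match(tab$assigned_spot_id, spots))]
  cell_scores <- tab
  cell_scores$confidence <- as.numeric(conf)
  cell_scores$flagged <- !is.na(conf) & conf < threshold
  structure(list(cell_scores = cell_scores, spot_scores = spot_scores,
                 markers = markers, skipped = skipped, threshold = threshold),
            class = "confidence_report")
}

#' @export
print.confidence_report <- function(x, ...) {
  scored <- sum(!is.na(x$cell_scores$confidence))
  cat(sprintf("confidence_report: %d/%d cells scored, %d flagged below %.2f",
              scored, nrow(x$cell_scores), sum(x$cell_scores$flagged),
              x$threshold))
  if (length(x$skipped))
    cat("; skipped types: ", paste(x$skipped, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Partition mapped cells by distance to tumor cells
#'
#' For every mapped non-tumor cell, computes the mean Euclidean distance from
#' its spot to the spots of its `k` nearest mapped tumor cells, then
#' median-stratifies the distances within each cell type into `"close"` and
#' `"far"` groups (ties at the median go to `"close"`). Cells assigned to
#' spots listed in `tumor_region_spots` get distance 0.
#'
#' @param mapping a `cellmap` or mapping data.frame.
#' @param geometry coordinate data.frame `(spot_id, x, y)`.
#' @param tumor_type the cell type label marking tumor cells.
#' @param k number of nearest tumor cells averaged (default 5; capped at the
#'   number of mapped tumor cells).
#' @param tumor_region_spots optional spot ids inside an annotated tumor
#'   region; cells mapped there receive distance 0.
#' @return data.frame: the non-tumor mapping rows plus `distance` and
#'   `group` (`"close"`/`"far"`).
#' @export
partition_by_tumor_distance <- function(mapping, geometry, tumor_type, k = 5,
                                        tumor_region_spots = NULL) {
  tab <- mapping_table(mapping)
  tum <- tab[tab$cell_type == tumor_type, , drop = FALSE]
  if (nrow(tum) < 1L) stop("no mapped cells of tumor type '", tumor_type, "'")
  k <- min(k, nrow(tum))
  coords <- function(ids) {
    idx <- match(ids, geometry$spot_id)
    if (anyNA(idx)) stop("geometry does not cover all assigned spots")
    cbind(geometry$x[idx], geometry$y[idx])
  }
  tc <- coords(tum$assigned_spot_id)
  rest <- tab[tab$cell_type != tumor_type, , drop = FALSE]
  rc <- coords(rest$assigned_spot_id)
  d <- vapply(seq_len(nrow(rest)), function(i) {
    dd <- sqrt((tc[, 1] - rc[i, 1])^2 + (tc[, 2] - rc[i, 2])^2)
    mean(sort(dd)[seq_len(k)])
  }, numeric(1))
  if (!is.null(tumor_region_spots))
    d[rest$assigned_spot_id %in% tumor_region_spots] <- 0
  rest$distance <- d
  rest$group <- NA_character_
  for (t in unique(rest$cell_type)) {
    sel <- rest$cell_type == t
    med <- stats::median(rest$distance[sel])
    rest$group[sel] <- ifelse(rest$distance[sel] <= med, "close", "far")
  }
  rest
}

#' Rank genes by close/far log2 fold change
#'
#' For the cells of one type split into `"close"` and `"far"` groups,
#' computes per gene `log2((mean_close + pc) / (mean_far + pc))` on
#' normalized expression and returns genes in descending order — the
#' pre-ranked list format consumed by GSEA tools. Both groups must contain
#' at least `min_cells` cells; otherwise `NULL` is returned with a warning
#' (the type is excluded).
#'
#' @param expr normalized [expr_matrix()] (or matrix) of the type's cells.
#' @param groups character vector (`"close"`/`"far"`) parallel to the
#'   columns of `expr`.
#' @param pseudocount added to both means (default 1).
#' @param min_cells minimum group size (default 10).
#' @return data.frame `(gene, log2fc)` sorted descending, or `NULL`.
#' @export
rank_genes_by_fold_change <- function(expr, groups, pseudocount = 1,
                                      min_cells = 10) {
  x <- unclass(expr)
  stopifnot(length(groups) == ncol(x))
  n_close <- sum(groups == "close")
  n_far <- sum(groups == "far")
  if (n_close < min_cells || n_far < min_cells) {
    warning("fewer than ", min_cells, " cells in a partition; type excluded")
    return(NULL)
  }
  lfc <- log2((rowMeans(x[, groups == "close", drop = FALSE]) + pseudocount) /
                (rowMeans(x[, groups == "far", drop = FALSE]) + pseudocount))
  out <- data.frame(gene = rownames(x), log2fc = as.numeric(lfc),
                    stringsAsFactors = FALSE)
  out[order(-out$log2fc), , drop = FALSE]
}

#' Write a pre-ranked gene list
#'
#' Two-column TSV `(gene, score)` without header — the de-facto ranked-list
#' input of GSEA tools.
#'
#' @param ranked data.frame from [rank_genes_by_fold_change()].
#' @param path output file.
#' @export
write_ranked_list <- function(ranked, path) {
  utils::write.table(ranked[, c("gene", "log2fc")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Retention index: preservation of cell-cell correlation structure
#'
#' Given a query matrix of mapped cells and the reference matrix of their
#' assigned cells over the same ordered cell set (log2 space), computes the
#' pairwise Pearson correlation matrix of each and returns the Pearson
#' correlation between the two upper triangles. 1 means the transcriptomic
#' neighborhood structure is perfectly retained. Zero-variance columns
#' contribute 0 correlations.
#'
#' @param query,reference matrices (genes x cells), columns ordered
#'   identically.
#' @return numeric in `[-1, 1]`.
#' @export
retention_index <- function(query, reference) {
  q <- unclass(query); r <- unclass(reference)
  if (ncol(q) != ncol(r)) stop("matrices must cover the same ordered cell set")
  if (ncol(q) < 3L) stop("need at least 3 cells")
  Q <- suppressWarnings(stats::cor(q)); Q[is.na(Q)] <- 0
  R <- suppressWarnings(stats::cor(r)); R[is.na(R)] <- 0
  ut <- upper.tri(Q)
  cor0(Q[ut], R[ut])
}

#' Balanced per-type subsample
#'
#' Uniformly samples (without replacement) `n` cells of every type that has
#' at least `n`; types with fewer are dropped. Supports the equal-type
#' sampling convention of [retention_index()] comparisons (default 150).
#'
#' @param ann annotation data.frame `(cell_id, cell_type)`.
#' @param n cells per type (default 150).
#' @param seed integer seed.
#' @return character vector of sampled cell ids.
#' @export
subsample_per_type <- function(ann, n = 150, seed = 1) {
  ann <- validate_annotations(ann)
  out <- character(0)
  for (k in sort(unique(ann$cell_type))) {
    ids <- ann$cell_id[ann$cell_type == k]
    if (length(ids) < n) next
    out <- c(out, with_seed(derive_seed(seed, paste0("sub::", k)),
                            sort(sample_safe(ids, n))))
  }
  out
}
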