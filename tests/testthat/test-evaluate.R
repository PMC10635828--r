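mk_mapping <- function(ids, spots, types = "T",
                       prov = "original", sub = seq_along(ids)) {
  data.frame(query_cell_id = ids, assigned_spot_id = spots,
             sub_spot_index = sub, cell_type = types, provenance = prov,
             confidence = NA_real_, stringsAsFactors = FALSE)
}

test_that("precision counts unique cells and honors the multi-copy rule", {
  truth <- c(c1 = "s1", c2 = "s2", c3 = "s3", c4 = "s4")
  tab <- mk_mapping(c("c1", "c2", "c3", "c4"), c("s1", "s2", "s3", "s9"))
  pr <- precision(tab, truth)
  expect_equal(pr$overall, 0.75)
  expect_equal(pr$denominator, 4L)

  # duplicated copies: correct at least once counts once, denominator unchanged
  tab2 <- mk_mapping(c("c1", "c1", "c2"), c("s9", "s1", "s9"),
                     prov = c("original", "duplicated", "original"))
  pr2 <- precision(tab2, truth)
  expect_equal(pr2$overall, 0.5)
  expect_equal(pr2$denominator, 2L)

  # generated cells are excluded entirely
  tab3 <- rbind(tab, mk_mapping("T::gen1", "s1", prov = "generated", sub = 99L))
  expect_equal(precision(tab3, truth)$overall, 0.75)
  expect_error(precision(tab3[5, ], truth), "ground-truth")
})

test_that("concordance helpers handle extremes and degeneracy", {
  f <- c(a = 0.2, b = 0.3, c = 0.5)
  expect_equal(as.numeric(fraction_concordance(f, f)), 1)
  # reversed ranking of equally spaced fractions is perfectly anti-correlated
  expect_equal(as.numeric(fraction_concordance(c(a = 0.2, b = 0.3, c = 0.4),
                                               c(a = 0.4, b = 0.3, c = 0.2))),
               -1)
  flat <- c(a = 1 / 3, b = 1 / 3, c = 1 / 3)
  got <- fraction_concordance(flat, f)
  expect_equal(as.numeric(got), 0)
  expect_true(attr(got, "degenerate"))
  expect_error(fraction_concordance(c(a = 1), c(a = 1)), "at least 3")

  sm <- spot_model(c("s1", "s2", "s3"), c(2, 4, 6))
  expect_equal(as.numeric(cells_per_spot_concordance(
    sm, c(s1 = 10, s2 = 20, s3 = 30))), 1)
  set.seed(2)
  big <- stats::setNames(sample(1:20, 1000, TRUE), paste0("s", 1:1000))
  shuffled <- stats::setNames(sample(big), names(big))
  expect_lt(abs(as.numeric(cells_per_spot_concordance(big, shuffled))), 0.1)
})

test_that("an exclusive gene tops its type's marker list", {
  a <- generate_atlas(3, 60, 20, seed = 15)
  x <- unclass(a$expr)
  x["g0001", ] <- 0
  x["g0001", a$annotation$cell_type == "typeB"] <- 50
  mk <- find_markers(expr_matrix(x, layer = "raw"), a$annotation)
  expect_identical(mk$typeB$gene[1], "g0001")
  expect_true(all(mk$typeB$log2fc > 0))
  expect_true(all(mk$typeB$p_adj >= mk$typeB$p))
  expect_true(all(vapply(mk, nrow, 1L) >= 5 & vapply(mk, nrow, 1L) <= 50))
})

test_that("marker discovery is gene-order invariant and label-sensitive", {
  a <- generate_atlas(2, 80, 15, seed = 16)
  mk1 <- find_markers(a$expr, a$annotation)
  shuf <- unclass(a$expr)[sample(nrow(a$expr)), ]
  mk2 <- find_markers(expr_matrix(shuf, layer = "raw"), a$annotation)
  expect_identical(lapply(mk1, `[[`, "gene"), lapply(mk2, `[[`, "gene"))
  # permuted labels leave no real signal
  meds <- sapply(1:3, function(s) {
    ann <- a$annotation
    set.seed(s)
    ann$cell_type <- sample(ann$cell_type)
    mkp <- suppressWarnings(find_markers(a$expr, ann))
    if (length(mkp) == 0) return(1)
    min(sapply(mkp, function(d) stats::median(d$p_adj)))
  })
  expect_gt(stats::median(meds), 0.05)
})

test_that("tumor-distance partition median-splits each type", {
  geo <- data.frame(spot_id = c("t0", paste0("s", 1:4)),
                    x = c(0, 1, 2, 3, 4), y = 0)
  tab <- rbind(mk_mapping("tum1", "t0", types = "Tumor"),
               mk_mapping(paste0("c", 1:4), paste0("s", 1:4), types = "Tcell",
                          sub = 2:5))
  tab$sub_spot_index <- seq_len(nrow(tab))
  part <- partition_by_tumor_distance(tab, geo, "Tumor", k = 5)
  expect_identical(part$group[match(paste0("c", 1:4), part$query_cell_id)],
                   c("close", "close", "far", "far"))
  expect_equal(part$distance[part$query_cell_id == "c3"], 3)
  # annotated tumor-region spots force distance zero
  part0 <- partition_by_tumor_distance(tab, geo, "Tumor", k = 5,
                                       tumor_region_spots = "s4")
  expect_equal(part0$distance[part0$query_cell_id == "c4"], 0)
  expect_error(partition_by_tumor_distance(tab, geo, "Bcell"), "no mapped")
})

test_that("distance partition sizes differ by at most one per type", {
  set.seed(5)
  n <- 31
  geo <- data.frame(spot_id = c("t0", paste0("s", 1:n)),
                    x = c(0, runif(n, 1, 10)), y = c(0, runif(n, 1, 10)))
  tab <- rbind(mk_mapping("tum1", "t0", types = "Tumor"),
               mk_mapping(paste0("c", 1:n), paste0("s", 1:n), types = "Tcell"))
  tab$sub_spot_index <- seq_len(nrow(tab))
  part <- partition_by_tumor_distance(tab, geo, "Tumor")
  expect_lte(abs(sum(part$group == "close") - sum(part$group == "far")), 1)
})

test_that("fold-change ranking is antisymmetric with exact doubling", {
  x <- matrix(c(2, 4, 2, 4, 1, 2, 1, 2), nrow = 2,
              dimnames = list(c("gA", "gB"), paste0("c", 1:4)))
  groups <- c("close", "close", "far", "far")
  r <- rank_genes_by_fold_change(x, groups, pseudocount = 0, min_cells = 2)
  expect_equal(r$log2fc[r$gene == "gA"], 1)
  expect_equal(r$log2fc[r$gene == "gB"], 1)
  swapped <- rank_genes_by_fold_change(x, ifelse(groups == "close", "far", "close"),
                                       pseudocount = 0, min_cells = 2)
  expect_equal(swapped$log2fc[order(swapped$gene)],
               -r$log2fc[order(r$gene)])
  identical_groups <- rank_genes_by_fold_change(cbind(x, x)[, c(1, 2, 1, 2) + c(0, 0, 4, 4)],
                                                groups, min_cells = 2)
  expect_true(all(identical_groups$log2fc == 0))
  expect_warning(out <- rank_genes_by_fold_change(x, groups, min_cells = 10),
                 "fewer than")
  expect_null(out)
  f <- tempfile()
  write_ranked_list(r, f)
  expect_length(readLines(f), 2L)
})

test_that("retention index is exact on self and null under permutation", {
  set.seed(31)
  q <- matrix(rnorm(40 * 30), 40)
  expect_equal(retention_index(q, q), 1, tolerance = 1e-12)
  noisy <- q + matrix(rnorm(length(q), sd = 0.2), nrow(q))
  expect_gt(retention_index(q, noisy), 0.8)
  expect_error(retention_index(q, q[, 1:10]), "same ordered")
})

test_that("balanced subsampling drops scarce types", {
  ann <- data.frame(cell_id = paste0("c", 1:30),
                    cell_type = rep(c("A", "B", "C"), c(15, 10, 5)))
  ids <- subsample_per_type(ann, n = 10, seed = 1)
  expect_length(ids, 20L)
  got <- table(ann$cell_type[match(ids, ann$cell_id)])
  expect_identical(as.integer(got), c(10L, 10L))
})
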