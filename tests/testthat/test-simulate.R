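test_that("atlas generation is seeded, typed and marker-structured", {
  a1 <- generate_atlas(3, 100, 20, seed = 4)
  a2 <- generate_atlas(3, 100, 20, seed = 4)
  expect_identical(unclass(a1$expr)[, ], unclass(a2$expr)[, ])
  expect_identical(dim(a1$expr), c(100L, 60L))
  # marker genes of a type are higher inside that type
  x <- unclass(a1$expr)
  for (t in names(a1$markers)) {
    inside <- a1$annotation$cell_type == t
    mk <- a1$markers[[t]]
    expect_gt(mean(x[mk, inside]), 2 * mean(x[mk, !inside]))
  }
})

test_that("effect size 1 removes type structure in expectation", {
  a <- generate_atlas(2, 400, 50, effect_size = 1, seed = 6)
  x <- unclass(a$expr)
  inside <- a$annotation$cell_type == "typeA"
  expect_equal(mean(x[, inside]), mean(x[, !inside]), tolerance = 0.05)
})

test_that("pooling conserves counts and hits the target occupancy", {
  a <- generate_atlas(4, 80, 25, seed = 2)
  tis <- lay_out_and_pool(a$expr, a$annotation, "blocks",
                          target_mean_cells_per_spot = 5, seed = 2)
  expect_equal(sum(tis$spot_counts), sum(a$expr))
  occupancy <- ncol(a$expr) / ncol(tis$spot_counts)
  expect_lt(abs(occupancy - 5) / 5, 0.2)
  # every cell has exactly one truth spot; spot sums match memberships
  expect_setequal(names(tis$truth), colnames(a$expr))
  s <- colnames(tis$spot_counts)[1]
  members <- names(tis$truth)[tis$truth == s]
  expect_equal(unname(unclass(tis$spot_counts)[, s]),
               unname(rowSums(unclass(a$expr)[, members, drop = FALSE])))
})

test_that("blocks layout concentrates each type spatially", {
  a <- generate_atlas(4, 50, 30, seed = 3)
  tis <- lay_out_and_pool(a$expr, a$annotation, "blocks", 5, seed = 3)
  pos <- tis$positions
  type_of <- a$annotation$cell_type[match(pos$cell_id, a$annotation$cell_id)]
  global_sd <- stats::sd(pos$x)
  for (t in unique(type_of))
    expect_lt(stats::sd(pos$x[type_of == t]), global_sd)
})

test_that("within-type permutation swaps the documented number of genes", {
  a <- generate_atlas(2, 100, 10, seed = 8)
  out <- permute_within_type(a$expr, a$annotation, fraction = 0.2, seed = 1)
  expect_identical(dim(out), dim(a$expr))
  n_diff <- colSums(unclass(out) != unclass(a$expr))
  expect_true(all(n_diff <= 20))
  expect_gt(mean(n_diff), 5)  # donors differ at most selected genes
  # fraction 0 is the identity
  expect_identical(unclass(permute_within_type(a$expr, a$annotation, 0, 1))[, ],
                   unclass(a$expr)[, ])
})

test_that("a single-cell type is left unchanged with a warning", {
  m <- toy_counts(c(1, 2, 3, 4, 5, 6, 7, 8, 9), nrow = 3,
                  cells = c("c1", "c2", "c3"))
  ann <- data.frame(cell_id = c("c1", "c2", "c3"),
                    cell_type = c("T", "T", "B"))
  expect_warning(out <- permute_within_type(m, ann, 0.5, 1), "single cell")
  expect_identical(unclass(out)[, "c3"], unclass(m)[, "c3"])
})

test_that("expression noise is multiplicative with median factor ~1", {
  a <- generate_atlas(2, 500, 10, seed = 9)
  noised <- add_expression_noise(a$expr, p = 0.25, seed = 2)
  x0 <- unclass(a$expr); x1 <- unclass(noised)
  changed <- x0 != x1
  frac_changed <- colMeans(changed)
  # at most a quarter can change (zeros stay zero under multiplication)
  expect_true(all(frac_changed <= 0.25 + 1e-9))
  mult <- (x1 / x0)[changed & x0 > 0]
  expect_equal(stats::median(mult), 1, tolerance = 0.1)
  expect_identical(unclass(add_expression_noise(a$expr, 0, 1))[, ], x0[, ])
  # p = 1 on a constant positive matrix changes everything a.s.
  cm <- expr_matrix(matrix(3, 20, 4, dimnames = list(paste0("g", 1:20),
                                                     paste0("c", 1:4))),
                    layer = "raw")
  expect_true(all(unclass(add_expression_noise(cm, 1, 3)) != 3))
  expect_error(add_expression_noise(a$expr, 1.2, 1), "\\[0, 1\\]")
})

test_that("fraction perturbation follows its noise law", {
  expect_equal(spotalign:::fraction_sigma(1), 0.5)
  expect_equal(spotalign:::fraction_sigma(1 / 8), 1)
  f <- c(a = 0.5, b = 0.3, c = 0.15, d = 0.05)
  out <- perturb_fractions(f, seed = 1)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  mult <- attr(out, "multipliers")
  expect_true(all(mult >= 0.25 & mult <= 4))
  # zero fractions pass through
  fz <- c(a = 0.6, b = 0.4, z = 0)
  expect_equal(unname(perturb_fractions(fz, 3)[["z"]]), 0)
})

test_that("count perturbation stays integer inside its bounds", {
  expect_equal(spotalign:::count_sigma(8, 1.4), 0.7)
  sm <- spot_model(paste0("s", 1:50), rep(c(1L, 5L, 9L, 14L, 20L), 10))
  out <- perturb_cell_counts(sm, p = 1.4, seed = 5)
  expect_true(all(out$n >= 1))
  expect_true(all(out$n <= ceiling(1.1 * max(sm$n))))
  expect_type(out$n, "integer")
  # stronger tuning degrades rank agreement with the original counts
  r <- sapply(c(1.4, 3.7), function(p) {
    mean(sapply(1:10, function(s)
      stats::cor(sm$n, perturb_cell_counts(sm, p, seed = s)$n,
                 method = "spearman")))
  })
  expect_gt(r[1], r[2])
})

test_that("same-type correlation matching picks the best column", {
  a <- generate_atlas(2, 60, 5, seed = 12)
  # target = a noisy copy of the atlas; each column should match itself
  noisy <- add_expression_noise(a$expr, 0.05, seed = 1)
  tgt <- expr_matrix(unclass(noisy), column_ids = paste0("t_", colnames(noisy)),
                     layer = "raw")
  tann <- data.frame(cell_id = colnames(tgt), cell_type = a$annotation$cell_type)
  hit <- match_by_correlation(tgt, tann, a$expr, a$annotation)
  expect_gt(mean(hit == colnames(a$expr)), 0.9)
})

test_that("simulated tissues round-trip through the on-disk format", {
  tis <- simulate_tissue(n_types = 3, n_genes = 50, cells_per_type = 15,
                         noise_p = 0.05, seed = 21)
  dir <- tempfile()
  write_tissue(tis, dir)
  st <- read_expression(file.path(dir, "st.tsv"), "tsv")
  expect_equal(unclass(st)[, ], unclass(tis$spot_counts)[, ])
  truth <- utils::read.table(file.path(dir, "truth.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  expect_identical(stats::setNames(truth$spot_id, truth$cell_id)[names(tis$truth)],
                   tis$truth)
  fr <- read_fractions(file.path(dir, "fractions.tsv"))
  expect_equal(sum(fr), 1, tolerance = 1e-9)
})
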