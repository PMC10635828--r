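test_that("the diagonal toy maps every cell to its own spot", {
  toy <- diagonal_toy()
  fit <- map_cells(toy$sc, toy$ann, toy$st, toy$fractions,
                   cells_per_spot = toy$counts, seed = 1)
  pr <- precision(fit, toy$truth)
  expect_equal(pr$overall, 1.0)
  base <- baseline_argmax(toy$sc, toy$ann, toy$st)
  expect_equal(precision(base, toy$truth)$overall, 1.0)
})

test_that("mapping is invariant to spot column order", {
  toy <- diagonal_toy(n_cells = 12, seed = 13)
  fit1 <- map_cells(toy$sc, toy$ann, toy$st, toy$fractions,
                    cells_per_spot = toy$counts, seed = 2)
  perm <- sample(colnames(toy$st))
  st2 <- expr_matrix(unclass(toy$st)[, perm], layer = "raw")
  fit2 <- map_cells(toy$sc, toy$ann, st2, toy$fractions,
                    cells_per_spot = toy$counts, seed = 2)
  pairs1 <- with(fit1$table, sort(paste(query_cell_id, assigned_spot_id)))
  pairs2 <- with(fit2$table, sort(paste(query_cell_id, assigned_spot_id)))
  expect_identical(pairs1, pairs2)
})

test_that("a fixed seed reproduces the mapping bit-for-bit", {
  tis <- study_tissue(seed = 91, noise_p = 0.05)
  f1 <- map_tissue(tis, seed = 5)
  f2 <- map_tissue(tis, seed = 5)
  expect_identical(f1$table, f2$table)
  t1 <- tempfile(); t2 <- tempfile()
  write_mapping(f1$table, t1); write_mapping(f2$table, t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("mapping satisfies balance, census and provenance contracts", {
  tis <- study_tissue(seed = 17, noise_p = 0.05)
  fit <- map_tissue(tis, seed = 2)
  sm <- fit$spot_model
  expect_identical(sort(fit$table$sub_spot_index), seq_len(sm$L))
  expect_identical(sum(sm$n), sm$L)
  expect_identical(nrow(fit$table), sm$L)
  census <- table(fit$table$cell_type)
  for (k in names(fit$targets))
    expect_identical(as.integer(census[[k]]), as.integer(fit$targets[[k]]))
  per_spot <- table(fit$table$assigned_spot_id)
  expect_identical(as.integer(per_spot[sm$spot_ids]), as.integer(sm$n))
})

test_that("solver choice barely changes the mapping", {
  tis <- study_tissue(seed = 23)
  f_ex <- map_tissue(tis, seed = 1, solver = "exact")
  f_ap <- map_tissue(tis, seed = 1, solver = "integer")
  same <- mean(f_ex$table$assigned_spot_id == f_ap$table$assigned_spot_id)
  expect_gte(same, 0.99)
})

test_that("cellmap methods print, summarize and convert", {
  toy <- diagonal_toy(n_cells = 12, seed = 3)
  fit <- map_cells(toy$sc, toy$ann, toy$st, toy$fractions,
                   cells_per_spot = toy$counts, seed = 1)
  expect_output(print(fit), "balanced assignment")
  expect_output(print(summary(fit)), "cells per type")
  expect_s3_class(as.data.frame(fit), "data.frame")
  geo <- data.frame(spot_id = colnames(toy$st),
                    x = seq_len(ncol(toy$st)), y = 1)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit, geo))
})

test_that("single-bin binned mapping equals the unbinned pipeline", {
  toy <- diagonal_toy(n_cells = 18, seed = 19)
  unbinned <- map_cells(toy$sc, toy$ann, toy$st, toy$fractions,
                        cells_per_spot = toy$counts, seed = 4)
  binned <- map_cells_binned(toy$sc, toy$ann, toy$st, toy$fractions,
                             bin_size = 100, seed = 4)
  expect_equal(binned$n_bins, 1L)
  ord <- order(unbinned$table$sub_spot_index)
  ordb <- order(binned$table$sub_spot_index)
  expect_identical(unbinned$table$query_cell_id[ord],
                   binned$table$query_cell_id[ordb])
  expect_identical(unbinned$table$assigned_spot_id[ord],
                   binned$table$assigned_spot_id[ordb])
})

test_that("bins partition the ST cells exactly once", {
  toy <- diagonal_toy(n_cells = 24, seed = 29)
  binned <- map_cells_binned(toy$sc, toy$ann, toy$st, toy$fractions,
                             bin_size = 10, seed = 6)
  expect_equal(binned$n_bins, 3L)
  expect_setequal(binned$table$assigned_spot_id, colnames(toy$st))
  expect_identical(anyDuplicated(binned$table$sub_spot_index), 0L)
})

test_that("split-half mapping recovers matching cell types above chance", {
  a <- generate_atlas(n_types = 4, n_genes = 120, cells_per_type = 30, seed = 37)
  noised <- add_expression_noise(a$expr, 0.05, seed = 1)
  set.seed(44)
  half <- sample(ncol(a$expr), ncol(a$expr) / 2)
  query <- expr_matrix(unclass(noised)[, half], layer = "raw")
  ref <- expr_matrix(unclass(a$expr)[, -half], layer = "raw")
  q_ann <- a$annotation[match(colnames(query), a$annotation$cell_id), ]
  r_ann <- a$annotation[match(colnames(ref), a$annotation$cell_id), ]
  fit <- map_cells_binned(query, q_ann, ref, bin_size = 40, seed = 2)
  ref_type <- r_ann$cell_type[match(fit$table$assigned_spot_id, r_ann$cell_id)]
  agreement <- mean(fit$table$cell_type == ref_type)
  expect_gt(agreement, 1.5 / 4)  # well above the 1/4 chance level
})

test_that("the naive baseline ignores capacity", {
  g <- paste0("g", 1:4)
  sc <- expr_matrix(matrix(c(1, 2, 3, 4, 1.1, 2.1, 3.1, 4.1), 4,
                           dimnames = list(g, c("c1", "c2"))), layer = "raw")
  st <- expr_matrix(matrix(c(1, 2, 3, 4, 9, 2, 1, 7), 4,
                           dimnames = list(g, c("s1", "s2"))), layer = "raw")
  ann <- data.frame(cell_id = c("c1", "c2"), cell_type = "T")
  base <- baseline_argmax(sc, ann, st)
  expect_identical(base$assigned_spot_id, c("s1", "s1"))
})
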