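#' Build the cell-by-sub-spot cost matrix
#'
#' Entry `d[k, l]` is the dissimilarity between the expression profile of pool
#' cell `k` and sub-spot `l` over their (already intersected, identically
#' ordered) shared genes:
#'
#' * `neg_pearson` (default): `-cor(a_k, b_l)`, the negated Pearson
#'   correlation, so well-matched pairs are cheap;
#' * `neg_spearman`: Pearson on per-vector average-tie ranks, negated;
#' * `euclidean`: the Euclidean distance between the profiles.
#'
#' A zero-variance profile makes a correlation undefined; such entries are
#' set to 0 (neutral) so the solver never sees a non-finite cost.
#'
#' @param pool a `sampled_pool` (or genes x K `expr_matrix`).
#' @param subspots genes x L `expr_matrix` from [expand_subspots()].
#' @param metric one of `"neg_pearson"`, `"neg_spearman"`, `"euclidean"`.
#' @return An object of class `cost_matrix`: the K x L numeric matrix with a
#'   `metric` attribute.
#' @export
build_cost_matrix <- function(pool, subspots,
                              metric = c("neg_pearson", "neg_spearman", "euclidean")) {
  metric <- match.arg(metric)
  a <- if (inherits(pool, "sampled_pool")) unclass(pool$expr) else unclass(pool)
  b <- unclass(subspots)
  if (nrow(a) != nrow(b) || !identical(rownames(a), rownames(b)))
    stop("pool and sub-spots must share an identical gene ordering")
  if (nrow(a) < 2L) stop("need at least 2 shared genes")
  if (ncol(a) != ncol(b))
    stop("unbalanced problem: ", ncol(a), " cells vs ", ncol(b), " sub-spots")
  d <- switch(metric,
    neg_pearson = {
      cc <- suppressWarnings(stats::cor(a, b))
      cc[is.na(cc)] <- 0
      -cc
    },
    neg_spearman = {
      cc <- suppressWarnings(stats::cor(a, b, method = "spearman"))
      cc[is.na(cc)] <- 0
      -cc
    },
    euclidean = {
      sq <- outer(colSums(a^2), colSums(b^2), "+") - 2 * crossprod(a, b)
      sqrt(pmax(sq, 0))
    })
  d <- unname(as.matrix(d))
  structure(d, metric = metric, class = c("cost_matrix", "matrix", "array"))
}

new_assignment <- function(perm, cost, u, v, solver) {
  total <- sum(cost[cbind(seq_along(perm), perm)])
  structure(list(perm = as.integer(perm), total_cost = total,
                 u = u, v = v, solver = solver),
            class = "assignment")
}

#' @export
print.assignment <- function(x, ...) {
  cat(sprintf("assignment: %d cells <-> %d sub-spots, total cost %.6g (solver: %s)\n",
              length(x$perm), length(x$perm), x$total_cost, x$solver))
  invisible(x)
}

#' Solve the balanced assignment exactly
#'
#' Finds the permutation minimizing the total cost by shortest augmenting
#' paths (Jonker-Volgenant family, `O(L^3)`), returning the optimal
#' permutation together with dual potentials `u`, `v` that certify
#' optimality: every reduced cost `d[k,l] - u[k] - v[l]` is nonnegative (to
#' within `eps = 1e-8 * max|d|`), matched edges have zero reduced cost, and
#' `sum(u) + sum(v)` equals the total cost (strong duality).
#'
#' @param cost a square [build_cost_matrix()] result (or plain matrix).
#' @return An object of class `assignment`: `perm` (row k -> column
#'   `perm[k]`), `total_cost`, `u`, `v`, `solver`.
#' @export
solve_exact <- function(cost) {
  cost <- as.matrix(cost)
  if (nrow(cost) != ncol(cost)) stop("cost matrix must be balanced (square)")
  if (any(!is.finite(cost))) stop("non-finite cost entries")
  r <- lap_solve_cpp(unclass(cost))
  new_assignment(r$perm, cost, r$u, r$v, "jv_exact")
}

#' Solve on integer-rounded costs
#'
#' Rounds every cost to the nearest multiple of `1/scale` and solves that
#' integer problem exactly; mirrors integer-programming approximations in
#' which exact costs are converted to integers with some loss of numerical
#' precision. The reported `total_cost` is evaluated on the *original* real
#' costs, so it is directly comparable with [solve_exact()]; the returned
#' duals certify the rounded problem (rescaled back).
#'
#' @param cost square cost matrix.
#' @param scale positive integer; default `1e6`.
#' @return an `assignment` with `solver = "integer_approx"`.
#' @export
solve_integer_approx <- function(cost, scale = 1e6) {
  cost <- as.matrix(cost)
  if (nrow(cost) != ncol(cost)) stop("cost matrix must be balanced (square)")
  if (any(!is.finite(cost))) stop("non-finite cost entries")
  stopifnot(scale >= 1)
  if (max(abs(cost)) * scale >= 2^53)
    stop("integer scale overflows exact integer range")
  ic <- round(unclass(cost) * scale)
  r <- lap_solve_cpp(ic)
  new_assignment(r$perm, cost, r$u / scale, r$v / scale, "integer_approx")
}

#' Exhaustive assignment oracle
#'
#' Enumerates all `K!` permutations (K <= 8) and returns the minimum-cost
#' one; on cost ties the lexicographically first permutation wins. Intended
#' as an independent test oracle for the polynomial solvers.
#'
#' @param cost square cost matrix, at most 8 x 8.
#' @return an `assignment` with `solver = "brute_force"` (duals are `NA`).
#' @export
solve_bruteforce <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (n != ncol(cost)) stop("cost matrix must be balanced (square)")
  if (n > 8L) stop("brute force limited to K <= 8")
  perms <- all_perms(n)               # already in lexicographic order
  costs <- perms                      # reuse dims
  total <- rowSums(matrix(cost[cbind(rep(seq_len(n), each = nrow(perms)),
                                     as.vector(perms))],
                          nrow = nrow(perms)))
  best <- which.min(total)            # which.min takes the first minimum
  new_assignment(perms[best, ], cost, rep(NA_real_, n), rep(NA_real_, n),
                 "brute_force")
}

# All permutations of 1..n, rows in lexicographic order.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    rest <- setdiff(seq_len(n), i)
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(rest[sub], nrow(sub))
  }
  out
}

# Check the dual certificate of an exact assignment against its cost matrix.
# Returns a list with the worst reduced cost, the worst slack on matched
# edges, and the duality gap.
dual_certificate <- function(assign, cost) {
  cost <- as.matrix(cost)
  red <- unclass(cost) - outer(assign$u, assign$v, "+")
  list(min_reduced = min(red),
       max_matched_slack = max(abs(red[cbind(seq_along(assign$perm), assign$perm)])),
       duality_gap = sum(assign$u) + sum(assign$v) - assign$total_cost,
       eps = 1e-8 * max(abs(cost)))
}
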