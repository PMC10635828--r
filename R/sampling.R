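#' Resample single cells to match per-type targets
#'
#' Builds the pool of `K = sum(targets)` query cells the solver will place,
#' exactly matching the integer per-type targets. Two schemes fill a
#' shortfall (`num_sc,k < num_ST,k`):
#'
#' * **duplication** (`sample_duplication()`): every available cell of the
#'   type is retained and the shortfall is drawn uniformly with replacement
#'   from those same cells. The default for real data, so every mapped
#'   profile is a measured cell.
#' * **generation** (`sample_generation()`): shortfall cells are synthesized
#'   gene by gene, each gene's value copied from a uniformly chosen cell of
#'   the same type, independently across genes. Used for benchmarking so
#'   duplicated cells cannot inflate precision; generated cells carry no
#'   ground-truth location and are excluded from precision scoring.
#'
#' When a type has at least as many cells as its target, both schemes draw
#' the target uniformly without replacement. Each cell type uses its own
#' RNG stream derived from `seed`, so draws for one type are unaffected by
#' the presence of others.
#'
#' @param sc [expr_matrix()] of single cells (any layer; the pool inherits it).
#' @param ann annotation data.frame `(cell_id, cell_type)` covering `sc`.
#' @param targets named integer vector from [type_targets_from_fractions()].
#' @param seed integer master seed.
#' @return An object of class `sampled_pool`: list with `expr` (genes x K
#'   `expr_matrix`, columns ordered by type then source id), `cell_type`,
#'   `provenance` (`original`/`duplicated`/`generated`), `source_cell_id`
#'   (`NA` for generated), `seed`.
#' @export
sample_duplication <- function(sc, ann, targets, seed) {
  sample_pool(sc, ann, targets, seed, scheme = "duplication")
}

#' @rdname sample_duplication
#' @export
sample_generation <- function(sc, ann, targets, seed) {
  sample_pool(sc, ann, targets, seed, scheme = "generation")
}

sample_pool <- function(sc, ann, targets, seed,
                        scheme = c("duplication", "generation")) {
  scheme <- match.arg(scheme)
  stopifnot(!is.null(names(targets)))
  ann <- ann[match(colnames(sc), ann$cell_id, nomatch = 0L), , drop = FALSE]
  types <- sort(names(targets)[targets > 0])
  missing <- types[!types %in% ann$cell_type]
  if (length(missing))
    stop("cell type(s) with positive target absent from scRNA-seq data: ",
         paste(missing, collapse = ", "))

  cols <- list(); ctype <- list(); prov <- list(); src <- list()
  vals <- unclass(sc)
  for (k in types) {
    avail <- sort(ann$cell_id[ann$cell_type == k])
    nk <- length(avail)
    tk <- as.integer(targets[[k]])
    picked <- with_seed(derive_seed(seed, k), {
      if (nk >= tk) {
        list(ids = sort(sample_safe(avail, tk)), gen = 0L)
      } else if (scheme == "duplication") {
        extra <- sample_safe(avail, tk - nk, replace = TRUE)
        list(ids = c(avail, sort(extra)), gen = 0L)
      } else {
        shortfall <- tk - nk
        g <- nrow(vals)
        donor <- matrix(sample.int(nk, g * shortfall, replace = TRUE),
                        nrow = g, ncol = shortfall)
        gen_vals <- matrix(vals[, avail, drop = FALSE][cbind(rep(seq_len(g), shortfall),
                                                             as.vector(donor))],
                           nrow = g, ncol = shortfall)
        list(ids = avail, gen = shortfall, gen_vals = gen_vals)
      }
    })
    ids <- picked$ids
    block <- vals[, ids, drop = FALSE]
    n_orig <- min(nk, tk)
    pv <- c(rep("original", n_orig), rep("duplicated", length(ids) - n_orig))
    sid <- ids
    if (picked$gen > 0L) {
      block <- cbind(block, picked$gen_vals)
      pv <- c(pv, rep("generated", picked$gen))
      sid <- c(sid, rep(NA_character_, picked$gen))
      ids <- c(ids, paste0(k, "::gen", seq_len(picked$gen)))
    }
    cols[[k]] <- block
    ctype[[k]] <- rep(k, ncol(block))
    prov[[k]] <- pv
    src[[k]] <- sid
  }
  expr <- do.call(cbind, cols)
  ctype <- unlist(ctype, use.names = FALSE)
  prov <- unlist(prov, use.names = FALSE)
  src <- unlist(src, use.names = FALSE)
  query_id <- src
  # generated columns have no source id: name them <type>::gen<i>
  gen <- which(is.na(src))
  if (length(gen))
    query_id[gen] <- paste0(ctype[gen], "::gen",
                            stats::ave(gen, ctype[gen], FUN = seq_along))
  pool_ids <- paste0("pool", seq_len(ncol(expr)))
  colnames(expr) <- pool_ids
  structure(list(expr = expr_matrix(expr, layer = em_layer(sc)),
                 cell_type = ctype, provenance = prov,
                 source_cell_id = src, query_id = query_id,
                 pool_ids = pool_ids, seed = seed),
            class = "sampled_pool")
}

#' @export
print.sampled_pool <- function(x, ...) {
  cat(sprintf("sampled_pool: %d cells (%d original, %d duplicated, %d generated), %d types\n",
              ncol(x$expr), sum(x$provenance == "original"),
              sum(x$provenance == "duplicated"), sum(x$provenance == "generated"),
              length(unique(x$cell_type))))
  invisible(x)
}
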