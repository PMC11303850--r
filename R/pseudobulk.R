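#' Gaussian random-projection basis
#'
#' Draws a d x D matrix of i.i.d. standard normal entries used to project
#' D-dimensional cell count vectors onto d random directions.
#'
#' @param d number of projections (tree depth).
#' @param n_genes number of features D.
#' @param seed integer seed; the basis is the only stochastic element of
#'   pseudobulk construction.
#' @return list with `matrix` (d x D), `d` and `seed`.
#' @export
projection_basis <- function(d, n_genes, seed = 1L) {
  stopifnot(d >= 1L, n_genes >= 1L)
  R <- with_local_seed(seed, matrix(rnorm(d * n_genes), nrow = d))
  list(matrix = R, d = as.integer(d), seed = as.integer(seed))
}

#' Random projection of a count matrix
#'
#' Computes Q = R X without densifying X; columns are processed in chunks so
#' memory stays proportional to d x n plus one pass over the nonzeros.
#'
#' @param X genes x cells count matrix (sparse or dense).
#' @param basis a [projection_basis()] (or any list with a `matrix` element
#'   whose columns match the genes of `X`).
#' @param chunk_size number of cells per block.
#' @param log1p project log1p-transformed counts instead of raw counts.
#' @return dense d x n matrix Q.
#' @export
random_projection <- function(X, basis, chunk_size = 10000L, log1p = FALSE) {
  X <- as_count_matrix(X)
  R <- basis$matrix
  if (ncol(R) != nrow(X)) {
    stop("projection basis has ", ncol(R), " columns but X has ", nrow(X),
         " genes", call. = FALSE)
  }
  n <- ncol(X)
  Q <- matrix(0, nrow(R), n)
  for (idx in chunk_indices(n, chunk_size)) {
    Xc <- X[, idx, drop = FALSE]
    if (log1p) Xc@x <- log1p(Xc@x)
    Q[, idx] <- as.matrix(R %*% Xc)
  }
  dimnames(Q) <- list(NULL, colnames(X))
  Q
}

#' Orthogonalize and row-standardize projections
#'
#' Takes the economical SVD Q = U S V' and keeps the orthonormal rows of V'
#' (the singular-value scaling is immaterial once rows are standardized), with
#' signs fixed so the largest-magnitude entry of each right-singular vector is
#' positive. Each retained row is then standardized to mean 0 and population
#' standard deviation 1. Rows beyond the numerical rank of Q are zeroed with a
#' warning, as are zero-variance rows.
#'
#' @param Q d x n matrix of raw projections, d <= n.
#' @return d x n matrix with standardized, mutually orthogonal (pre-scaling)
#'   rows.
#' @export
orthogonalize_standardize <- function(Q) {
  d <- nrow(Q)
  n <- ncol(Q)
  if (d > n) stop("cannot build ", d, " orthogonal directions over ", n,
                  " cells (need d <= n)", call. = FALSE)
  sv <- svd(Q, nu = 0L, nv = d)
  Vt <- t(sv$v)
  tol <- max(sv$d) * max(d, n) * .Machine$double.eps
  keep <- sv$d > tol
  if (!all(keep)) {
    warning("projection matrix has rank ", sum(keep), " < ", d,
            "; trailing components zeroed", call. = FALSE)
    Vt[!keep, ] <- 0
  }
  # deterministic sign: largest-magnitude entry of each kept row positive
  for (k in which(keep)) {
    piv <- which.max(abs(Vt[k, ]))
    if (Vt[k, piv] < 0) Vt[k, ] <- -Vt[k, ]
  }
  standardize_rows(Vt)
}

standardize_rows <- function(M) {
  n <- ncol(M)
  mu <- rowMeans(M)
  ctr <- M - mu
  s <- sqrt(rowMeans(ctr^2))  # population SD
  flat <- s < 1e-12
  if (any(flat)) {
    warning(sum(flat), " constant projection row(s) set to zero",
            call. = FALSE)
    ctr[flat, ] <- 0
    s[flat] <- 1
  }
  ctr / s
}

#' Binary codes and leaf assignment
#'
#' A cell branches right (code 1) at level k when its standardized projection
#' is strictly positive; ties at exactly zero branch left. The d codes read as
#' a binary number give the leaf index in `[0, 2^d - 1]`.
#'
#' @param Qtilde d x n standardized projection matrix.
#' @return list with `B` (d x n 0/1 matrix) and `leaves` (integer vector,
#'   length n).
#' @export
binarize_and_assign <- function(Qtilde) {
  B <- (Qtilde > 0) + 0L
  pow <- 2^(seq_len(nrow(B)) - 1L)
  leaves <- as.integer(round(colSums(B * pow)))
  list(B = B, leaves = leaves)
}

#' Aggregate cells into pseudobulk samples
#'
#' Sums the count vectors of all cells assigned to the same leaf. Empty leaves
#' are dropped; total counts are conserved exactly.
#'
#' @param X genes x cells count matrix.
#' @param leaves integer leaf id per cell.
#' @return list with `Y` (genes x leaves, columns `pb_<leafid>`), `leaf_ids`,
#'   `assignment` (tibble cell/leaf) and `occupancy` (tibble leaf/n_cells).
#' @export
aggregate_pseudobulk <- function(X, leaves) {
  X <- as_count_matrix(X)
  n <- ncol(X)
  if (length(leaves) != n) stop("leaf vector length ", length(leaves),
                                " != number of cells ", n, call. = FALSE)
  ids <- sort(unique(leaves))
  grp <- match(leaves, ids)
  ind <- Matrix::sparseMatrix(i = seq_len(n), j = grp, x = 1,
                              dims = c(n, length(ids)))
  Y <- as.matrix(X %*% ind)
  colnames(Y) <- paste0("pb_", ids)
  rownames(Y) <- rownames(X)
  list(
    Y = Y,
    leaf_ids = as.integer(ids),
    assignment = tibble::tibble(cell = colnames(X), leaf = as.integer(leaves)),
    occupancy = tibble::tibble(leaf = as.integer(ids),
                               n_cells = as.integer(tabulate(grp, length(ids))))
  )
}

#' Depth-normalize pseudobulk columns
#'
#' Rescales every column to a total of 10^4 so pseudobulk samples share a
#' uniform sequencing depth.
#'
#' @param Y genes x leaves non-negative matrix.
#' @param target column total after scaling.
#' @return matrix of the same shape, every column summing to `target`.
#' @export
normalize_pseudobulk <- function(Y, target = 1e4) {
  tot <- colSums(Y)
  if (any(tot <= 0)) {
    stop("all-zero pseudobulk column(s): ",
         paste(colnames(Y)[tot <= 0], collapse = ", "), call. = FALSE)
  }
  sweep(Y, 2L, tot / target, "/")
}

#' Build a normalized pseudobulk panel from a count matrix
#'
#' Runs the full first stage: random projection, SVD orthogonalization and
#' standardization, binary leaf assignment, aggregation and depth
#' normalization. Deterministic given `(X, depth, seed)`.
#'
#' @param X genes x cells count matrix.
#' @param depth tree depth d (at most `ceiling(log2)`-free: d <= n required).
#' @param seed integer seed for the Gaussian basis.
#' @param chunk_size cells per projection block.
#' @param log1p project log1p counts.
#' @param target depth-normalization total per pseudobulk column.
#' @return an object of class `asap_pseudobulk`: list with normalized `Y`,
#'   `Y_raw`, `leaf_ids`, `assignment`, `occupancy`, `depth`, `seed`.
#' @export
build_pseudobulk <- function(X, depth, seed = 1L, chunk_size = 10000L,
                             log1p = FALSE, target = 1e4) {
  X <- as_count_matrix(X)
  stopifnot(depth >= 1L)
  if (depth > ncol(X)) stop("depth ", depth, " exceeds number of cells ",
                            ncol(X), call. = FALSE)
  basis <- projection_basis(depth, nrow(X), seed)
  Q <- random_projection(X, basis, chunk_size = chunk_size, log1p = log1p)
  Qt <- orthogonalize_standardize(Q)
  codes <- binarize_and_assign(Qt)
  agg <- aggregate_pseudobulk(X, codes$leaves)
  res <- list(
    Y = normalize_pseudobulk(agg$Y, target = target),
    Y_raw = agg$Y,
    leaf_ids = agg$leaf_ids,
    assignment = agg$assignment,
    occupancy = agg$occupancy,
    depth = as.integer(depth),
    seed = as.integer(seed),
    target = target
  )
  class(res) <- "asap_pseudobulk"
  res
}

#' @export
print.asap_pseudobulk <- function(x, ...) {
  cat("Pseudobulk panel: ", nrow(x$Y), " genes x ", ncol(x$Y),
      " samples (depth ", x$depth, ", capacity ", 2^x$depth, ")\n", sep = "")
  cat("Cells assigned: ", nrow(x$assignment), "; occupied leaves: ",
      length(x$leaf_ids), "\n", sep = "")
  invisible(x)
}

#' @rdname build_pseudobulk
#' @param x an `asap_pseudobulk` object.
#' @param ... unused.
#' @method tidy asap_pseudobulk
#' @export
tidy.asap_pseudobulk <- function(x, ...) {
  dplyr::left_join(x$assignment, x$occupancy, by = "leaf")
}

#' Pseudobulk occupancy plot
#'
#' Bar chart of the number of cells landing in each occupied leaf.
#'
#' @param object an `asap_pseudobulk` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot asap_pseudobulk
#' @export
autoplot.asap_pseudobulk <- function(object, ...) {
  ggplot2::ggplot(object$occupancy,
                  ggplot2::aes(x = factor(.data$leaf), y = .data$n_cells)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "leaf", y = "cells",
                  title = "Pseudobulk leaf occupancy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

# Internal helpers ------------------------------------------------------

chunk_indices <- function(n, chunk_size) {
  chunk_size <- max(1L, as.integer(chunk_size))
  starts <- seq.int(1L, n, by = chunk_size)
  lapply(starts, function(s) s:min(n, s + chunk_size - 1L))
}

# run expr under a temporary RNG state so callers' streams are untouched
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
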