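#' Topic responsibilities of a cell
#'
#' The per-cell topic weight is the softmax over topics of the
#' depth-averaged dictionary log-score plus the current loading mean-log:
#' `log rho_k = sum_i(Y_ij Elog_beta_ik) / sum_i(Y_ij) + Elog_theta_k`.
#' The division by the cell's total count is applied exactly as stated by the
#' update; set `scale_data_term = FALSE` for the unscaled variant.
#'
#' @param x_col non-negative count vector (length D) with positive total.
#' @param Elog_beta D x K dictionary mean-log matrix.
#' @param Elog_theta_row length-K loading mean-log vector.
#' @param scale_data_term divide the data term by the total count (default).
#' @return length-K probability vector.
#' @export
responsibilities <- function(x_col, Elog_beta, Elog_theta_row,
                             scale_data_term = TRUE) {
  tot <- sum(x_col)
  if (tot <= 0) stop("cell has zero total count", call. = FALSE)
  data_term <- drop(crossprod(x_col, Elog_beta))
  if (scale_data_term) data_term <- data_term / tot
  softmax(data_term + Elog_theta_row)
}

softmax <- function(w) {
  w <- w - max(w)
  e <- exp(w)
  e / sum(e)
}

#' Per-cell conjugate loading update
#'
#' Given responsibilities, the cell's loading posterior over topic k is
#' `Gamma(a0 + rho_k * c, b0 + sum_i Ebeta_ik)` where `c` is the cell's total
#' count.
#'
#' @param rho length-K probability vector.
#' @param total_count positive scalar `c`.
#' @param Ebeta_colsums length-K vector of dictionary column sums.
#' @param a0,b0 prior shape and rate.
#' @return list with `shape` and `rate` (length-K vectors).
#' @export
update_theta_cell <- function(rho, total_count, Ebeta_colsums, a0 = 1, b0 = 1) {
  if (total_count <= 0) stop("cell has zero total count", call. = FALSE)
  list(shape = a0 + rho * total_count, rate = b0 + Ebeta_colsums)
}

#' Regress cells onto a fixed topic dictionary
#'
#' Recovers per-cell topic loadings with the dictionary held fixed: each cell
#' independently alternates the responsibility softmax with the conjugate
#' loading update for `n_iter` rounds, starting from a flat loading mean-log
#' so the first responsibilities are purely dictionary-driven. Cells are
#' independent, so chunking and ordering cannot change the result.
#'
#' Zero-count cells are dropped with a warning and listed in the result.
#'
#' @param X genes x cells count matrix; gene order must match the model.
#' @param model an `asap_pmf` fitted model (dictionary provider).
#' @param n_iter rounds of responsibility/loading alternation.
#' @param chunk_size cells per processing block.
#' @param scale_data_term see [responsibilities()].
#' @return object of class `asap_theta`: list with `theta`
#'   (`gamma_posterior`, cells x topics), `proportions` (tibble: cell id plus
#'   one column per topic, rows summing to 1), `rho` (responsibility matrix),
#'   `dropped` (zero-count cell ids).
#' @export
regress_cells <- function(X, model, n_iter = 10L, chunk_size = 10000L,
                          scale_data_term = TRUE) {
  X <- as_count_matrix(X)
  if (!is.null(model$genes) && !identical(rownames(X), model$genes)) {
    stop("gene order of X does not match the fitted dictionary", call. = FALSE)
  }
  if (nrow(X) != nrow(model$beta$shape)) {
    stop("X has ", nrow(X), " genes; dictionary has ",
         nrow(model$beta$shape), call. = FALSE)
  }
  tot <- Matrix::colSums(X)
  dropped <- colnames(X)[tot <= 0]
  if (length(dropped)) {
    warning(length(dropped), " zero-count cell(s) dropped", call. = FALSE)
    X <- X[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  n <- ncol(X)
  if (n == 0L) stop("no cells with positive counts", call. = FALSE)
  K <- model$K
  elog_b <- gamma_mean_log(model$beta)
  eb_colsums <- colSums(gamma_mean(model$beta))
  a0 <- model$a0
  b0 <- model$b0

  shape <- matrix(NA_real_, n, K)
  rho_all <- matrix(NA_real_, n, K)
  rate_row <- b0 + eb_colsums
  for (idx in chunk_indices(n, chunk_size)) {
    Xc <- X[, idx, drop = FALSE]
    # data term: (t(Xc) %*% Elog_beta) / total, fixed across iterations
    dt <- as.matrix(Matrix::crossprod(Xc, elog_b))
    if (scale_data_term) dt <- dt / tot[idx]
    elog_t <- matrix(0, length(idx), K)
    rho <- NULL
    for (iter in seq_len(n_iter)) {
      rho <- row_softmax(dt + elog_t)
      sh <- a0 + rho * tot[idx]
      elog_t <- digamma(sh) - matrix(log(rate_row), length(idx), K,
                                     byrow = TRUE)
    }
    shape[idx, ] <- a0 + rho * tot[idx]
    rho_all[idx, ] <- rho
  }
  rate <- matrix(rate_row, n, K, byrow = TRUE)
  theta <- gamma_posterior(shape, rate)
  prop <- shape / rate
  prop <- prop / rowSums(prop)
  colnames(prop) <- paste0("topic_", seq_len(K))
  colnames(rho_all) <- paste0("topic_", seq_len(K))
  structure(
    list(theta = theta,
         proportions = dplyr::bind_cols(tibble::tibble(cell = colnames(X)),
                                        tibble::as_tibble(prop)),
         rho = rho_all,
         cells = colnames(X),
         dropped = dropped,
         K = K),
    class = "asap_theta")
}

row_softmax <- function(W) {
  W <- W - apply(W, 1L, max)
  E <- exp(W)
  E / rowSums(E)
}

#' @export
print.asap_theta <- function(x, ...) {
  cat("Topic loadings for ", length(x$cells), " samples x ", x$K,
      " topics\n", sep = "")
  if (length(x$dropped)) cat(length(x$dropped), "zero-count samples dropped\n")
  invisible(x)
}

#' @method tidy asap_theta
#' @export
tidy.asap_theta <- function(x, ...) {
  tidyr::pivot_longer(x$proportions, -"cell", names_to = "topic",
                      names_prefix = "topic_", values_to = "proportion")
}

#' Topic-proportion structure plot
#'
#' Stacked per-sample topic proportions, the usual way grade-of-membership
#' fits are displayed.
#'
#' @param object an `asap_theta` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot asap_theta
#' @export
autoplot.asap_theta <- function(object, ...) {
  df <- tidy(object)
  df$cell <- factor(df$cell, levels = object$cells)
  ggplot2::ggplot(df, ggplot2::aes(.data$cell, .data$proportion,
                                   fill = .data$topic)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "topic proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Extract the proportions matrix of an `asap_theta`
#'
#' @param x an `asap_theta` object.
#' @return numeric matrix, samples x topics, rows summing to 1.
#' @export
proportions_matrix <- function(x) {
  m <- as.matrix(x$proportions[, -1L, drop = FALSE])
  rownames(m) <- x$proportions$cell
  m
}

#' Project bulk samples onto the topic dictionary
#'
#' Intersects the bulk gene universe with the model's, reorders to the model
#' order (dropping absent genes with a message), depth-normalizes every bulk
#' column to `target` so the dictionary's scale assumptions match the
#' pseudobulk convention, and runs the same fixed-dictionary regression as
#' [regress_cells()].
#'
#' @param B non-negative genes x samples bulk matrix with gene rownames.
#' @param model an `asap_pmf` fitted model.
#' @param n_iter,scale_data_term passed to [regress_cells()].
#' @param target per-column total after depth normalization.
#' @return an `asap_theta` object.
#' @export
project_bulk <- function(B, model, n_iter = 10L, target = 1e4,
                         scale_data_term = TRUE) {
  B <- as.matrix(B)
  genes <- model$genes
  if (is.null(genes)) genes <- rownames(B)
  common <- intersect(genes, rownames(B))
  if (length(common) == 0L) stop("no genes shared with the model", call. = FALSE)
  n_drop <- nrow(B) - length(common)
  if (n_drop > 0L) message(n_drop, " bulk genes absent from the model dropped")
  Bm <- matrix(0, length(genes), ncol(B),
               dimnames = list(genes, colnames(B)))
  Bm[common, ] <- B[common, , drop = FALSE]
  tot <- colSums(Bm)
  if (any(tot <= 0)) stop("bulk sample(s) with no counts on model genes: ",
                          paste(colnames(Bm)[tot <= 0], collapse = ", "),
                          call. = FALSE)
  Bn <- sweep(Bm, 2L, tot / target, "/")
  regress_cells(Bn, model, n_iter = n_iter, scale_data_term = scale_data_term)
}

#' Deconvolve bulk samples by neighbour counting in topic space
#'
#' Each bulk sample's cell-type composition is estimated as the label
#' frequencies among its `k` nearest cells by Euclidean distance between
#' normalized topic-proportion vectors. Ties at the k-th distance are broken
#' by cell index order.
#'
#' @param theta_bulk `asap_theta` (or proportions matrix) for bulk samples.
#' @param theta_cells `asap_theta` (or proportions matrix) for cells.
#' @param labels cell-type label per cell.
#' @param k number of neighbours.
#' @return tibble: one row per (bulk sample, cell type) with `fraction`;
#'   fractions sum to 1 within each bulk sample.
#' @export
deconvolve_by_neighbors <- function(theta_bulk, theta_cells, labels, k = 100L) {
  Pb <- if (inherits(theta_bulk, "asap_theta")) proportions_matrix(theta_bulk) else as.matrix(theta_bulk)
  Pc <- if (inherits(theta_cells, "asap_theta")) proportions_matrix(theta_cells) else as.matrix(theta_cells)
  labels <- as.character(labels)
  if (length(labels) != nrow(Pc)) stop("labels length != number of cells",
                                       call. = FALSE)
  if (k > nrow(Pc)) stop("k = ", k, " exceeds number of cells ", nrow(Pc),
                         call. = FALSE)
  types <- sort(unique(labels))
  bulk_ids <- rownames(Pb)
  if (is.null(bulk_ids)) bulk_ids <- paste0("bulk", seq_len(nrow(Pb)))
  out <- lapply(seq_len(nrow(Pb)), function(s) {
    d2 <- colSums((t(Pc) - Pb[s, ])^2)
    nn <- order(d2)[seq_len(k)]  # order() is stable: ties broken by index
    freq <- table(factor(labels[nn], levels = types))
    tibble::tibble(sample = bulk_ids[s], cell_type = types,
                   fraction = as.numeric(freq) / k)
  })
  dplyr::bind_rows(out)
}
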