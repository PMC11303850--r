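#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected agreement between two partitions, computed
#' from the contingency table. Equals 1 for identical partitions (including
#' the degenerate single-cluster vs single-cluster case, where the raw index
#' is already maximal) and has expectation ~0 under independent random
#' partitions.
#'
#' @param a,b label vectors of equal length.
#' @return scalar in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  check_labelings(a, b)
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maximum <- (sum_a + sum_b) / 2
  if (abs(maximum - expected) < .Machine$double.eps) return(1)
  (sum_ij - expected) / (maximum - expected)
}

#' Normalized mutual information
#'
#' Mutual information between the two partitions normalized by the arithmetic
#' mean of their entropies (the Danon variant): `2 I(a;b) / (H(a) + H(b))`.
#' Lies in [0, 1]; equals 1 iff the partitions are identical up to
#' relabelling, and is defined as 1 when both partitions are trivial (a
#' single cluster each, zero entropy on both sides).
#'
#' @param a,b label vectors of equal length.
#' @return scalar in [0, 1].
#' @export
normalized_mutual_info <- function(a, b) {
  check_labelings(a, b)
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pa <- rowSums(pij)
  pb <- colSums(pij)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha + hb < .Machine$double.eps) return(1)
  outer_p <- outer(pa, pb)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer_p[nz]))
  2 * mi / (ha + hb)
}

#' Cluster purity
#'
#' Fraction of samples that belong to the majority truth class of their
#' cluster: `(1/n) sum_clusters max_type |cluster intersect type|`. Reaches 1
#' when every cluster is type-pure (trivially including the all-singletons
#' partition).
#'
#' @param clusters estimated labels.
#' @param truth reference labels.
#' @return scalar in (0, 1].
#' @export
purity <- function(clusters, truth) {
  check_labelings(clusters, truth)
  tab <- table(clusters, truth)
  sum(apply(tab, 1L, max)) / sum(tab)
}

check_labelings <- function(a, b) {
  if (length(a) != length(b)) {
    stop("labelings have different lengths (", length(a), " vs ", length(b),
         ")", call. = FALSE)
  }
  if (length(a) == 0L || anyNA(a) || anyNA(b)) {
    stop("labelings must be non-empty and free of missing values",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Score a partition against ground truth
#'
#' @param clusters estimated labels.
#' @param truth reference labels.
#' @return one-row tibble with `ari`, `nmi`, `purity`.
#' @export
score_clustering <- function(clusters, truth) {
  tibble::tibble(ari = adjusted_rand_index(clusters, truth),
                 nmi = normalized_mutual_info(clusters, truth),
                 purity = purity(clusters, truth))
}

#' Cluster samples in topic space
#'
#' Builds a k-nearest-neighbour graph (Euclidean distance on normalized topic
#' proportions, ties broken by sample index) and partitions it with Leiden
#' community detection via igraph at the given resolution (modularity
#' objective). A seeded k-means fallback (`method = "kmeans"`) is provided
#' for settings where a graph backend is unwanted; it requires `k`.
#'
#' @param theta an `asap_theta` object or a samples x topics matrix.
#' @param n_neighbors neighbours per sample in the graph.
#' @param method `"leiden"` or `"kmeans"`.
#' @param resolution Leiden resolution parameter.
#' @param k number of clusters for the k-means fallback.
#' @param seed integer seed (community detection and k-means both consume
#'   randomness).
#' @return integer cluster label vector, length n.
#' @export
cluster_topics <- function(theta, n_neighbors = 15L,
                           method = c("leiden", "kmeans"), resolution = 1,
                           k = NULL, seed = 1L) {
  P <- if (inherits(theta, "asap_theta")) proportions_matrix(theta) else as.matrix(theta)
  n <- nrow(P)
  if (n < n_neighbors + 1L) stop("need at least n_neighbors + 1 = ",
                                 n_neighbors + 1L, " samples", call. = FALSE)
  method <- match.arg(method)
  if (method == "kmeans") {
    if (is.null(k)) stop("k-means fallback requires k", call. = FALSE)
    km <- with_local_seed(seed, kmeans(P, centers = k, nstart = 10L))
    return(as.integer(km$cluster))
  }
  nn <- knn_indices(P, n_neighbors)
  edges <- cbind(rep(seq_len(n), each = n_neighbors), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- with_local_seed(seed, igraph::cluster_leiden(
    g, objective_function = "modularity", resolution = resolution,
    n_iterations = 5L))
  as.integer(igraph::membership(comm))
}

# k nearest neighbours (excluding self) by Euclidean distance, stable ties
knn_indices <- function(P, k, block = 1024L) {
  n <- nrow(P)
  sq <- rowSums(P^2)
  out <- matrix(0L, n, k)
  for (idx in chunk_indices(n, block)) {
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(P[idx, , drop = FALSE], P)
    for (r in seq_along(idx)) {
      d2[r, idx[r]] <- Inf  # drop self
      out[idx[r], ] <- order(d2[r, ])[seq_len(k)]
    }
  }
  out
}
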