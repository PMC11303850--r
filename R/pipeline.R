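#' Run the full three-step pipeline
#'
#' Pseudobulk construction, Gamma-Poisson factorization of the pseudobulk
#' panel, and fixed-dictionary regression of every cell. This is the
#' end-to-end path used by the benchmarks; each step is also exported on its
#' own.
#'
#' @param X genes x cells count matrix.
#' @param K number of topics.
#' @param depth random-projection tree depth.
#' @param seed integer seed (basis and dictionary initialization).
#' @param a0,b0 Gamma prior shape and rate.
#' @param max_iter,tol factorization stopping rule.
#' @param n_iter_regress per-cell regression rounds.
#' @param chunk_size cells per processing block.
#' @return list with `pseudobulk` (`asap_pseudobulk`), `model` (`asap_pmf`)
#'   and `theta` (`asap_theta` over the original cells).
#' @export
run_asap <- function(X, K, depth = 10L, seed = 1L, a0 = 1, b0 = 1,
                     max_iter = 100L, tol = 1e-6, n_iter_regress = 10L,
                     chunk_size = 10000L) {
  pb <- build_pseudobulk(X, depth = depth, seed = seed,
                         chunk_size = chunk_size)
  model <- fit_pmf(pb$Y, K = K, a0 = a0, b0 = b0, max_iter = max_iter,
                   tol = tol, seed = seed)
  theta <- regress_cells(X, model, n_iter = n_iter_regress,
                         chunk_size = chunk_size)
  list(pseudobulk = pb, model = model, theta = theta)
}
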