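#' Sufficient statistics of the auxiliary multinomial variables
#'
#' For every nonzero entry of `Y` the responsibilities over topics are the
#' softmax of `Elog_beta[i, ] + Elog_theta[j, ]`; the count-weighted sums over
#' genes and samples are accumulated without ever materializing the
#' D x L x K tensor (zeros of `Y` contribute nothing).
#'
#' @param Y non-negative genes x samples matrix (sparse or dense).
#' @param Elog_beta D x K matrix of dictionary mean-log moments.
#' @param Elog_theta L x K matrix of loading mean-log moments.
#' @return object of class `pmf_stats`: list with `s_theta` (L x K),
#'   `s_beta` (D x K) and `loglik` (the count-weighted log-normalizer term of
#'   the evidence lower bound).
#' @export
auxiliary_stats <- function(Y, Elog_beta, Elog_theta) {
  trip <- as_triplets(Y)
  Elog_beta <- as.matrix(Elog_beta)
  Elog_theta <- as.matrix(Elog_theta)
  if (anyNA(Elog_beta) || anyNA(Elog_theta)) {
    stop("NaN in mean-log moments", call. = FALSE)
  }
  if (nrow(Elog_beta) != trip$dim[1L] || nrow(Elog_theta) != trip$dim[2L] ||
      ncol(Elog_beta) != ncol(Elog_theta)) {
    stop("moment matrices do not match Y", call. = FALSE)
  }
  out <- .aux_stats_sparse(trip$i, trip$j, trip$x, Elog_beta, Elog_theta)
  structure(list(s_theta = out$s_theta, s_beta = out$s_beta,
                 loglik = out$loglik),
            class = "pmf_stats")
}

as_triplets <- function(Y) {
  if (inherits(Y, "sparseMatrix")) {
    T <- as(as(Y, "generalMatrix"), "TsparseMatrix")
    if (any(T@x < 0)) stop("Y must be non-negative", call. = FALSE)
    keep <- T@x != 0
    list(i = T@i[keep], j = T@j[keep], x = T@x[keep], dim = dim(Y))
  } else {
    Y <- as.matrix(Y)
    if (anyNA(Y)) stop("Y contains NA", call. = FALSE)
    if (any(Y < 0)) stop("Y must be non-negative", call. = FALSE)
    nz <- which(Y != 0)
    list(i = as.integer((nz - 1L) %% nrow(Y)),
         j = as.integer((nz - 1L) %/% nrow(Y)),
         x = as.double(Y[nz]), dim = dim(Y))
  }
}

#' Variational update of the sample loadings
#'
#' Conjugate Gamma update: `shape = a0 + S_theta`, `rate = b0 + colSums(Ebeta)`
#' shared across samples within each topic.
#'
#' @param stats a [auxiliary_stats()] result.
#' @param Ebeta D x K dictionary posterior means.
#' @param a0,b0 Gamma prior shape and rate.
#' @return `gamma_posterior` over samples x topics.
#' @export
update_theta <- function(stats, Ebeta, a0 = 1, b0 = 1) {
  stopifnot(a0 > 0, b0 > 0)
  shape <- a0 + stats$s_theta
  rate <- matrix(b0 + colSums(Ebeta), nrow(stats$s_theta),
                 ncol(stats$s_theta), byrow = TRUE)
  gamma_posterior(shape, rate)
}

#' Variational update of the dictionary
#'
#' Mirror image of [update_theta()]: `shape = a0 + S_beta`,
#' `rate = b0 + colSums(Etheta)` shared across genes within each topic.
#'
#' @param stats a [auxiliary_stats()] result.
#' @param Etheta L x K loading posterior means.
#' @param a0,b0 Gamma prior shape and rate.
#' @return `gamma_posterior` over genes x topics.
#' @export
update_beta <- function(stats, Etheta, a0 = 1, b0 = 1) {
  stopifnot(a0 > 0, b0 > 0)
  shape <- a0 + stats$s_beta
  rate <- matrix(b0 + colSums(Etheta), nrow(stats$s_beta),
                 ncol(stats$s_beta), byrow = TRUE)
  gamma_posterior(shape, rate)
}

#' Evidence lower bound of the Gamma-Poisson factorization
#'
#' Computed up to the additive constant `-sum(lgamma(Y + 1))` (independent of
#' all variational parameters). The data term uses the log-normalizer
#' accumulated by [auxiliary_stats()]; the Poisson rate term and the Gamma
#' prior/entropy terms are added in closed form.
#'
#' @param stats a [auxiliary_stats()] result for the current moments.
#' @param beta,theta `gamma_posterior` objects.
#' @param a0,b0 prior shape and rate.
#' @return scalar ELBO (up to a constant).
#' @export
pmf_elbo <- function(stats, beta, theta, a0 = 1, b0 = 1) {
  eb <- gamma_mean(beta)
  et <- gamma_mean(theta)
  rate_term <- sum(colSums(eb) * colSums(et))
  stats$loglik - rate_term +
    gamma_prior_elbo(beta, a0, b0) + gamma_prior_elbo(theta, a0, b0)
}

#' Fit the Gamma-Poisson topic model by mean-field variational inference
#'
#' Alternates the auxiliary softmax statistics with the conjugate updates of
#' the loadings and the dictionary until the relative change of the evidence
#' lower bound falls below `tol` or `max_iter` is reached. The dictionary
#' shapes are initialized with small seeded uniform noise; loading shapes are
#' initialized flat so inference is equivariant under sample permutation.
#'
#' @param Y non-negative genes x samples matrix (a pseudobulk panel, or a
#'   full count matrix for the unapproximated variant).
#' @param K number of topics.
#' @param a0,b0 Gamma prior shape and rate.
#' @param max_iter iteration cap.
#' @param tol relative ELBO change declaring convergence.
#' @param seed integer seed for the dictionary initialization.
#' @param init optional list with `beta` and `theta` `gamma_posterior`
#'   objects to start from (replaces the seeded default).
#' @param verbose print the ELBO every 10 iterations.
#' @return object of class `asap_pmf`: list with `beta` and `theta`
#'   (`gamma_posterior`), `K`, `a0`, `b0`, `elbo_trace`, `seed`, `genes`,
#'   `samples`, `converged`, `n_iter`.
#' @export
fit_pmf <- function(Y, K, a0 = 1, b0 = 1, max_iter = 500L, tol = 1e-6,
                    seed = 1L, init = NULL, verbose = FALSE) {
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (is.null(dim(Y)) || nrow(Y) == 0L || ncol(Y) == 0L) {
    stop("Y must be a non-empty matrix", call. = FALSE)
  }
  D <- nrow(Y)
  L <- ncol(Y)
  if (K > min(D, L)) warning("K = ", K, " exceeds min(dim(Y)) = ", min(D, L),
                             call. = FALSE)
  genes <- rownames(Y)
  samples <- colnames(Y)

  if (is.null(init)) {
    scale0 <- mean_nonzero(Y) / K
    beta <- gamma_posterior(
      shape = a0 + with_local_seed(seed, matrix(runif(D * K), D, K)) * 0.1,
      rate = matrix(b0 + 1 / max(scale0, 1e-8), D, K)
    )
    theta <- gamma_posterior(shape = matrix(a0, L, K),
                             rate = matrix(b0 + 1, L, K))
  } else {
    beta <- init$beta
    theta <- init$theta
    stopifnot(all(dim(beta) == c(D, K)), all(dim(theta) == c(L, K)))
  }

  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  stats <- NULL
  while (it < max_iter) {
    it <- it + 1L
    stats <- auxiliary_stats(Y, gamma_mean_log(beta), gamma_mean_log(theta))
    trace[it] <- pmf_elbo(stats, beta, theta, a0, b0)
    theta <- update_theta(stats, gamma_mean(beta), a0, b0)
    beta <- update_beta(stats, gamma_mean(theta), a0, b0)
    if (verbose && it %% 10L == 0L) {
      message("iter ", it, " elbo ", format(trace[it], digits = 10))
    }
    if (it > 1L) {
      delta <- abs(trace[it] - trace[it - 1L]) /
        max(abs(trace[it - 1L]), .Machine$double.eps)
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
  }
  model <- structure(
    list(beta = beta, K = as.integer(K), a0 = a0, b0 = b0,
         elbo_trace = trace, seed = as.integer(seed), genes = genes,
         samples = samples, converged = converged, n_iter = it),
    class = "asap_pmf")
  model$theta <- theta
  model
}

mean_nonzero <- function(Y) {
  if (inherits(Y, "sparseMatrix")) {
    if (length(Y@x)) mean(Y@x) else 1
  } else {
    nz <- Y[Y != 0]
    if (length(nz)) mean(nz) else 1
  }
}

#' Rescale factors onto the multinomial topic-model scale
#'
#' The Gamma-Poisson factors are identifiable only up to a per-topic scale.
#' This absorbs each topic's dictionary column total into the loadings, then
#' normalizes: dictionary columns sum to 1 (topic-specific gene frequencies)
#' and loading rows sum to 1 (per-sample topic proportions).
#'
#' @param beta_mean D x K non-negative matrix.
#' @param theta_mean n x K non-negative matrix.
#' @return list with `beta` (columns sum to 1) and `theta` (rows sum to 1).
#' @export
to_multinomial_scale <- function(beta_mean, theta_mean) {
  beta_mean <- as.matrix(beta_mean)
  theta_mean <- as.matrix(theta_mean)
  s <- colSums(beta_mean)
  if (any(s <= 0)) stop("all-zero dictionary column", call. = FALSE)
  beta_norm <- sweep(beta_mean, 2L, s, "/")
  theta_scaled <- sweep(theta_mean, 2L, s, "*")
  rs <- rowSums(theta_scaled)
  if (any(rs <= 0)) stop("all-zero loading row", call. = FALSE)
  list(beta = beta_norm, theta = theta_scaled / rs)
}

#' @export
print.asap_pmf <- function(x, ...) {
  cat("Gamma-Poisson topic model: ", nrow(x$beta$shape), " genes x ", x$K,
      " topics over ", nrow(x$theta$shape), " samples\n", sep = "")
  cat(if (x$converged) "Converged" else "Stopped", " after ", x$n_iter,
      " iterations; ELBO ", format(utils::tail(x$elbo_trace, 1L)), "\n",
      sep = "")
  invisible(x)
}

#' Tidy a fitted topic model
#'
#' Long tibble of the dictionary on the multinomial scale: one row per
#' (gene, topic) with the topic-specific gene frequency and the posterior
#' shape/rate.
#'
#' @param x an `asap_pmf` object.
#' @param ... unused.
#' @method tidy asap_pmf
#' @export
tidy.asap_pmf <- function(x, ...) {
  bn <- to_multinomial_scale(gamma_mean(x$beta), gamma_mean(x$theta))$beta
  genes <- if (!is.null(x$genes)) x$genes else paste0("g", seq_len(nrow(bn)))
  tibble::tibble(
    gene = rep(genes, times = x$K),
    topic = rep(seq_len(x$K), each = nrow(bn)),
    frequency = as.vector(bn),
    shape = as.vector(x$beta$shape),
    rate = as.vector(x$beta$rate)
  )
}

#' @rdname tidy.asap_pmf
#' @method glance asap_pmf
#' @export
glance.asap_pmf <- function(x, ...) {
  tibble::tibble(
    K = x$K, a0 = x$a0, b0 = x$b0,
    n_genes = nrow(x$beta$shape), n_samples = nrow(x$theta$shape),
    n_iter = x$n_iter, converged = x$converged,
    elbo = utils::tail(x$elbo_trace, 1L)
  )
}

#' ELBO trace plot
#'
#' @param object an `asap_pmf` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot asap_pmf
#' @export
autoplot.asap_pmf <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$elbo_trace),
                       elbo = object$elbo_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$elbo)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "evidence lower bound",
                  title = "Variational inference trace") +
    ggplot2::theme_minimal()
}
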