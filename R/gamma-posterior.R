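#' Element-wise Gamma variational posterior
#'
#' Container for a matrix of independent Gamma(shape, rate) distributions,
#' used both for the gene-by-topic dictionary and the sample-by-topic
#' loadings. Moments follow the standard identities mean = shape/rate and
#' E[log x] = digamma(shape) - log(rate).
#'
#' @param shape,rate positive matrices of equal dimension.
#' @return object of class `gamma_posterior`.
#' @export
gamma_posterior <- function(shape, rate) {
  shape <- as.matrix(shape)
  rate <- as.matrix(rate)
  stopifnot(all(dim(shape) == dim(rate)))
  if (any(shape <= 0) || any(rate <= 0)) {
    stop("Gamma posterior requires strictly positive shape and rate",
         call. = FALSE)
  }
  structure(list(shape = shape, rate = rate), class = "gamma_posterior")
}

#' @rdname gamma_posterior
#' @param q a `gamma_posterior`.
#' @export
gamma_mean <- function(q) q$shape / q$rate

#' @rdname gamma_posterior
#' @export
gamma_mean_log <- function(q) digamma(q$shape) - log(q$rate)

#' @export
print.gamma_posterior <- function(x, ...) {
  cat("Gamma posterior over a ", nrow(x$shape), " x ", ncol(x$shape),
      " matrix\n", sep = "")
  invisible(x)
}

#' @export
dim.gamma_posterior <- function(x) dim(x$shape)

# entropy + cross-entropy against a Gamma(a0, b0) prior, summed over elements
gamma_prior_elbo <- function(q, a0, b0) {
  a <- q$shape
  b <- q$rate
  elog <- digamma(a) - log(b)
  e <- a / b
  eplogp <- (a0 - 1) * elog - b0 * e + a0 * log(b0) - lgamma(a0)
  entropy <- a - log(b) + lgamma(a) + (1 - a) * digamma(a)
  sum(eplogp) + sum(entropy)
}
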