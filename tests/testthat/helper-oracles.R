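# Independent reference implementations used as oracles. Deliberately naive:
# dense loops, full tensors, textbook formulas -- nothing shared with the
# package's computational path.

# Full-tensor mean-field inference for the Gamma-Poisson factorization.
# Materializes z[i, j, k] explicitly and loops; returns posteriors and the
# ELBO trace evaluated the same way as the package (bound at the top of each
# iteration, before the updates).
naive_pmf <- function(Y, K, a0 = 1, b0 = 1, n_iter = 100L, init) {
  Y <- as.matrix(Y)
  D <- nrow(Y)
  L <- ncol(Y)
  bs <- init$beta$shape;  br <- init$beta$rate
  ts <- init$theta$shape; tr <- init$theta$rate
  elbo <- numeric(n_iter)
  for (iter in seq_len(n_iter)) {
    elb <- digamma(bs) - log(br)
    elt <- digamma(ts) - log(tr)
    z <- array(0, c(D, L, K))
    for (i in seq_len(D)) for (j in seq_len(L)) {
      w <- elb[i, ] + elt[j, ]
      w <- exp(w - max(w))
      z[i, j, ] <- w / sum(w)
    }
    # bound: E[log p(Y | lambda)] (+ log Y! const dropped) + prior - entropy
    eb <- bs / br
    et <- ts / tr
    acc <- 0
    for (i in seq_len(D)) for (j in seq_len(L)) for (k in seq_len(K)) {
      if (Y[i, j] > 0 && z[i, j, k] > 0) {
        acc <- acc + z[i, j, k] * Y[i, j] *
          (elb[i, k] + elt[j, k] - log(z[i, j, k]))
      }
    }
    acc <- acc - sum(tcrossprod(eb, et))
    gam <- function(s, r) {
      el <- digamma(s) - log(r)
      sum((a0 - 1) * el - b0 * s / r + a0 * log(b0) - lgamma(a0)) +
        sum(s - log(r) + lgamma(s) + (1 - s) * digamma(s))
    }
    elbo[iter] <- acc + gam(bs, br) + gam(ts, tr)
    # theta update, then beta update with refreshed theta means
    for (j in seq_len(L)) for (k in seq_len(K)) {
      ts[j, k] <- a0 + sum(Y[, j] * z[, j, k])
      tr[j, k] <- b0 + sum(bs[, k] / br[, k])
    }
    et <- ts / tr
    for (i in seq_len(D)) for (k in seq_len(K)) {
      bs[i, k] <- a0 + sum(Y[i, ] * z[i, , k])
      br[i, k] <- b0 + sum(et[, k])
    }
  }
  list(beta_shape = bs, beta_rate = br, theta_shape = ts, theta_rate = tr,
       elbo = elbo, lambda = tcrossprod(bs / br, ts / tr))
}

# shared random starting point for dual-route comparisons
pmf_init <- function(D, L, K, a0 = 1, b0 = 1, seed = 1) {
  set.seed(seed)
  list(beta = gamma_posterior(matrix(a0 + runif(D * K) * 0.1, D, K),
                              matrix(b0 + 0.5, D, K)),
       theta = gamma_posterior(matrix(a0 + runif(L * K) * 0.1, L, K),
                               matrix(b0 + 0.5, L, K)))
}

# Adjusted Rand index from raw pair concordance counts (quadratic loop),
# an algebraically different route than the contingency-table formula.
pair_counting_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (p in seq_len(n - 1)) for (q in (p + 1):n) {
    sa <- a[p] == a[q]
    sb <- b[p] == b[q]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# all set partitions of seq_len(n) as label vectors (restricted growth)
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (v in seq_len(max(labels) + 1L)) grow(c(labels, v))
  }
  grow(1L)
  out
}

# simulate from the generative model: beta, theta ~ Gamma(a0, b0),
# Y ~ Poisson(beta theta')
simulate_pmf_data <- function(D, L, K, a0 = 1, b0 = 1, seed = 1,
                              scale = 20) {
  set.seed(seed)
  beta <- matrix(rgamma(D * K, a0, b0), D, K)
  theta <- matrix(rgamma(L * K, a0, b0), L, K)
  lambda <- tcrossprod(beta, theta) * scale
  Y <- matrix(rpois(D * L, lambda), D, L)
  list(Y = Y, lambda = lambda, beta = beta, theta = theta)
}
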