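test_that("Gamma moment accessors match numerical integration", {
  grid <- expand.grid(a = c(0.5, 1, 2.5, 10), b = c(0.2, 1, 3))
  q <- gamma_posterior(matrix(grid$a), matrix(grid$b))
  m <- gamma_mean(q)
  ml <- gamma_mean_log(q)
  for (r in seq_len(nrow(grid))) {
    a <- grid$a[r]; b <- grid$b[r]
    num_mean <- integrate(function(x) x * dgamma(x, a, b), 0, Inf)$value
    num_mlog <- integrate(function(x) log(x) * dgamma(x, a, b), 0, Inf,
                          rel.tol = 1e-10)$value
    expect_equal(m[r, 1], num_mean, tolerance = 1e-6)
    expect_equal(ml[r, 1], num_mlog, tolerance = 1e-6)
  }
  expect_error(gamma_posterior(matrix(-1), matrix(1)), "positive")
})

test_that("auxiliary statistics distribute counts by softmax and conserve totals", {
  # K = 1: all mass on the single topic
  Y <- matrix(c(0, 2, 3, 1), 2, 2)
  s1 <- auxiliary_stats(Y, matrix(0, 2, 1), matrix(0, 2, 1))
  expect_equal(drop(s1$s_theta), colSums(Y))
  expect_equal(drop(s1$s_beta), rowSums(Y))

  # equal log-weights: each entry split Y/K
  s2 <- auxiliary_stats(Y, matrix(1, 2, 2), matrix(-0.5, 2, 2))
  expect_equal(s2$s_theta, cbind(colSums(Y) / 2, colSums(Y) / 2))

  # log-weights (log 1, log 3) with y = 4 contribute (1, 3)
  s3 <- auxiliary_stats(matrix(4), matrix(c(log(1), log(3)), 1),
                        matrix(0, 1, 2))
  expect_equal(drop(s3$s_beta), c(1, 3))

  # responsibility normalization: topic sums of S_theta match column totals
  set.seed(3)
  Yr <- matrix(rpois(30 * 8, 2), 30, 8)
  elb <- matrix(rnorm(30 * 4), 30, 4)
  elt <- matrix(rnorm(8 * 4), 8, 4)
  sr <- auxiliary_stats(Yr, elb, elt)
  expect_equal(rowSums(sr$s_theta), colSums(Yr), tolerance = 1e-10)
  expect_equal(rowSums(sr$s_beta), rowSums(Yr), tolerance = 1e-10)

  elb[1, 1] <- NaN
  expect_error(auxiliary_stats(Yr, elb, elt), "NaN")
})

test_that("conjugate updates and their transpose symmetry", {
  stats <- structure(list(s_theta = matrix(4), s_beta = matrix(9),
                          loglik = 0), class = "pmf_stats")
  th <- update_theta(stats, Ebeta = matrix(2), a0 = 1, b0 = 1)
  expect_equal(th$shape[1, 1], 5)
  expect_equal(th$rate[1, 1], 3)
  expect_equal(gamma_mean(th)[1, 1], 5 / 3)
  be <- update_beta(stats, Etheta = matrix(2), a0 = 1, b0 = 1)
  expect_equal(be$shape[1, 1], 10)
  expect_equal(be$rate[1, 1], 3)

  # a silent sample shrinks to the prior shifted only through the rate
  stats0 <- structure(list(s_theta = matrix(0, 2, 2), s_beta = matrix(0, 3, 2),
                           loglik = 0), class = "pmf_stats")
  th0 <- update_theta(stats0, Ebeta = matrix(1, 3, 2), a0 = 1.5, b0 = 2)
  expect_true(all(th0$shape == 1.5))
  expect_true(all(th0$rate == 2 + 3))

  # transposing Y swaps the roles of the two updates on a 5 x 4 toy
  set.seed(8)
  Y <- matrix(rpois(20, 3), 5, 4)
  elb <- matrix(rnorm(10), 5, 2)
  elt <- matrix(rnorm(8), 4, 2)
  s <- auxiliary_stats(Y, elb, elt)
  st <- auxiliary_stats(t(Y), elt, elb)
  expect_equal(s$s_beta, st$s_theta, tolerance = 1e-12)
  expect_equal(s$s_theta, st$s_beta, tolerance = 1e-12)
  et <- matrix(rgamma(8, 2), 4, 2)
  expect_equal(update_beta(s, et, 1, 1), update_theta(st, et, 1, 1),
               tolerance = 1e-12)
})

test_that("ELBO matches quadrature on a one-element model and scales responsibilities invariantly", {
  y <- 7
  a <- 2.3; b <- 1.7   # q(beta)
  cc <- 3.1; d <- 0.9  # q(theta)
  beta <- gamma_posterior(matrix(a), matrix(b))
  theta <- gamma_posterior(matrix(cc), matrix(d))
  stats <- auxiliary_stats(matrix(y), gamma_mean_log(beta),
                           gamma_mean_log(theta))
  got <- pmf_elbo(stats, beta, theta, a0 = 1, b0 = 1)

  # independent route: E_q[log p(y, beta, theta) - log q] by 2-D quadrature,
  # adding back the dropped log y! constant
  inner <- function(bv) {
    sapply(bv, function(bb) {
      integrate(function(tv) {
        lam <- bb * tv
        (dpois(y, lam, log = TRUE) +
           dgamma(bb, 1, 1, log = TRUE) + dgamma(tv, 1, 1, log = TRUE) -
           dgamma(bb, a, b, log = TRUE) - dgamma(tv, cc, d, log = TRUE)) *
          dgamma(tv, cc, d)
      }, 0, Inf, rel.tol = 1e-10)$value * dgamma(bb, a, b)
    })
  }
  oracle <- integrate(inner, 0, Inf, rel.tol = 1e-8)$value + lgamma(y + 1)
  expect_equal(got, oracle, tolerance = 1e-5)

  # doubling Y rescales the statistics but leaves responsibilities unchanged
  set.seed(4)
  Y <- matrix(rpois(12, 5), 3, 4)
  elb <- matrix(rnorm(6), 3, 2)
  elt <- matrix(rnorm(8), 4, 2)
  s1 <- auxiliary_stats(Y, elb, elt)
  s2 <- auxiliary_stats(2 * Y, elb, elt)
  expect_equal(2 * s1$s_beta, s2$s_beta, tolerance = 1e-12)
  expect_equal(2 * s1$s_theta, s2$s_theta, tolerance = 1e-12)
})

test_that("sparse-aware inference agrees with the naive full-tensor implementation", {
  for (dims in list(c(3, 3), c(5, 4))) {
    set.seed(17)
    Y <- matrix(rpois(prod(dims), 4), dims[1], dims[2])
    K <- 2
    init <- pmf_init(dims[1], dims[2], K, seed = 17)
    naive <- naive_pmf(Y, K, n_iter = 200, init = init)
    fit <- fit_pmf(Y, K, max_iter = 200, tol = 0, init = init)
    expect_equal(fit$elbo_trace, naive$elbo, tolerance = 1e-6)
    lhat <- tcrossprod(gamma_mean(fit$beta), gamma_mean(fit$theta))
    expect_equal(lhat, naive$lambda, tolerance = 1e-4)
  }
})

test_that("rank-1 fit recovers row/column profiles and the fit is permutation-equivariant", {
  set.seed(23)
  Y <- matrix(rpois(40 * 15, 6), 40, 15)
  fit <- fit_pmf(Y, K = 1, max_iter = 200, tol = 1e-10)
  eb <- drop(gamma_mean(fit$beta))
  et <- drop(gamma_mean(fit$theta))
  expect_gt(cor(eb, rowSums(Y)), 0.999)
  expect_gt(cor(et, colSums(Y)), 0.999)

  perm <- sample(ncol(Y))
  f1 <- fit_pmf(Y, K = 3, max_iter = 60, tol = 0, seed = 5)
  f2 <- fit_pmf(Y[, perm], K = 3, max_iter = 60, tol = 0, seed = 5)
  expect_equal(gamma_mean(f2$beta), gamma_mean(f1$beta), tolerance = 1e-6)
  expect_equal(gamma_mean(f2$theta), gamma_mean(f1$theta)[perm, ],
               tolerance = 1e-6)

  expect_error(fit_pmf(Y, K = 0), "K")
  expect_error(fit_pmf(matrix(numeric(0), 0, 0), K = 1), "non-empty")
  expect_warning(fit_pmf(Y[, 1:2], K = 3, max_iter = 2), "exceeds")
})

test_that("multinomial rescaling normalizes both factors and is idempotent", {
  beta <- cbind(c(2, 2, 4), c(1, 1, 2))
  theta <- rbind(c(1, 3), c(2, 2))
  out <- to_multinomial_scale(beta, theta)
  expect_equal(out$beta[, 1], c(0.25, 0.25, 0.5))
  expect_equal(colSums(out$beta), c(1, 1))
  expect_equal(rowSums(out$theta), c(1, 1))
  # theta row (1,3) against equal-scale topics: scale absorption keeps 8:3*4
  expect_equal(unname(out$theta[1, ]), c(8, 12) / 20)
  again <- to_multinomial_scale(out$beta, out$theta)
  expect_equal(again$beta, out$beta, tolerance = 1e-12)
  expect_equal(again$theta, out$theta, tolerance = 1e-12)
  expect_error(to_multinomial_scale(cbind(c(0, 0)), theta), "all-zero")
})

test_that("tidiers return well-formed tibbles", {
  set.seed(1)
  Y <- matrix(rpois(30 * 10, 4), 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  fit <- fit_pmf(Y, K = 2, max_iter = 30)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 60)
  expect_equal(sum(td$frequency), 2, tolerance = 1e-8)
  gl <- glance(fit)
  expect_equal(gl$K, 2)
  expect_s3_class(autoplot(fit), "ggplot")
})
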