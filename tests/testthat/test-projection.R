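test_that("responsibilities follow the printed update and normalize", {
  elb <- cbind(c(0, -10), c(-10, 0))
  rho <- responsibilities(c(2, 0), elb, c(0, 0))
  expect_equal(rho, exp(c(0, -10)) / sum(exp(c(0, -10))), tolerance = 1e-12)
  expect_equal(sum(rho), 1)

  expect_equal(responsibilities(c(1, 1), matrix(0, 2, 1), 0), 1)
  rho_u <- responsibilities(c(3, 1), matrix(0.7, 2, 4), rep(-1, 4))
  expect_equal(rho_u, rep(0.25, 4))
  expect_error(responsibilities(c(0, 0), elb, c(0, 0)), "zero total")

  # without the total-count divisor the data term is unscaled
  r1 <- responsibilities(c(4, 0), elb, c(0, 0), scale_data_term = FALSE)
  expect_equal(log(r1[1] / r1[2]), 40, tolerance = 1e-8)
})

test_that("per-cell loading update is the stated plug-in", {
  up <- update_theta_cell(c(0.25, 0.75), 8, c(2, 2), a0 = 1, b0 = 1)
  expect_equal(up$shape, c(3, 7))
  expect_equal(up$rate, c(3, 3))
  up2 <- update_theta_cell(c(1, 0), 10, c(5, 5))
  expect_equal(up2$shape, c(11, 1))
  expect_error(update_theta_cell(c(1, 0), 0, c(5, 5)), "zero total")
})

test_that("cell regression recovers pure topics and is exactly chunk-invariant", {
  # two disjoint gene programs; cells purely from one or the other
  set.seed(12)
  D <- 60
  beta_true <- cbind(c(rep(8, 30), rep(0.2, 30)), c(rep(0.2, 30), rep(8, 30)))
  n_per <- 60
  cells <- sapply(rep(1:2, each = n_per), function(k) {
    rpois(D, beta_true[, k] * 3)
  })
  rownames(cells) <- paste0("g", 1:D)
  colnames(cells) <- paste0("c", seq_len(ncol(cells)))
  Y <- cbind(rowSums(cells[, 1:n_per]), rowSums(cells[, -(1:n_per)]))
  rownames(Y) <- rownames(cells)
  fit <- fit_pmf(normalize_pseudobulk(Y), K = 2, max_iter = 100, seed = 2)

  th <- regress_cells(as_count_matrix(cells), fit)
  P <- proportions_matrix(th)
  truth <- rep(1:2, each = n_per)
  # align topics to truth by the first pure cell
  lead <- which.max(P[1, ])
  hit <- ifelse(truth == 1, P[, lead], P[, 3 - lead])
  expect_gt(mean(hit > 0.9), 0.95)

  expect_equal(rowSums(th$rho), rep(1, ncol(cells)), tolerance = 1e-8)
  expect_equal(rowSums(P), setNames(rep(1, ncol(cells)), rownames(P)),
               tolerance = 1e-8)

  # chunking cannot change per-cell results
  th1 <- regress_cells(as_count_matrix(cells), fit, chunk_size = 1)
  expect_identical(th$proportions, th1$proportions)

  # duplicated cells get identical loadings
  dup <- as_count_matrix(cells[, rep(1, 5)], cells = paste0("d", 1:5))
  thd <- regress_cells(dup, fit)
  Pd <- proportions_matrix(thd)
  expect_true(all(apply(Pd, 2, function(col) max(col) - min(col)) == 0))

  # zero-count cells are dropped with a warning and reported
  with0 <- cbind(cells[, 1:3], z = 0)
  expect_warning(th0 <- regress_cells(as_count_matrix(with0), fit), "dropped")
  expect_identical(th0$dropped, "z")

  bad <- cells
  rownames(bad) <- rev(rownames(bad))
  expect_error(regress_cells(as_count_matrix(bad), fit), "gene order")
})

test_that("fixed-dictionary regression tracks frozen-dictionary full inference", {
  set.seed(31)
  D <- 25; n <- 12; K <- 2
  sim <- simulate_pmf_data(D, n, K, seed = 31, scale = 8)
  fit <- fit_pmf(sim$Y, K, max_iter = 150, seed = 3)

  th_fast <- regress_cells(as_count_matrix(sim$Y), fit, n_iter = 30)
  P_fast <- proportions_matrix(th_fast)

  # independent route: full per-entry responsibilities with beta frozen
  elb <- gamma_mean_log(fit$beta)
  ts <- matrix(1, n, K); tr <- matrix(2, n, K)
  for (iter in 1:60) {
    elt <- digamma(ts) - log(tr)
    for (j in 1:n) {
      zj <- matrix(0, D, K)
      for (i in 1:D) {
        w <- elb[i, ] + elt[j, ]
        w <- exp(w - max(w))
        zj[i, ] <- w / sum(w)
      }
      ts[j, ] <- fit$a0 + colSums(sim$Y[, j] * zj)
      tr[j, ] <- fit$b0 + colSums(gamma_mean(fit$beta))
    }
  }
  P_full <- (ts / tr) / rowSums(ts / tr)
  for (j in 1:n) {
    expect_gt(cor(P_fast[j, ], P_full[j, ]), 0.99)
  }
})

test_that("bulk projection reuses the regression path on the shared gene universe", {
  set.seed(41)
  cfg <- benchmark_config(n_types = 2, cells_per_type = 80, depth = 3000,
                          rho = 1, seed = 41, D = 200)
  sim <- make_benchmark(cfg)
  pb <- build_pseudobulk(sim$counts, depth = 4, seed = 41)
  fit <- fit_pmf(pb$Y, K = 2, max_iter = 100, seed = 41)

  # a bulk sample that IS a pseudobulk column gets that column's loadings
  bulk1 <- pb$Y[, 2, drop = FALSE]
  th_b <- project_bulk(bulk1, fit)
  th_pb <- regress_cells(as_count_matrix(pb$Y), fit)
  expect_equal(proportions_matrix(th_b)[1, ],
               proportions_matrix(th_pb)[2, ], tolerance = 1e-10)

  # 50/50 mixture of the two topic-pure expression profiles projects near
  # (0.5, 0.5); few regression rounds keep the estimate calibrated (repeated
  # rounds progressively sharpen loadings toward the dominant topic)
  eb <- gamma_mean(fit$beta)
  mix <- matrix(0.5 * eb[, 1] / sum(eb[, 1]) + 0.5 * eb[, 2] / sum(eb[, 2]),
                dimnames = list(fit$genes, "mix"))
  th_mix <- project_bulk(mix * 1e4, fit, n_iter = 2)
  expect_lt(max(abs(proportions_matrix(th_mix) - 0.5)), 0.1)

  # disjoint gene universe errors
  rn <- paste0("other", seq_len(nrow(bulk1)))
  bulk_bad <- bulk1
  rownames(bulk_bad) <- rn
  expect_error(project_bulk(bulk_bad, fit), "shared")
})

test_that("neighbour-counting deconvolution returns probability vectors", {
  set.seed(6)
  Pc <- rbind(matrix(rep(c(0.9, 0.1), each = 30), 30),
              matrix(rep(c(0.1, 0.9), each = 30), 30))
  Pc <- Pc + matrix(runif(120, 0, 0.02), 60)
  Pc <- Pc / rowSums(Pc)
  labels <- rep(c("A", "B"), each = 30)

  # uniform labels give fraction 1 regardless of the query
  one <- deconvolve_by_neighbors(matrix(c(0.5, 0.5), 1), Pc,
                                 rep("A", 60), k = 10)
  expect_equal(one$fraction, 1)

  # k = 1 is an indicator of the nearest cell's label
  ind <- deconvolve_by_neighbors(matrix(c(0.88, 0.12), 1), Pc, labels, k = 1)
  expect_equal(ind$fraction, c(1, 0))

  mixed <- deconvolve_by_neighbors(rbind(c(0.9, 0.1), c(0.5, 0.5)), Pc,
                                   labels, k = 20)
  sums <- tapply(mixed$fraction, mixed$sample, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(mixed$fraction >= 0 & mixed$fraction <= 1))
  expect_error(deconvolve_by_neighbors(Pc[1:2, ], Pc, labels, k = 100), "k")
  expect_error(deconvolve_by_neighbors(Pc[1:2, ], Pc, labels[-1], k = 5),
               "labels")
})
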