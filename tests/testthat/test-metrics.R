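test_that("rmse and mae match hand-computed values and symmetries", {
  Q <- matrix(c(0.6, 0.4, 0.3, 0.7), 2, 2)
  expect_equal(rmse(Q, Q), 0)
  expect_equal(mae(Q, Q), 0)

  # d=1, n=2, errors (0.1, -0.1)
  a <- matrix(c(0.5, 0.5), 1, 2)
  b <- matrix(c(0.4, 0.6), 1, 2)
  expect_equal(rmse(a, b, aligned = FALSE), 0.1)
  expect_equal(mae(a, b, aligned = FALSE), 0.1)

  # invariance under simultaneous column relabeling; bounded by max error
  set.seed(60)
  Qh <- matrix(runif(40), 4, 10)
  Qt <- matrix(runif(40), 4, 10)
  perm <- sample(10)
  expect_equal(rmse(Qh, Qt), rmse(Qh[, perm], Qt[, perm]))
  expect_lte(mae(Qh, Qt, aligned = FALSE), max(abs(Qh - Qt)))
  expect_lte(rmse(Qh, Qt, aligned = FALSE), max(abs(Qh - Qt)))
})

test_that("factor alignment undoes row permutations and matches brute force", {
  set.seed(61)
  Qt <- matrix(runif(5 * 20), 5, 20)
  expect_equal(align_factors(Qt, Qt), 1:5)
  swap <- c(3, 1, 2, 5, 4)
  expect_equal(align_factors(Qt[swap, ], Qt), order(swap))
  expect_equal(rmse(Qt[swap, ], Qt), 0)

  # hungarian path equals exhaustive search, for matrices and raw costs
  for (i in 1:30) {
    d <- sample(2:7, 1L)
    Qh <- matrix(runif(d * 15), d, 15)
    Qt <- matrix(runif(d * 15), d, 15)
    ex <- align_factors(Qh, Qt, method = "exhaustive")
    hu <- align_factors(Qh, Qt, method = "hungarian")
    expect_equal(rmse(Qh[hu, ], Qt, aligned = FALSE),
                 rmse(Qh[ex, ], Qt, aligned = FALSE), tolerance = 1e-12)
    cost <- matrix(rnorm(d * d), d, d)
    a <- alstruct:::solve_assignment(cost)
    ao <- oracle_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(d), a)]),
                 sum(cost[cbind(seq_len(d), ao)]), tolerance = 1e-12)
  }
  expect_error(align_factors(matrix(0, 2, 3), matrix(0, 3, 3)), "identical dimensions")
})

test_that("mean log-likelihood matches the binomial pmf", {
  X1 <- genotype_matrix(matrix(1, 1, 1))
  expect_equal(mean_loglik(X1, matrix(0.5, 1, 1)), log(0.5))
  X2 <- genotype_matrix(matrix(2, 1, 1))
  expect_equal(mean_loglik(X2, matrix(1 - 1e-9, 1, 1)), 0, tolerance = 1e-6)
  expect_error(mean_loglik(X1, matrix(1.2, 1, 1)), "outside")

  set.seed(62)
  X <- suppressWarnings(genotype_matrix(matrix(sample(0:2, 60, replace = TRUE), 6, 10)))
  Fm <- matrix(runif(60, 0.05, 0.95), 6, 10)
  expect_lte(mean_loglik(X, Fm), 0)
  hand <- mean(log(choose(2, as.vector(unclass(X))) *
                     as.vector(Fm)^as.vector(unclass(X)) *
                     (1 - as.vector(Fm))^(2 - as.vector(unclass(X)))))
  expect_equal(mean_loglik(X, Fm), hand, tolerance = 1e-12)

  # the true F explains its own data better than a column-shuffled F
  sim <- simulate_psd(m = 400, n = 40, d = 3, alpha = "a2", seed = 63)
  shuffled <- sim$F[, sample(40)]
  expect_gt(mean_loglik(sim$X, sim$F), mean_loglik(sim$X, shuffled))
})

test_that("variation explained orders components and scales quadratically", {
  set.seed(64)
  X <- genotype_matrix(matrix(sample(0:2, 200, replace = TRUE), 20, 10))
  Q <- matrix(runif(30), 3, 10)
  s2 <- variation_explained(X, Q)
  expect_equal(s2[1], sum((unclass(X) %*% Q[1, ])^2))
  expect_equal(variation_explained(X, rbind(Q[1, ] * 2))[1], 4 * s2[1])
  expect_equal(variation_explained(X, rbind(rep(0, 10)))[1], 0)
})

test_that("anchor diagnostics detect vertex individuals and fixed SNPs", {
  Qa <- cbind(diag(3), matrix(1 / 3, 3, 5))
  expect_true(check_anchor_individuals(Qa, tol = 0.05)$satisfied)
  expect_equal(check_anchor_individuals(Qa)$witnesses, 1:3)
  Qc <- matrix(1 / 3, 3, 8)
  expect_false(check_anchor_individuals(Qc, tol = 0.05)$satisfied)

  # Dirichlet(0.1) columns produce near-anchors; Dirichlet(10) does not
  hits <- vapply(1:5, function(s) {
    sim <- suppressWarnings(
      simulate_psd(m = 1, n = 500, d = 3, alpha = "a3", seed = 70 + s))
    check_anchor_individuals(sim$Q, tol = 0.05)$satisfied
  }, logical(1L))
  expect_gte(mean(hits), 0.8)
  hits10 <- vapply(1:5, function(s) {
    sim <- suppressWarnings(
      simulate_psd(m = 1, n = 500, d = 3, alpha = "a1", seed = 70 + s))
    check_anchor_individuals(sim$Q, tol = 0.05)$satisfied
  }, logical(1L))
  expect_equal(mean(hits10), 0)

  # each population has one SNP segregating only in it
  P <- rbind(c(0.5, 0.01, 0.99), c(0.02, 0.6, 0.98), c(0.01, 0.99, 0.45))
  res <- check_anchor_snps(P, tol = 0.05)
  expect_true(res$satisfied)
  expect_false(check_anchor_snps(matrix(0.5, 4, 3))$satisfied)
})

test_that("fit_metrics bundles aligned errors with likelihood diagnostics", {
  sim <- simulate_psd(m = 500, n = 40, d = 3, alpha = "a3", seed = 71)
  fit <- fit_alstructure(sim$X, 3, seed = 1)
  mets <- fit_metrics(fit$Q, sim$Q, X = sim$X, Fhat = fit$Fhat)
  expect_gte(mets$rmse, 0)
  expect_gte(mets$mae, 0)
  expect_setequal(mets$alignment, 1:3)
  expect_lte(mets$mean_loglik, 0)
  expect_length(mets$variation_explained, 3L)
  expect_lte(mets$rmse, rmse(fit$Q, sim$Q, aligned = FALSE) + 1e-12)
})
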