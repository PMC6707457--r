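test_that("simplex projection matches the KKT enumeration oracle", {
  expect_equal(project_to_simplex(c(0.5, 0.5)), c(0.5, 0.5))
  expect_equal(project_to_simplex(c(2, 0, 0)), c(1, 0, 0))
  expect_error(project_to_simplex(numeric(0)), "empty")

  set.seed(41)
  for (i in 1:200) {
    d <- sample(2:10, 1L)
    v <- rnorm(d, sd = sample(c(0.5, 1, 5), 1L))
    w <- project_to_simplex(v)
    expect_equal(w, oracle_simplex_projection(v), tolerance = 1e-8)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
    expect_equal(project_to_simplex(w), w, tolerance = 1e-12) # idempotent
  }
})

test_that("truncation clips exactly to the unit interval", {
  expect_equal(truncate_unit_interval(c(1.3, -0.2, 0.42)), c(1, 0, 0.42))
})

test_that("constrained LS subproblem solvers are exact", {
  set.seed(42)
  grid_obj <- function(A, b, w) 0.5 * drop(t(w) %*% A %*% w) - sum(b * w)
  for (i in 1:40) {
    d <- sample(2:5, 1L)
    P <- matrix(runif(30 * d), 30, d)
    A <- crossprod(P)
    f <- runif(30)
    b <- drop(crossprod(P, f))
    # simplex-constrained: compare against dense sampling + local refinement
    q <- drop(alstruct:::simplex_ls(A, matrix(b, ncol = 1)))
    expect_equal(sum(q), 1, tolerance = 1e-10)
    expect_true(all(q >= -1e-12))
    # optimality: no feasible perturbation along simplex directions improves
    for (k in 1:20) {
      dir <- rnorm(d); dir <- dir - mean(dir)
      for (st in c(1e-4, 1e-3)) {
        cand <- q + st * dir
        if (all(cand >= 0)) {
          expect_gte(grid_obj(A, b, cand), grid_obj(A, b, q) - 1e-12)
        }
      }
    }
    # box-constrained: same first-order audit on [0,1]^d
    Qf <- matrix(runif(d * 25), d, 25)
    Ab <- tcrossprod(Qf)
    fb <- runif(25)
    bb <- drop(Qf %*% fb)
    p <- drop(alstruct:::box_ls(Ab, matrix(bb, nrow = 1)))
    expect_true(all(p >= 0 & p <= 1))
    for (k in 1:20) {
      cand <- p + rnorm(d, sd = 1e-3)
      if (all(cand >= 0 & cand <= 1)) {
        expect_gte(grid_obj(Ab, bb, cand), grid_obj(Ab, bb, p) - 1e-12)
      }
    }
  }
})

test_that("grouped box solver agrees with its exhaustive enumeration fallback", {
  set.seed(43)
  for (i in 1:20) {
    d <- sample(2:4, 1L)
    Qf <- matrix(runif(d * 30), d, 30)
    A <- tcrossprod(Qf)
    B <- matrix(rnorm(50 * d, sd = 3), 50, d)
    expect_equal(alstruct:::box_ls(A, B), alstruct:::box_ls_enum(A, B),
                 tolerance = 1e-8)
  }
})

test_that("ALS recovers noiseless factorizations with anchor individuals", {
  inst <- make_noiseless_instance(m = 1000, n = 100, d = 3, seed = 44)
  for (alg in c("tals", "cals")) {
    fac <- if (alg == "tals") {
      tals(inst$F, 3, tol = 1e-9, max_iter = 5000, seed = 2)
    } else {
      cals(inst$F, 3, tol = 1e-9, max_iter = 5000, seed = 2)
    }
    expect_lt(rmse(fac$Q, inst$Q), 1e-3)
    expect_true(all(fac$P >= 0 & fac$P <= 1))
    expect_true(all(fac$Q >= 0))
    expect_equal(colSums(fac$Q), rep(1, 100), tolerance = 1e-10)
    final_obj <- utils::tail(fac$objective_trace, 1L)
    expect_lt(final_obj, 1e-6 * sqrt(sum(inst$F^2)))
  }
})

test_that("d = 1 collapses the simplex to the all-ones row", {
  set.seed(45)
  Fm <- matrix(runif(200), 20, 10)
  fac <- tals(Fm, 1, seed = 1)
  expect_equal(fac$Q, matrix(1, 1, 10))
  expect_true(all(fac$P >= 0 & fac$P <= 1))
})

test_that("cALS objective trace is non-increasing", {
  for (s in 1:3) {
    sim <- simulate_psd(m = 800, n = 50, d = 3, alpha = "a3", seed = 50 + s)
    sub <- estimate_subspace(sim$X, 3)
    Fh <- project_frequencies(sim$X, sub)
    fac <- cals(Fh, 3, seed = s)
    expect_lt(max(diff(fac$objective_trace)), 1e-9)
    # trace values audited against the dense objective
    expect_equal(utils::tail(fac$objective_trace, 1L),
                 oracle_frobenius(Fh$values, fac$P, fac$Q),
                 tolerance = 1e-8)
  }
})

test_that("structured and dense frequency representations give identical fits", {
  sim <- simulate_psd(m = 1500, n = 60, d = 3, alpha = "a3", seed = 52)
  Fh <- project_frequencies(sim$X, estimate_subspace(sim$X, 3))
  expect_gt(Fh$clamped_fraction, 0) # exercise the sparse correction term
  for (ctor in list(tals, cals)) {
    fs <- ctor(Fh, 3, seed = 4)
    fd <- ctor(Fh$values, 3, seed = 4)
    expect_equal(fs$Q, fd$Q, tolerance = 1e-10)
    expect_equal(fs$P, fd$P, tolerance = 1e-10)
  }
})

test_that("fit_alstructure composes the pipeline and is deterministic", {
  sim <- simulate_psd(m = 1200, n = 60, d = 3, alpha = "a3", seed = 53)
  fit1 <- fit_alstructure(sim$X, 3, seed = 7)
  fit2 <- fit_alstructure(sim$X, 3, seed = 7)
  expect_identical(fit1$Q, fit2$Q)
  expect_identical(fit1$P, fit2$P)
  # constraint families hold on the output
  expect_true(all(fit1$P >= 0 & fit1$P <= 1))
  expect_equal(colSums(fit1$Q), rep(1, 60), tolerance = 1e-10)
  expect_true(all(fit1$Q >= 0))
  expect_lte(fit1$iterations, 1000L)
  expect_error(fit_alstructure(sim$X, 0), "positive")

  # sample relabeling equivariance: permuted columns give permuted Q
  perm <- sample(60)
  fit_p <- fit_alstructure(genotype_matrix(unclass(sim$X)[, perm]), 3, seed = 7)
  expect_equal(fit_p$Q, fit1$Q[, perm], tolerance = 1e-6)
})
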