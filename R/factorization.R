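#' Euclidean projection onto the probability simplex
#'
#' Returns the closest point (in Euclidean distance) to `v` on
#' `{w : w >= 0, sum(w) = 1}` by the sort-and-threshold method: sort `v`
#' descending as `u`, find `rho = max{k : u_k - (cumsum(u)_k - 1)/k > 0}`,
#' set `tau = (cumsum(u)_rho - 1)/rho` and `w = pmax(v - tau, 0)`.
#'
#' @param v numeric vector, length >= 1.
#' @return numeric vector on the simplex (sum exactly renormalized to 1 is
#'   not needed: the thresholding construction sums to 1 up to roundoff).
#' @export
project_to_simplex <- function(v) {
  if (length(v) == 0L) stop("cannot project an empty vector onto the simplex")
  if (!all(is.finite(v))) stop("non-finite entries in simplex projection input")
  if (length(v) == 1L) return(1)
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  k <- seq_along(u)
  rho <- max(which(u - (css - 1) / k > 0))
  tau <- (css[rho] - 1) / rho
  pmax(v - tau, 0)
}

# Column-wise simplex projection of a d x n matrix.
project_cols_to_simplex <- function(M) {
  if (nrow(M) == 1L) return(matrix(1, 1L, ncol(M)))
  apply(M, 2L, project_to_simplex)
}

#' Truncate a matrix into the unit interval
#'
#' Entrywise `min(max(x, 0), 1)` — the feasibility repair applied to the
#' ancestral-frequency factor after each unconstrained least-squares sweep.
#'
#' @param M numeric matrix or vector.
#' @return object of the same shape with entries in `[0, 1]`.
#' @export
truncate_unit_interval <- function(M) {
  pmin(pmax(M, 0), 1)
}

# --- frequency-matrix product kernels -----------------------------------

# The ALS sweeps only touch Fhat through the two products W'F (W: m x k)
# and F M (M: n x k) plus the constant ||F||^2. When the estimate carries
# its projection structure F = Z V' + E (Z = X V / 2, E the sparse clamping
# correction), both products collapse to thin-matrix algebra plus a sparse
# multiply — exact, and orders of magnitude cheaper than streaming the
# dense m x n matrix. Bare matrices fall back to dense products.
fhat_ops <- function(Fhat) {
  lr <- if (inherits(Fhat, "frequency_estimate")) Fhat$low_rank else NULL
  if (!is.null(lr)) {
    Z <- lr$Z; V <- lr$V; E <- lr$E
    list(
      m = nrow(Z), n = nrow(V), f2 = lr$f2,
      left = function(W) { # t(W) %*% F : k x n
        out <- crossprod(W, Z) %*% t(V)
        if (!is.null(E)) out <- out + t(as.matrix(Matrix::crossprod(E, W)))
        out
      },
      right = function(M) { # F %*% M : m x k
        out <- Z %*% crossprod(V, M)
        if (!is.null(E)) out <- out + as.matrix(E %*% M)
        out
      }
    )
  } else {
    Fm <- frequency_values(Fhat)
    list(
      m = nrow(Fm), n = ncol(Fm), f2 = sum(Fm^2),
      left = function(W) crossprod(W, Fm),
      right = function(M) Fm %*% M
    )
  }
}

# --- unconstrained multi-RHS least squares via thin QR ------------------

# Solve min_C || F - A C ||_F for C (A is m x d) using a thin QR of A;
# minimum-norm SVD solution when A is rank deficient.
lls_coef <- function(A, ops) {
  d <- ncol(A)
  qa <- qr(A)
  if (qa$rank == d) {
    U <- qr.Q(qa)
    R <- qr.R(qa)
    C <- backsolve(R, ops$left(U))
    if (!identical(qa$pivot, seq_len(d))) C[qa$pivot, ] <- C
    C
  } else {
    sv <- svd(A)
    pos <- sv$d > max(sv$d[1L], .Machine$double.eps) * 1e-12
    sv$v[, pos, drop = FALSE] %*%
      (ops$left(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  }
}

# Solve min_P || F - P Q ||_F for P (Q is d x n) without materializing
# t(F): thin QR of t(Q), coefficients P = (F U) R^{-T}.
lls_left <- function(ops, Q) {
  d <- nrow(Q)
  qt <- qr(t(Q))
  if (qt$rank == d) {
    U <- qr.Q(qt)
    R <- qr.R(qt)
    P <- t(backsolve(R, t(ops$right(U))))
    if (!identical(qt$pivot, seq_len(d))) P[, qt$pivot] <- P
    P
  } else {
    sv <- svd(t(Q))
    pos <- sv$d > max(sv$d[1L], .Machine$double.eps) * 1e-12
    ops$right(sv$u[, pos, drop = FALSE]) %*%
      (t(sv$v[, pos, drop = FALSE]) / sv$d[pos])
  }
}

# ||F - P Q||_F via the trace identity
# ||F||^2 - 2 <P'F, Q> + <P'P, QQ'>, never forming the m x n product.
frob_residual <- function(ops, P, Q) {
  val <- ops$f2 - 2 * sum(ops$left(P) * Q) + sum(crossprod(P) * tcrossprod(Q))
  sqrt(max(val, 0))
}

# --- exact constrained least-squares subproblems ------------------------

# Simplex-constrained LS: for each column f of F solve
#   min ||f - P q||^2  s.t.  q >= 0, sum(q) = 1,
# given A = P'P (d x d) and B = P'F (d x n). KKT support enumeration,
# grouped across columns: for support S solve
# [[A_SS, 1], [1', 0]] [q_S; lambda] = [b_S; 1]; accept when q_S >= -tol
# and dual feasibility (A q - b + lambda >= -tol off S) holds. Exact for
# any support size; enumeration is over 2^d - 1 supports, practical for
# the small d used in admixture fitting.
simplex_ls <- function(A, B, kkt_tol = 1e-9) {
  d <- nrow(A)
  n <- ncol(B)
  if (d == 1L) return(matrix(1, 1L, n))
  Q <- matrix(NA_real_, d, n)
  unresolved <- seq_len(n)
  supports <- support_list(d)
  for (S in supports) {
    if (length(unresolved) == 0L) break
    k <- length(S)
    K <- rbind(cbind(A[S, S, drop = FALSE], 1), c(rep(1, k), 0))
    sol <- tryCatch(solve(K, rbind(B[S, unresolved, drop = FALSE], 1)),
                    error = function(e) NULL)
    if (is.null(sol)) next
    qS <- sol[seq_len(k), , drop = FALSE]
    lambda <- sol[k + 1L, ]
    ok <- colSums(qS < -kkt_tol) == 0L
    notS <- setdiff(seq_len(d), S)
    if (length(notS) > 0L) {
      # mu_i = (A q - b)_i + lambda must be >= 0 for i outside the support
      mu <- A[notS, S, drop = FALSE] %*% qS -
        B[notS, unresolved, drop = FALSE] +
        rep(lambda, each = length(notS))
      ok <- ok & colSums(mu < -kkt_tol) == 0L
    }
    if (any(ok)) {
      cols <- unresolved[ok]
      qfull <- matrix(0, d, length(cols))
      qfull[S, ] <- pmax(qS[, ok, drop = FALSE], 0)
      Q[, cols] <- qfull
      unresolved <- unresolved[!ok]
    }
  }
  if (length(unresolved) > 0L) {
    # degenerate Gram matrix: fall back to the heuristic update for these
    # columns (ridge-regularized LS then simplex projection)
    warning(sprintf("simplex-constrained LS fell back to heuristic update for %d column(s)",
                    length(unresolved)))
    C <- solve(A + diag(1e-10, d), B[, unresolved, drop = FALSE])
    Q[, unresolved] <- project_cols_to_simplex(C)
  }
  Q
}

# All non-empty subsets of 1..d, largest first (the full support is by far
# the most common optimum).
support_list <- function(d) {
  subs <- lapply(seq_len(2^d - 1L), function(mask) which(bitwAnd(mask, bitwShiftL(1L, 0:(d - 1L))) > 0L))
  subs[order(vapply(subs, length, integer(1L)), decreasing = TRUE)]
}

# Box-constrained LS: for each row f of F solve
#   min ||f - p Q||^2  s.t.  0 <= p <= 1  (p a length-d row vector),
# given A = Q Q' (d x d) and B = F Q' (m x d).
# Grouped block-pivoting active set over rows: coordinates are free,
# clamped at 0, or clamped at 1; each pass solves the free block for every
# distinct pattern at once and re-clamps/frees by KKT signs. Rows that fail
# to settle (cycling is possible for block pivoting, though rare) fall back
# to exact enumeration over all 3^d patterns.
box_ls <- function(A, B, kkt_tol = 1e-9, max_pass = 30L) {
  d <- nrow(A)
  m <- nrow(B)
  P <- matrix(0, m, d)
  state <- matrix(0L, m, d) # 0 free, 1 at lower (0), 2 at upper (1)
  active <- seq_len(m)
  pass <- 0L
  while (length(active) > 0L && pass < max_pass) {
    pass <- pass + 1L
    st <- state[active, , drop = FALSE]
    pat <- as.vector(st %*% 3L^(seq_len(d) - 1L))
    for (pp in unique(pat)) {
      rows <- active[pat == pp]
      s <- state[rows[1L], ]
      free <- which(s == 0L)
      hi <- which(s == 2L)
      rhs <- t(B[rows, free, drop = FALSE])
      if (length(hi) > 0L) {
        rhs <- rhs - A[free, hi, drop = FALSE] %*% matrix(1, length(hi), length(rows))
      }
      if (length(free) > 0L) {
        pf <- tryCatch(solve(A[free, free, drop = FALSE], rhs), error = function(e) NULL)
        if (is.null(pf)) {
          # singular free block: ridge-regularized solve keeps the sweep going
          pf <- solve(A[free, free, drop = FALSE] + diag(1e-10, length(free)), rhs)
        }
        P[rows, free] <- t(pf)
      }
      if (length(hi) > 0L) P[rows, hi] <- 1
      P[rows, s == 1L] <- 0
    }
    # KKT audit for all still-active rows
    G <- P[active, , drop = FALSE] %*% A - B[active, , drop = FALSE]
    st <- state[active, , drop = FALSE]
    pv <- P[active, , drop = FALSE]
    viol_lo <- st == 0L & pv < -kkt_tol
    viol_hi <- st == 0L & pv > 1 + kkt_tol
    free_lo <- st == 1L & G < -kkt_tol
    free_hi <- st == 2L & G > kkt_tol
    bad <- viol_lo | viol_hi | free_lo | free_hi
    row_ok <- rowSums(bad) == 0L
    if (any(row_ok)) {
      done <- active[row_ok]
      P[done, ] <- pmin(pmax(P[done, , drop = FALSE], 0), 1)
    }
    st[viol_lo] <- 1L
    st[viol_hi] <- 2L
    st[free_lo] <- 0L
    st[free_hi] <- 0L
    state[active, ] <- st
    active <- active[!row_ok]
  }
  if (length(active) > 0L) {
    P[active, ] <- box_ls_enum(A, B[active, , drop = FALSE], kkt_tol)
  }
  P
}

# Exact enumeration fallback over all 3^d free/lower/upper patterns.
box_ls_enum <- function(A, B, kkt_tol = 1e-9) {
  d <- ncol(B)
  m <- nrow(B)
  P <- matrix(NA_real_, m, d)
  unresolved <- seq_len(m)
  patterns <- as.matrix(expand.grid(rep(list(0:2), d)))
  ord <- order(rowSums(patterns == 0L), decreasing = TRUE)
  for (r in ord) {
    if (length(unresolved) == 0L) break
    s <- patterns[r, ]
    free <- which(s == 0L); lo <- which(s == 1L); hi <- which(s == 2L)
    rhs <- t(B[unresolved, free, drop = FALSE])
    if (length(hi) > 0L && length(free) > 0L) {
      rhs <- rhs - A[free, hi, drop = FALSE] %*% matrix(1, length(hi), length(rhs) / length(free))
    }
    pf <- if (length(free) > 0L) {
      tryCatch(solve(A[free, free, drop = FALSE], rhs), error = function(e) NULL)
    } else {
      matrix(0, 0L, length(unresolved))
    }
    if (is.null(pf)) next
    cand <- matrix(0, length(unresolved), d)
    if (length(free) > 0L) cand[, free] <- t(pf)
    if (length(hi) > 0L) cand[, hi] <- 1
    G <- cand %*% A - B[unresolved, , drop = FALSE]
    ok <- rep(TRUE, length(unresolved))
    if (length(free) > 0L) {
      ok <- ok & rowSums(cand[, free, drop = FALSE] < -kkt_tol |
                           cand[, free, drop = FALSE] > 1 + kkt_tol) == 0L
    }
    if (length(lo) > 0L) ok <- ok & rowSums(G[, lo, drop = FALSE] < -kkt_tol) == 0L
    if (length(hi) > 0L) ok <- ok & rowSums(G[, hi, drop = FALSE] > kkt_tol) == 0L
    if (any(ok)) {
      P[unresolved[ok], ] <- pmin(pmax(cand[ok, , drop = FALSE], 0), 1)
      unresolved <- unresolved[!ok]
    }
  }
  if (length(unresolved) > 0L) {
    stop(sprintf("box-constrained LS subproblem failed for %d row(s)", length(unresolved)))
  }
  P
}

# --- alternating least squares drivers ----------------------------------

als_engine <- function(Fhat, d, tol, max_iter, seed, algorithm) {
  ops <- fhat_ops(Fhat)
  Fv <- if (inherits(Fhat, "frequency_estimate")) Fhat$values else Fhat
  if (!is.null(Fv) && !all(is.finite(Fv))) {
    stop("frequency estimate contains non-finite entries")
  }
  m <- ops$m; n <- ops$n
  d <- as.integer(d)
  if (d < 1L || d > min(m, n)) stop("d must satisfy 1 <= d <= min(m, n)")
  if (!is.numeric(tol) || tol <= 0) stop("tol must be positive")
  if (!is.null(seed)) set.seed(seed)
  P <- matrix(stats::runif(m * d), m, d)
  Q <- matrix(1 / d, d, n)
  trace <- numeric(max_iter)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Q_old <- Q
    if (algorithm == "tALS") {
      Q <- project_cols_to_simplex(lls_coef(P, ops))
    } else {
      Q <- simplex_ls(crossprod(P), ops$left(P))
    }
    Q <- revive_dead_rows(Q)
    if (algorithm == "tALS") {
      P <- truncate_unit_interval(lls_left(ops, Q))
    } else {
      P <- box_ls(tcrossprod(Q), ops$right(t(Q)))
    }
    trace[iter] <- frob_residual(ops, P, Q)
    rel <- norm(Q - Q_old, "F") / max(norm(Q_old, "F"), .Machine$double.eps)
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  trace <- trace[seq_len(iter)]
  structure(
    list(P = P, Q = Q, objective_trace = trace, iterations = iter,
         converged = converged, algorithm = algorithm, d = d, tol = tol,
         seed = seed),
    class = "admixture_factors"
  )
}

# A population row that lost all mass cannot recover through least squares;
# reseed it from the running generator (and warn), then re-project columns.
revive_dead_rows <- function(Q) {
  dead <- rowSums(Q) <= 0
  if (any(dead)) {
    warning(sprintf("%d admixture row(s) collapsed to zero; reinitializing", sum(dead)))
    Q[dead, ] <- matrix(stats::runif(sum(dead) * ncol(Q)), sum(dead), ncol(Q))
    Q <- project_cols_to_simplex(Q)
  }
  Q
}

#' Truncated alternating least squares factorization
#'
#' Factors a frequency estimate `Fhat` into `P Q` under the unit-cube
#' constraint on `P` and the column-simplex constraint on `Q` by the fast
#' heuristic: alternate unconstrained least-squares solves for `Q` then
#' `P`, repairing feasibility after each solve (column-wise simplex
#' projection of `Q`, entrywise truncation of `P`). The returned factors
#' satisfy both constraint families exactly. The objective
#' `||Fhat - P Q||_F` is recorded per sweep but is not guaranteed monotone
#' (the feasibility repairs can perturb it); use [cals] for the
#' monotone-descent variant.
#'
#' @param Fhat `frequency_estimate` (or bare m x n matrix) with entries in
#'   `[0, 1]`.
#' @param d number of ancestral populations.
#' @param tol convergence tolerance: relative Frobenius change of `Q`
#'   between sweeps.
#' @param max_iter maximum number of sweeps.
#' @param seed integer seed for the uniform initialization of `P`; `NULL`
#'   uses the current RNG state.
#' @return object of class `admixture_factors`: list with `P` (m x d), `Q`
#'   (d x n), `objective_trace`, `iterations`, `converged`, `algorithm`.
#' @export
tals <- function(Fhat, d, tol = 1e-5, max_iter = 1000L, seed = NULL) {
  als_engine(Fhat, d, tol, max_iter, seed, "tALS")
}

#' Constrained alternating least squares factorization
#'
#' The provably convergent variant: each sweep solves the two convex
#' subproblems exactly — for every column of `Q` a simplex-constrained
#' least-squares quadratic program, and for every row of `P` a
#' box-constrained one. Block-optimal updates cannot increase the
#' objective, so `objective_trace` is non-increasing and limit points are
#' stationary points of the constrained problem. Substantially slower than
#' [tals]; fits are typically indistinguishable in practice.
#'
#' @inheritParams tals
#' @return object of class `admixture_factors` (see [tals]).
#' @export
cals <- function(Fhat, d, tol = 1e-5, max_iter = 1000L, seed = NULL) {
  als_engine(Fhat, d, tol, max_iter, seed, "cALS")
}

#' @export
print.admixture_factors <- function(x, ...) {
  cat(sprintf("admixture_factors (%s): P %d x %d, Q %d x %d\n",
              x$algorithm, nrow(x$P), ncol(x$P), nrow(x$Q), ncol(x$Q)))
  cat(sprintf("  %d sweep(s), converged: %s, final ||F - PQ||: %.6g\n",
              x$iterations, x$converged,
              if (length(x$objective_trace)) utils::tail(x$objective_trace, 1L) else NA))
  invisible(x)
}

#' Fit the admixture model by latent-subspace projection and ALS
#'
#' The full pipeline: (i) estimate the latent row subspace of the admixture
#' proportions from the adjusted Gram matrix of `X`; (ii) project `X/2`
#' onto it to obtain the individual-specific allele frequency estimate
#' `Fhat` (clamped into `[0, 1]`); (iii) factor `Fhat = P Q` under the
#' probabilistic constraints with [tals] (default, fast) or [cals]
#' (monotone descent).
#'
#' @param X genotype matrix (m SNPs x n individuals).
#' @param d number of ancestral populations (`1 <= d <= n`).
#' @param algorithm `"tals"` or `"cals"`.
#' @param tol,max_iter ALS stopping rule: relative Frobenius change of `Q`
#'   between sweeps below `tol`, or `max_iter` sweeps.
#' @param seed integer seed controlling the ALS initialization; fits are
#'   bit-reproducible for a fixed seed.
#' @return object of class `alstructure_fit`: list with `P`, `Q`, `Fhat`
#'   (a `frequency_estimate`), `subspace` (a `latent_subspace`),
#'   `clamped_fraction`, `objective_trace`, `iterations`, `converged`,
#'   `algorithm`, `d`, `tol`, `seed`.
#' @examples
#' sim <- simulate_psd(m = 300, n = 40, d = 2, alpha = c(0.5, 0.5), seed = 7)
#' fit <- fit_alstructure(sim$X, d = 2, seed = 7)
#' colSums(fit$Q)[1:5] # simplex columns
#' @export
fit_alstructure <- function(X, d, algorithm = c("tals", "cals"),
                            tol = 1e-5, max_iter = 1000L, seed = NULL) {
  algorithm <- match.arg(algorithm)
  subspace <- estimate_subspace(X, d)
  Fhat <- project_frequencies(X, subspace, clamp = "unit_interval")
  fac <- if (algorithm == "tals") {
    tals(Fhat, d, tol = tol, max_iter = max_iter, seed = seed)
  } else {
    cals(Fhat, d, tol = tol, max_iter = max_iter, seed = seed)
  }
  if (!is.null(colnames(X))) colnames(fac$Q) <- colnames(X)
  if (!is.null(rownames(X))) rownames(fac$P) <- rownames(X)
  structure(
    list(P = fac$P, Q = fac$Q, Fhat = Fhat, subspace = subspace,
         clamped_fraction = Fhat$clamped_fraction,
         objective_trace = fac$objective_trace,
         iterations = fac$iterations, converged = fac$converged,
         algorithm = fac$algorithm, d = as.integer(d), tol = tol, seed = seed),
    class = "alstructure_fit"
  )
}

#' @export
print.alstructure_fit <- function(x, ...) {
  cat(sprintf("alstructure_fit: %d SNPs, %d individuals, d = %d (%s)\n",
              nrow(x$P), ncol(x$Q), x$d, x$algorithm))
  cat(sprintf("  sweeps: %d (converged: %s); clamped F entries: %.3g%%\n",
              x$iterations, x$converged, 100 * x$clamped_fraction))
  cat("  top eigenvalues of adjusted Gram:",
      format(utils::head(x$subspace$eigenvalues, x$d + 2L), digits = 4), "\n")
  invisible(x)
}
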