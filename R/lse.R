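#' Column-wise heteroscedasticity adjustment
#'
#' For genotype column `j`, computes `delta_j = (1/m) * sum_i (2*x_ij -
#' x_ij^2)`. Because `2x - x^2` equals 1 when `x = 1` and 0 when `x` is 0 or
#' 2, `delta_j` is exactly the fraction of heterozygous genotypes for
#' individual `j`. These form the diagonal correction that distinguishes the
#' adjusted Gram matrix from a plain SNP-wise PCA: under the binomial model
#' the per-entry noise variance depends on the (latent) allele frequency,
#' and subtracting `diag(delta)` removes its expected contribution to the
#' sample covariance.
#'
#' @param X genotype matrix (m SNPs x n individuals).
#' @return numeric vector of length `n`, entries in `[0, 1]`.
#' @export
hetero_adjustment <- function(X) {
  colSums(X * (2 - X)) / nrow(X)
}

#' Heteroscedasticity-adjusted Gram matrix
#'
#' `G = (1/m) X'X - D` with `D = diag(delta)` from [hetero_adjustment].
#' The result is symmetrized exactly (`(G + G')/2`) so eigen-decompositions
#' are reproducible across BLAS backends. `G` may be indefinite — the
#' diagonal subtraction can push trailing eigenvalues below zero — and no
#' positive-semidefinite repair is attempted: only the top-`d` eigenvectors
#' are consumed downstream.
#'
#' @param X genotype matrix.
#' @return `n x n` symmetric matrix.
#' @export
adjusted_gram <- function(X) {
  X <- unclass(X)
  G <- crossprod(X) / nrow(X)
  diag(G) <- diag(G) - hetero_adjustment(X)
  (G + t(G)) / 2
}

#' Estimate the latent row subspace of the admixture proportions
#'
#' The top-`d` eigenvectors of the adjusted Gram matrix [adjusted_gram]
#' consistently span the row space of the true admixture-proportion matrix
#' `Q` as the number of SNPs `m` grows, and the trailing `n - d` eigenvalues
#' shrink to 0. Eigenvector signs are fixed so that each basis vector's
#' largest-magnitude component is positive (ties broken toward the earliest
#' index), making output reproducible across linear-algebra backends.
#'
#' A warning is issued when the spectral gap between the `d`-th and
#' `(d+1)`-th eigenvalues is below `1e-6` times the leading eigenvalue: the
#' subspace is then numerically ill-determined and `d` is likely mischosen.
#'
#' @param X genotype matrix.
#' @param d latent dimension, `1 <= d <= n` (number of ancestral
#'   populations; chosen by the user, e.g. via a structural
#'   Hardy-Weinberg goodness-of-fit scan).
#' @return an object of class `latent_subspace`: list with `basis` (n x d,
#'   orthonormal columns), `eigenvalues` (all n, descending), `d`, and
#'   `hetero_adjust`.
#' @export
estimate_subspace <- function(X, d) {
  n <- ncol(X)
  d <- as.integer(d)
  if (length(d) != 1L || is.na(d) || d < 1L) stop("d must be a positive integer")
  if (d > n) stop(sprintf("d = %d exceeds the number of individuals n = %d", d, n))
  delta <- hetero_adjustment(X)
  G <- adjusted_gram(X)
  eg <- eigen(G, symmetric = TRUE)
  ev <- eg$values
  V <- eg$vectors[, seq_len(d), drop = FALSE]
  V <- fix_signs(V)
  if (d < n && (ev[d] - ev[d + 1L]) < 1e-6 * abs(ev[1L])) {
    warning(sprintf(
      "eigenvalue gap between components %d and %d is below 1e-6 * leading eigenvalue; the d-dimensional subspace is ill-determined",
      d, d + 1L
    ))
  }
  structure(
    list(basis = V, eigenvalues = ev, d = d, hetero_adjust = delta),
    class = "latent_subspace"
  )
}

# Flip each column so its largest-|.| entry is positive; which.max takes the
# earliest index on ties.
fix_signs <- function(V) {
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  V
}

#' @export
print.latent_subspace <- function(x, ...) {
  cat(sprintf("latent_subspace: d = %d basis vectors in R^%d\n", x$d, nrow(x$basis)))
  cat("  top eigenvalues:", format(utils::head(x$eigenvalues, x$d + 2L), digits = 4), "\n")
  invisible(x)
}

#' Latent subspace from a known factor matrix
#'
#' Builds a `latent_subspace` whose basis spans the row space of `M`
#' (typically a true admixture-proportion matrix `Q` from a simulation).
#' Used for oracle projections and for subspace-accuracy diagnostics.
#'
#' @param M `d x n` matrix whose row space is wanted.
#' @return `latent_subspace` with an orthonormal `n x d` basis (eigenvalues
#'   `NA`: no data spectrum is associated).
#' @export
subspace_from_rows <- function(M) {
  qrt <- qr(t(M))
  r <- qrt$rank
  V <- fix_signs(qr.Q(qrt)[, seq_len(r), drop = FALSE])
  structure(
    list(basis = V, eigenvalues = rep(NA_real_, ncol(M)), d = r,
         hetero_adjust = NULL),
    class = "latent_subspace"
  )
}

#' Project genotypes onto a latent subspace to estimate allele frequencies
#'
#' Rows of `X/2` are projected onto the span of the subspace basis:
#' `Fhat = (1/2) X V V'`. When the basis spans the true row space of `Q`
#' this estimator is unbiased for the individual-specific allele frequency
#' matrix `F` and has minimal risk among unbiased row-projection estimators.
#' Projection can leave entries slightly outside `[0, 1]`; with
#' `clamp = "unit_interval"` (the fitting default) they are truncated and
#' the altered fraction is recorded. `clamp = "none"` preserves the exact
#' linear projection (rank at most `d`) for theoretical diagnostics.
#'
#' @param X genotype matrix.
#' @param subspace a `latent_subspace`, or an `n x d` matrix with
#'   orthonormal columns.
#' @param clamp `"unit_interval"` or `"none"`.
#' @return object of class `frequency_estimate`: list with `values`
#'   (m x n), `clamped_fraction`, `d`.
#' @export
project_frequencies <- function(X, subspace, clamp = c("unit_interval", "none")) {
  clamp <- match.arg(clamp)
  V <- if (inherits(subspace, "latent_subspace")) subspace$basis else as.matrix(subspace)
  if (nrow(V) != ncol(X)) {
    stop(sprintf("subspace basis has %d rows but X has %d columns", nrow(V), ncol(X)))
  }
  Z <- 0.5 * (unclass(X) %*% V)
  Fh <- Z %*% t(V)
  cf <- 0
  E <- NULL
  if (clamp == "unit_interval") {
    idx <- which(Fh < 0 | Fh > 1)
    cf <- length(idx) / length(Fh)
    if (length(idx) > 0L) {
      clamped <- pmin(pmax(Fh[idx], 0), 1)
      # sparse correction so that values = Z V' + E exactly; ALS kernels
      # exploit this low-rank-plus-sparse structure on large problems
      E <- Matrix::sparseMatrix(
        i = ((idx - 1L) %% nrow(Fh)) + 1L,
        j = ((idx - 1L) %/% nrow(Fh)) + 1L,
        x = clamped - Fh[idx],
        dims = dim(Fh)
      )
      Fh[idx] <- clamped
    }
  }
  structure(
    list(values = Fh, clamped_fraction = cf, d = ncol(V),
         low_rank = list(Z = Z, V = V, E = E, f2 = sum(Fh^2))),
    class = "frequency_estimate"
  )
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf("frequency_estimate: %d x %d, d = %d, clamped fraction %.3g\n",
              nrow(x$values), ncol(x$values), x$d, x$clamped_fraction))
  invisible(x)
}

# Accept a frequency_estimate or bare matrix.
frequency_values <- function(Fhat) {
  if (inherits(Fhat, "frequency_estimate")) Fhat$values else as.matrix(Fhat)
}

#' Principal angles between two subspaces
#'
#' Canonical angles (radians, ascending) between the column spans of `A`
#' and `B`, computed from the singular values of the product of their
#' orthonormalized bases. The largest angle is the standard measure of
#' subspace estimation error.
#'
#' @param A,B matrices whose column spans are compared (same number of
#'   rows).
#' @return numeric vector of angles in `[0, pi/2]`.
#' @export
principal_angles <- function(A, B) {
  QA <- qr.Q(qr(as.matrix(A)))
  QB <- qr.Q(qr(as.matrix(B)))
  s <- svd(crossprod(QA, QB), nu = 0, nv = 0)$d
  acos(pmin(pmax(s, -1), 1))
}
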