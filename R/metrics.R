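#' Align estimated admixture components to a reference by permutation
#'
#' The admixture factorization is identifiable only up to a simultaneous
#' permutation of `P`'s columns and `Q`'s rows, so estimated components
#' must be matched to reference labels before error metrics mean anything.
#' Finds the row permutation `perm` of `Qhat` minimizing the squared error
#' against `Qtrue`; because the objective separates over matched row pairs
#' this is a linear assignment problem on the pairwise cost matrix
#' `C[k, l] = sum((Qhat[k, ] - Qtrue[l, ])^2)`. Solved exhaustively for
#' `d <= 8` and by an optimal Hungarian (shortest augmenting path) solver
#' for larger `d`; the two coincide.
#'
#' @param Qhat,Qtrue `d x n` matrices.
#' @param method `"auto"` (exhaustive up to d = 8), `"exhaustive"`, or
#'   `"hungarian"`.
#' @return integer permutation `perm` such that `Qhat[perm, ]` is the best
#'   match to `Qtrue` (row `perm[k]` of `Qhat` pairs with row `k` of
#'   `Qtrue`).
#' @export
align_factors <- function(Qhat, Qtrue,
                          method = c("auto", "exhaustive", "hungarian")) {
  method <- match.arg(method)
  Qhat <- as.matrix(Qhat); Qtrue <- as.matrix(Qtrue)
  if (!all(dim(Qhat) == dim(Qtrue))) {
    stop("Qhat and Qtrue must have identical dimensions")
  }
  d <- nrow(Qhat)
  # C[k, l]: cost of pairing estimated row k with true row l
  C <- outer(rowSums(Qhat^2), rep(1, d)) +
    outer(rep(1, d), rowSums(Qtrue^2)) -
    2 * tcrossprod(Qhat, Qtrue)
  if (method == "auto") method <- if (d <= 8L) "exhaustive" else "hungarian"
  if (method == "exhaustive") {
    perms <- permutations(d)
    costs <- vapply(perms, function(p) sum(C[cbind(p, seq_len(d))]), numeric(1L))
    perms[[which.min(costs)]]
  } else {
    solve_assignment(t(C))
  }
}

# All permutations of 1..n, in a stable order.
permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(i, rest[p])
    }
  }
  out
}

#' Root mean squared error between admixture-proportion matrices
#'
#' `sqrt((1/(d*n)) * sum((qhat_kj - q_kj)^2))`, by default computed after
#' optimal permutation alignment of the estimated rows ([align_factors]).
#' The error definition itself does not fix a labeling; set
#' `aligned = FALSE` to compare under the given labeling.
#'
#' @param Qhat,Qtrue `d x n` matrices.
#' @param aligned align rows before measuring (default `TRUE`).
#' @return non-negative scalar.
#' @export
rmse <- function(Qhat, Qtrue, aligned = TRUE) {
  if (aligned) Qhat <- Qhat[align_factors(Qhat, Qtrue), , drop = FALSE]
  sqrt(mean((Qhat - Qtrue)^2))
}

#' Mean absolute error between admixture-proportion matrices
#'
#' `(1/(d*n)) * sum(|qhat_kj - q_kj|)`, aligned as in [rmse].
#'
#' @inheritParams rmse
#' @return non-negative scalar.
#' @export
mae <- function(Qhat, Qtrue, aligned = TRUE) {
  if (aligned) Qhat <- Qhat[align_factors(Qhat, Qtrue), , drop = FALSE]
  mean(abs(Qhat - Qtrue))
}

#' Mean per-observation binomial log-likelihood of a frequency fit
#'
#' `(1/(m*n)) * sum log P(x_ij | 2, fhat_ij)` under the binomial genotype
#' model, including the binomial coefficient (`log 2` for heterozygotes) so
#' values are comparable across methods. Frequencies are bounded into
#' `[eps, 1 - eps]` before taking logs; entries outside `[0, 1]` are an
#' error (clamp the frequency estimate first).
#'
#' @param X genotype matrix.
#' @param Fhat `frequency_estimate` or bare matrix of the same shape.
#' @param eps likelihood bounding constant.
#' @return scalar `<= 0` (multiply by `m*n` for the full-data
#'   log-likelihood).
#' @export
mean_loglik <- function(X, Fhat, eps = 1e-8) {
  Fm <- frequency_values(Fhat)
  if (!all(dim(Fm) == dim(X))) stop("X and Fhat must have identical dimensions")
  if (any(Fm < 0 | Fm > 1)) {
    stop("frequency estimate has entries outside [0, 1]; clamp before computing likelihoods")
  }
  Fm <- pmin(pmax(Fm, eps), 1 - eps)
  mean(stats::dbinom(as.vector(unclass(X)), 2L, as.vector(Fm), log = TRUE))
}

#' Variation explained by each admixture component
#'
#' `s_k^2 = || X q_k ||^2` for each row `q_k` of `Qhat`: the squared norm
#' of the genotype matrix projected along that component. Sorting
#' components by decreasing `s^2` gives a deterministic output ordering
#' under the model's permutation nonidentifiability.
#'
#' @param X genotype matrix (m x n).
#' @param Qhat `d x n` admixture-proportion matrix.
#' @return numeric vector of length `d`.
#' @export
variation_explained <- function(X, Qhat) {
  if (ncol(X) != ncol(Qhat)) stop("X and Qhat must agree on the number of individuals")
  colSums((unclass(X) %*% t(Qhat))^2)
}

#' Full metric report for a fit against simulation truth
#'
#' Convenience wrapper: permutation alignment, aligned RMSE and MAE, and —
#' when genotype data are supplied — mean per-observation log-likelihood
#' (requires the fitted frequency matrix) and per-component variation
#' explained.
#'
#' @param Qhat,Qtrue `d x n` admixture-proportion matrices.
#' @param X optional genotype matrix.
#' @param Fhat optional frequency estimate (for the likelihood).
#' @return object of class `fit_metrics`: list with `rmse`, `mae`,
#'   `alignment`, and optionally `mean_loglik`, `variation_explained`.
#' @export
fit_metrics <- function(Qhat, Qtrue, X = NULL, Fhat = NULL) {
  perm <- align_factors(Qhat, Qtrue)
  Qa <- Qhat[perm, , drop = FALSE]
  out <- list(
    rmse = sqrt(mean((Qa - Qtrue)^2)),
    mae = mean(abs(Qa - Qtrue)),
    alignment = perm
  )
  if (!is.null(X) && !is.null(Fhat)) out$mean_loglik <- mean_loglik(X, Fhat)
  if (!is.null(X)) out$variation_explained <- variation_explained(X, Qa)
  structure(out, class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("fit_metrics: RMSE %.6g, MAE %.6g (alignment %s)\n",
              x$rmse, x$mae, paste(x$alignment, collapse = " ")))
  if (!is.null(x$mean_loglik)) cat(sprintf("  mean log-likelihood: %.4f\n", x$mean_loglik))
  invisible(x)
}

#' Check the anchor-individuals identifiability condition
#'
#' An anchor individual derives their entire genome from one ancestral
#' population (their admixture column sits on a simplex vertex). If every
#' population has at least one anchor (within tolerance), the admixture
#' factorization is identifiable up to permutation. Diagnostic only: the
#' fitting pipeline does not require anchors.
#'
#' @param Q `d x n` admixture-proportion matrix (columns on the simplex).
#' @param tol vertex tolerance: individual `j` anchors population `k` when
#'   `q_kj >= 1 - tol`.
#' @return list with `satisfied` (logical) and `witnesses` (length-`d`
#'   integer vector of one anchor column per population, `NA` where none).
#' @export
check_anchor_individuals <- function(Q, tol = 0.05) {
  d <- nrow(Q)
  witnesses <- vapply(seq_len(d), function(k) {
    j <- which(Q[k, ] >= 1 - tol)
    if (length(j) > 0L) j[1L] else NA_integer_
  }, integer(1L))
  list(satisfied = !anyNA(witnesses), witnesses = witnesses)
}

#' Check the anchor-SNPs identifiability condition
#'
#' An anchor SNP is fixed (frequency 0 or 1, within tolerance) in every
#' ancestral population except one. One anchor SNP per population likewise
#' makes the factorization identifiable up to permutation.
#'
#' @param P `m x d` ancestral allele-frequency matrix.
#' @param tol fixation tolerance on `|p|` and `|1 - p|`.
#' @return list with `satisfied` and `witnesses` (one anchor SNP row per
#'   population, `NA` where none).
#' @export
check_anchor_snps <- function(P, tol = 0.05) {
  fixed <- pmin(P, 1 - P) <= tol
  witnesses <- vapply(seq_len(ncol(P)), function(k) {
    i <- which(!fixed[, k] & rowSums(fixed) == ncol(P) - 1L)
    if (length(i) > 0L) i[1L] else NA_integer_
  }, integer(1L))
  list(satisfied = !anyNA(witnesses), witnesses = witnesses)
}
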