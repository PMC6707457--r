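#' Draws from the Balding-Nichols allele-frequency distribution
#'
#' Balding-Nichols(F, p) is the Beta distribution reparameterized by the
#' per-SNP fixation index `F` (FST) and the ancestral allele frequency `p`:
#' `Beta(((1 - F)/F) * p, ((1 - F)/F) * (1 - p))`. Its mean is `p` and its
#' variance `F * p * (1 - p)`, so `F` controls how far derived population
#' frequencies drift from the ancestral value. Draws numerically equal to 0
#' or 1 are nudged into `[1e-12, 1 - 1e-12]` to keep downstream frequency
#' products interior.
#'
#' @param fst fixation index, strictly inside `(0, 1)` (degenerate Beta at
#'   the endpoints). Vectors are recycled against `count`.
#' @param p ancestral allele frequency, strictly inside `(0, 1)`.
#' @param count number of draws.
#' @return numeric vector of `count` frequencies in `(0, 1)`.
#' @export
sample_balding_nichols <- function(fst, p, count) {
  if (any(fst <= 0 | fst >= 1)) stop("fst must lie strictly inside (0, 1)")
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0, 1)")
  ab <- (1 - fst) / fst
  draws <- stats::rbeta(count, ab * p, ab * (1 - p))
  pmin(pmax(draws, 1e-12), 1 - 1e-12)
}

#' Dirichlet concentration prototypes for simulation studies
#'
#' Four qualitatively different admixture regimes on the simplex:
#' `a1 = (10, ..., 10)` concentrates individuals near the simplex center
#' (heavy admixture), `a2 = (1, ..., 1)` is uniform, `a3 = (0.1, ..., 0.1)`
#' pushes individuals toward vertices and edges (near-anchor individuals),
#' and `a4` is the asymmetric prototype `(10, 1, 0.1)` extended in blocks:
#' for `d` divisible by 3, each of `10, 1, 0.1` is repeated `d/3` times
#' (e.g. `d = 6` gives `(10, 10, 1, 1, 0.1, 0.1)`).
#'
#' @param name one of `"a1"`, `"a2"`, `"a3"`, `"a4"`.
#' @param d number of ancestral populations (`a4` requires `d` divisible
#'   by 3).
#' @return numeric vector of length `d`.
#' @export
alpha_prototype <- function(name = c("a1", "a2", "a3", "a4"), d = 3L) {
  name <- match.arg(name)
  d <- as.integer(d)
  if (d < 1L) stop("d must be >= 1")
  switch(name,
    a1 = rep(10, d),
    a2 = rep(1, d),
    a3 = rep(0.1, d),
    a4 = {
      if (d %% 3L != 0L) {
        stop("the a4 prototype extends in blocks of (10, 1, 0.1); d must be divisible by 3")
      }
      rep(c(10, 1, 0.1), each = d %/% 3L)
    }
  )
}

#' Default per-SNP Balding-Nichols parameters
#'
#' Draws `p_i ~ Uniform(0.1, 0.9)` and `F_i ~ Uniform(0.01, 0.2)`, ranges
#' typical of common human SNPs. This is a documented synthetic proxy for
#' parameter vectors estimated from a real reference panel (such panels
#' are not bundled); supply your own `bn_fst`/`bn_maf` vectors to
#' [simulate_psd] to use empirical estimates.
#'
#' @param m number of SNPs.
#' @return list with numeric vectors `fst` (in `[0.01, 0.2]`) and `maf`
#'   (in `[0.1, 0.9]`), each of length `m`. Uses the current RNG state;
#'   seed beforehand for reproducibility.
#' @export
default_bn_params <- function(m) {
  list(fst = stats::runif(m, 0.01, 0.2),
       maf = stats::runif(m, 0.1, 0.9))
}

# Dirichlet draws via normalized gamma variates; columns on the simplex.
rdirichlet_cols <- function(n, alpha) {
  d <- length(alpha)
  G <- matrix(stats::rgamma(d * n, shape = alpha), d, n)
  cs <- colSums(G)
  zero <- cs <= 0
  if (any(zero)) { # all-component underflow; vanishingly rare at alpha >= 0.1
    G[, zero] <- 1
    cs[zero] <- d
  }
  sweep(G, 2L, cs, "/")
}

# Shared tail: draw P rows from Balding-Nichols, form F = P Q blockwise
# (column blocks keep the column-major RNG stream identical regardless of
# blocking), draw X ~ Binomial(2, F).
simulate_admixture_tail <- function(Q, m, n, d, bn, keep_F, block_cols = 250L) {
  ab <- (1 - bn$fst) / bn$fst
  P <- matrix(stats::rbeta(m * d, ab * bn$maf, ab * (1 - bn$maf)), m, d)
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  X <- matrix(0, m, n)
  Ffull <- if (keep_F) matrix(0, m, n) else NULL
  j <- 1L
  while (j <= n) {
    cols <- j:min(j + block_cols - 1L, n)
    Fb <- P %*% Q[, cols, drop = FALSE]
    X[, cols] <- stats::rbinom(m * length(cols), 2L, Fb)
    if (keep_F) Ffull[, cols] <- Fb
    j <- j + block_cols
  }
  list(P = P, F = Ffull, X = X)
}

#' Simulate genotypes from the PSD admixture model
#'
#' The Pritchard-Stephens-Donnelly generative model: admixture columns
#' `q_j ~ Dirichlet(alpha)`, ancestral frequencies
#' `p_ik ~ Balding-Nichols(F_i, p_i)` independently across the `d`
#' populations, individual-specific frequencies `F = P Q`, genotypes
#' `x_ij ~ Binomial(2, f_ij)` independently. Balding-Nichols parameters
#' default to the synthetic proxy of [default_bn_params].
#'
#' @param m number of SNPs.
#' @param n number of individuals.
#' @param d number of ancestral populations.
#' @param alpha Dirichlet concentration vector of length `d` (or a
#'   prototype name accepted by [alpha_prototype]).
#' @param bn_fst,bn_maf optional length-`m` vectors of per-SNP FST and
#'   ancestral frequencies.
#' @param seed integer seed; the full output is reproducible from it.
#' @param keep_F keep the `m x n` frequency matrix in the result (set
#'   `FALSE` to save memory on large designs; all other outputs are
#'   bit-identical either way).
#' @return object of class `sim_truth`: list with `X` (a
#'   [genotype_matrix]), `P`, `Q`, `F` (or `NULL`), and `params`.
#' @examples
#' sim <- simulate_psd(m = 200, n = 30, d = 3, alpha = "a2", seed = 1)
#' range(colSums(sim$Q)) # exactly 1
#' @export
simulate_psd <- function(m, n, d, alpha = "a2", bn_fst = NULL, bn_maf = NULL,
                         seed = NULL, keep_F = TRUE) {
  m <- as.integer(m); n <- as.integer(n); d <- as.integer(d)
  if (m < 1L || n < 1L || d < 1L) stop("m, n and d must be positive")
  if (is.character(alpha)) alpha <- alpha_prototype(alpha, d)
  if (length(alpha) != d) stop("alpha must have length d")
  if (any(alpha <= 0)) stop("alpha entries must be positive")
  if (!is.null(seed)) set.seed(seed)
  bn <- resolve_bn(m, bn_fst, bn_maf)
  Q <- rdirichlet_cols(n, alpha)
  tail <- simulate_admixture_tail(Q, m, n, d, bn, keep_F)
  structure(
    list(X = new_genotype_matrix(tail$X), P = tail$P, Q = Q, F = tail$F,
         params = list(model = "psd", m = m, n = n, d = d, alpha = alpha,
                       bn_fst = bn$fst, bn_maf = bn$maf, seed = seed)),
    class = "sim_truth"
  )
}

resolve_bn <- function(m, bn_fst, bn_maf) {
  if (is.null(bn_fst) != is.null(bn_maf)) {
    stop("supply both bn_fst and bn_maf, or neither")
  }
  if (is.null(bn_fst)) return(default_bn_params(m))
  if (length(bn_fst) != m || length(bn_maf) != m) {
    stop("bn_fst and bn_maf must have length m")
  }
  if (any(bn_fst <= 0 | bn_fst >= 1)) stop("bn_fst entries must lie in (0, 1)")
  if (any(bn_maf <= 0 | bn_maf >= 1)) stop("bn_maf entries must lie in (0, 1)")
  list(fst = bn_fst, maf = bn_maf)
}

#' Simulate genotypes from the spatial-diffusion admixture model
#'
#' `d` unadmixed ancestral populations sit at unit-spaced positions
#' `x0, x0 + 1, ..., x0 + d - 1` on a line and diffuse as Gaussians with a
#' common SD `sigma`. An individual sampled at position `x` has admixture
#' proportions proportional to the Gaussian densities:
#' `q_k(x) = phi((x - mu_k)/sigma) / sum_l phi((x - mu_l)/sigma)`.
#' The columns of `Q` therefore lie on a one-dimensional curve inside the
#' simplex — a deliberately hard regime for subspace-based fitting, since
#' the data only weakly spans the full `d`-dimensional subspace when
#' `sigma` is large. Ancestral frequencies and genotypes are drawn as in
#' [simulate_psd]. Only relative positions matter: translating `x0` and
#' the sampling positions together leaves `Q` unchanged.
#'
#' @inheritParams simulate_psd
#' @param sigma diffusion SD (same units as the unit population spacing).
#' @param x0 position of the leftmost population mean.
#' @param positions optional length-`n` sampling positions; default is a
#'   uniform grid spanning `[mu_1 - 2*sigma, mu_d + 2*sigma]`. Set
#'   `position_method = "uniform"` for uniform-random positions over the
#'   same interval.
#' @param position_method `"grid"` or `"uniform"` (ignored when
#'   `positions` is supplied).
#' @return object of class `sim_truth` (see [simulate_psd]); `params`
#'   additionally records `sigma` and the positions used.
#' @export
simulate_spatial <- function(m, n, d = 3L, sigma = 1, x0 = 0,
                             positions = NULL,
                             position_method = c("grid", "uniform"),
                             bn_fst = NULL, bn_maf = NULL,
                             seed = NULL, keep_F = TRUE) {
  m <- as.integer(m); n <- as.integer(n); d <- as.integer(d)
  position_method <- match.arg(position_method)
  if (m < 1L || n < 1L) stop("m and n must be positive")
  if (d < 2L) stop("the spatial model needs at least d = 2 populations")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a positive scalar")
  }
  if (!is.null(seed)) set.seed(seed)
  mu <- x0 + seq_len(d) - 1
  if (is.null(positions)) {
    lo <- mu[1L] - 2 * sigma
    hi <- mu[d] + 2 * sigma
    positions <- if (position_method == "grid") {
      seq(lo, hi, length.out = n)
    } else {
      stats::runif(n, lo, hi)
    }
  }
  if (length(positions) != n) stop("positions must have length n")
  W <- vapply(positions, function(x) stats::dnorm(x, mu, sigma), numeric(d))
  W <- matrix(W, d, n)
  Q <- sweep(W, 2L, colSums(W), "/")
  bn <- resolve_bn(m, bn_fst, bn_maf)
  tail <- simulate_admixture_tail(Q, m, n, d, bn, keep_F)
  structure(
    list(X = new_genotype_matrix(tail$X), P = tail$P, Q = Q, F = tail$F,
         params = list(model = "spatial", m = m, n = n, d = d, sigma = sigma,
                       x0 = x0, positions = positions, seed = seed)),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  p <- x$params
  cat(sprintf("sim_truth (%s model): m = %d SNPs, n = %d individuals, d = %d\n",
              p$model, p$m, p$n, p$d))
  if (p$model == "psd") cat("  alpha:", format(p$alpha), "\n")
  if (p$model == "spatial") cat("  sigma:", format(p$sigma), "\n")
  invisible(x)
}
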