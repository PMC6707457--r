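# Independent brute-force oracles used to cross-check the package's
# optimized routines. These deliberately share no code with the
# implementation paths they verify.

# Simplex projection oracle: min ||v - w||^2 s.t. w >= 0, sum w = 1,
# by KKT enumeration over all non-empty supports S:
#   w_S = v_S - (sum(v_S) - 1)/|S|, w = 0 off S;
# accept when w_S >= 0 and v_i - tau <= 0 for i outside S.
oracle_simplex_projection <- function(v) {
  d <- length(v)
  best <- NULL
  best_obj <- Inf
  for (mask in seq_len(2^d - 1L)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, 0:(d - 1L))) > 0L)
    tau <- (sum(v[S]) - 1) / length(S)
    w <- numeric(d)
    w[S] <- v[S] - tau
    if (any(w[S] < -1e-12)) next
    if (any(v[-S] - tau > 1e-12)) next
    obj <- sum((v - w)^2)
    if (obj < best_obj) {
      best_obj <- obj
      best <- w
    }
  }
  best
}

# Exhaustive minimum-cost assignment: a[i] = column for row i.
oracle_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- all_perms(n)
  costs <- vapply(perms, function(p) sum(cost[cbind(seq_len(n), p)]), numeric(1L))
  perms[[which.min(costs)]]
}

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- list()
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- c(out, lapply(sub, function(p) c(i, rest[p])))
  }
  out
}

# Dense-matrix objective, used to audit ALS traces independently of the
# structured kernels.
oracle_frobenius <- function(Fm, P, Q) sqrt(sum((Fm - P %*% Q)^2))

# A tiny bi-allelic VCF with the given GT strings (sites x samples).
write_tiny_vcf <- function(path, gt) {
  n <- ncol(gt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("s", seq_len(n))), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(gt)), function(i) {
    paste(c("1", as.character(i * 100L), paste0("rs", i), "A", "G", ".",
            "PASS", ".", "GT", gt[i, ]), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  path
}

# Noiseless admixture factorization instance with planted anchor
# individuals (one pure column per population). Ancestral populations are
# strongly diverged (FST 0.3-0.5) so that P is well-conditioned: the ALS
# convergence rate to an exact factorization degrades as P's columns become
# collinear, which is a property of alternating least squares, not of the
# constraint handling this instance is designed to verify.
make_noiseless_instance <- function(m, n, d, alpha = rep(1, d), seed = 1) {
  set.seed(seed)
  fst <- runif(m, 0.3, 0.5)
  maf <- runif(m, 0.1, 0.9)
  ab <- (1 - fst) / fst
  P <- matrix(rbeta(m * d, ab * maf, ab * (1 - maf)), m, d)
  G <- matrix(rgamma(d * n, shape = alpha), d, n)
  Q <- sweep(G, 2L, colSums(G), "/")
  Q[, seq_len(d)] <- diag(d) # anchors: identifiable up to permutation
  list(P = P, Q = Q, F = P %*% Q)
}
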