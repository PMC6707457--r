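---
title: "Methods: likelihood-free fitting of the admixture model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: likelihood-free fitting of the admixture model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alstruct)
```

## The model

The observed data are an $m \times n$ genotype matrix $X$ with $m$ SNPs in
rows and $n$ individuals in columns; entry $x_{ij} \in \{0, 1, 2\}$ counts
reference alleles. Under the admixture model each genotype is drawn
independently as

$$x_{ij} \mid f_{ij} \sim \mathrm{Binomial}(2, f_{ij}),$$

where $F = (f_{ij})$ is the matrix of individual-specific allele
frequencies. $F$ is assumed to have low rank $d \ll n \ll m$ and to factor
as $F = PQ$ with

- $P$ ($m \times d$): ancestral allele frequencies, every entry in
  $[0, 1]$ (the *cube* constraint);
- $Q$ ($d \times n$): admixture proportions, entries non-negative with
  every column summing to 1 (the *simplex* constraint).

$d$ is the number of ancestral populations and is a **user input**
throughout this package: selecting it (for instance with a structural
Hardy–Weinberg goodness-of-fit scan across candidate $d$) is out of scope.

The binomial assumption is no more than independence of the two alleles;
nothing parametric is assumed about $P$ or $Q$, and the likelihood surface
is never searched. The fit is instead derived from three observations:

1. **Subspace.** Because $F = PQ$, the rows of $F$ lie in the row space
   $\langle Q \rangle$. That space can be estimated consistently from the
   data alone (below), which converts the problem of estimating $F$ into a
   projection.
2. **Projection.** $X/2$ is unbiased for $F$; projecting its rows onto
   $\langle Q \rangle$ keeps unbiasedness while minimizing risk among
   row-projection estimators. Projection onto any *larger* subspace stays
   unbiased but fits extra noise; onto any *smaller* one is biased. Both
   facts are exercised by the test suite as Monte-Carlo checks.
3. **Factorization.** Given $\hat F$, estimating $(P, Q)$ is a constrained
   low-rank factorization problem,
   $\min_{P, Q} \lVert \hat F - PQ \rVert_F$ subject to the cube and
   simplex constraints, solved by alternating least squares.

## Subspace estimation

Plain SNP-wise PCA of $\tfrac1m X^\top X$ is biased by the binomial noise
variance, which differs by column. The correction subtracts each column's
average heterozygosity: with
$\hat\delta_j = \tfrac1m \sum_i (2 x_{ij} - x_{ij}^2)$ — identically the
fraction of heterozygous genotypes in column $j$ — form

$$G = \tfrac1m X^\top X - \mathrm{diag}(\hat\delta).$$

The top-$d$ eigenvectors of $G$ span a consistent estimate of
$\langle Q \rangle$ as $m \to \infty$, and the trailing $n - d$ eigenvalues
shrink to zero — both verified empirically in the acceptance tests on a
ladder of $m$ values. Numerical choices:

- the eigen-decomposition is the full symmetric one (`eigen(symmetric =
  TRUE)`); $n$ is at most a few thousand in the intended regime, so this
  is cheap next to forming $X^\top X$;
- $G$ is symmetrized exactly and may be indefinite; no repair is
  attempted since only the leading eigenvectors are used;
- eigenvector signs are fixed (largest-magnitude entry positive, ties to
  the earliest index) so output is reproducible across BLAS backends;
- when the gap between the $d$-th and $(d{+}1)$-th eigenvalues falls below
  $10^{-6} \lambda_1$ the subspace is ill-determined and a warning is
  raised rather than silently picking a direction.

The frequency estimate is $\hat F = \tfrac12 X V V^\top$ with $V$ the
$n \times d$ basis. Projection can leave entries slightly outside
$[0, 1]$; the fitting default truncates them into the interval and
reports the altered fraction (typically well under 1%). For likelihood
evaluation, frequencies are further bounded into
$[\varepsilon, 1 - \varepsilon]$ with $\varepsilon = 10^{-8}$ to keep log
terms finite. An unclamped mode is kept for theoretical diagnostics,
where $\hat F$ has exact rank $\le d$.

### Structured representation

After clamping, $\hat F = Z V^\top + E$ with $Z = \tfrac12 X V$
($m \times d$) and $E$ the sparse matrix of clamping corrections. The ALS
sweeps touch $\hat F$ only through products $W^\top \hat F$ and
$\hat F M$ with thin matrices, so the engine evaluates those products
through the structure instead of streaming the dense $m \times n$ matrix.
This is exact algebra — the test suite checks the structured and dense
paths agree to machine precision — and is the reason the constrained
algorithm is practical at full study sizes.

## Alternating least squares

Both algorithms initialize $\hat P$ with i.i.d. Uniform$(0,1)$ entries
from a seeded generator (arbitrary initialization is permitted; uniform
draws respect the cube constraint and make runs reproducible), then
alternate updates of $Q$ and $P$ (in that order) until the relative
Frobenius change of $\hat Q$ between sweeps falls below `tol` (default
$10^{-5}$) or `max_iter` (default 1000) sweeps elapse. $\hat Q$ is the
quantity of interest and is scale-free, which is why the stopping rule
watches it; the model itself prescribes no criterion, so this is a
declared package decision.

**Truncated ALS (`tals`, default).** Each update solves the
*unconstrained* least-squares problem via a thin QR decomposition (with a
minimum-norm SVD fallback for rank-deficient blocks), then repairs
feasibility: columns of $Q^\*$ are projected onto the probability simplex
by the sort-and-threshold algorithm, and $P^\*$ is truncated entrywise
into $[0, 1]$. Fast, but the repairs can perturb the objective, so the
recorded trace is not guaranteed monotone.

**Constrained ALS (`cals`).** Each update solves its convex subproblem
*exactly*: per column of $Q$ a simplex-constrained least-squares QP,
per row of $P$ a box-constrained one. Block-optimal updates cannot
increase the objective, so the trace is non-increasing (asserted to
$10^{-9}$ in the tests) and limit points are stationary points of the
constrained problem. The subproblems are solved by exact KKT methods
written for the small $d$ of admixture models: support enumeration for
the simplex QP ($2^d - 1$ supports, solved grouped across columns), and
grouped block-pivoting with an enumeration fallback for the box QP. Both
are validated against brute-force KKT oracles.

Degenerate states are handled explicitly: a $\hat Q$ row that loses all
mass (a population with no assigned ancestry) cannot recover through
least squares, so it is re-seeded from the running generator with a
warning. With $d = 1$ the simplex is the single point $\{1\}$ and
$\hat Q$ is exactly the all-ones row.

Label order is *not* resolved inside the fitting routines — the
factorization is identifiable only up to permutation, so any ordering
would be arbitrary. The command-line `fit` orders output components by
decreasing variation explained $s_k^2 = \lVert X q_k^\top \rVert^2$;
metric functions align estimate to truth by optimal assignment before
measuring.

### Convergence and conditioning

On noiseless inputs $\hat F = PQ$ with anchor individuals present, both
algorithms recover the factors up to permutation. The *rate* depends
strongly on the conditioning of $P$: when ancestral populations are
weakly diverged ($F_{ST} \lesssim 0.1$) the columns of $P$ are nearly
collinear and plain ALS approaches the exact factorization sublinearly —
tens of thousands of sweeps may still leave errors near $10^{-2}$. With
strongly diverged populations ($F_{ST} \approx 0.3$–$0.5$) recovery to
$10^{-6}$ takes a few thousand sweeps. The exact-recovery tests therefore
use strongly diverged instances; this is a known limitation of
alternating least squares, not of the constraint handling.

## Simulators

`simulate_psd` draws the classical Dirichlet–Balding-Nichols generative
model: $q_{\cdot j} \sim \mathrm{Dirichlet}(\alpha)$,
$p_{ik} \sim \mathrm{BN}(F_i, p_i) =
\mathrm{Beta}\big(\tfrac{1-F_i}{F_i} p_i, \tfrac{1-F_i}{F_i}(1-p_i)\big)$,
$x_{ij} \sim \mathrm{Binomial}(2, (PQ)_{ij})$. The four concentration
prototypes `a1`–`a4` (`alpha_prototype`) reproduce the standard simulation
regimes: center-concentrated, uniform, vertex-concentrated, and
asymmetric, extended in blocks for $d > 3$.

Per-SNP Balding-Nichols parameters default to a **synthetic proxy**:
$p_i \sim U(0.1, 0.9)$, $F_i \sim U(0.01, 0.2)$, ranges typical of common
human SNPs. Published simulation studies instead resample $(F_i, p_i)$
estimated from a reference panel; no such panel is bundled, so users with
empirical estimates should pass them via `bn_fst`/`bn_maf`. Consequences
of the proxy: headline error numbers carry extra run-to-run spread, and
simulated SNPs are exchangeable (no frequency spectrum shape, no linkage
disequilibrium — sites are independent by construction). Passing tests
demonstrate correctness of the machinery under the admixture model, not
robustness to the LD, missingness, and ascertainment structure of real
genotype panels.

`simulate_spatial` places $d$ populations at unit spacing on a line,
diffusing as Gaussians with common SD $\sigma$; an individual at position
$x$ has $q_k(x) \propto \phi((x - \mu_k)/\sigma)$. Its admixture columns
lie on a one-dimensional curve inside the simplex, deliberately straining
the $d$-dimensional-subspace assumption. Sampling positions default to a
uniform grid over $[\mu_1 - 2\sigma, \mu_d + 2\sigma]$ (a uniform-random
option exists); the leftmost mean defaults to $x_0 = 0$ since the model
is translation invariant — both are declared choices where the model
itself is silent. Draws numerically equal to 0 or 1 are nudged into
$[10^{-12}, 1 - 10^{-12}]$ so $F$ stays interior.

Genotype sampling is chunked by column blocks so that the RNG stream is
identical whether or not the dense $F$ matrix is retained (`keep_F`);
large-design memory use is a choice with no effect on output.

## Metrics

Errors on admixture proportions are
$\mathrm{RMSE} = \sqrt{\tfrac{1}{dn} \sum_{k,j} (\hat q_{kj} - q_{kj})^2}$
and $\mathrm{MAE} = \tfrac{1}{dn} \sum_{k,j} |\hat q_{kj} - q_{kj}|$,
computed **after** optimal row alignment by default: under permutation
nonidentifiability an unaligned comparison is meaningless, though the
unaligned mode is exposed. Alignment minimizes total squared error, which
separates over matched rows, so it is a linear assignment problem: solved
exhaustively for $d \le 8$ and by a Hungarian
shortest-augmenting-path solver above that (the two coincide, which is
itself tested). The mean per-observation log-likelihood
$\tfrac{1}{mn} \sum \log \Pr(x_{ij} \mid 2, \hat f_{ij})$ includes the
binomial coefficient ($\log 2$ for heterozygotes) so values are
comparable across methods. Anchor diagnostics report, per population,
a witness individual with $q_{kj} \ge 1 - \mathrm{tol}$ (or a witness
SNP fixed everywhere but in one population), with a default tolerance of
0.05 on both sides.

## Problem sizes exercised by the tests

The acceptance suite runs the full example design ($m = 10^5$, $n = 500$,
$d = 3$, $\alpha = (0.1, 0.1, 0.1)$, five seeds, both algorithms), a
subspace-consistency ladder $m \in \{5 \times 10^3, 5 \times 10^4,
5 \times 10^5\}$ at $n = 200$, a 200-replicate unbiasedness/risk Monte
Carlo at $m = 5 \times 10^4$, and the spatial stress design ($m = 10^5$,
$n = 10^3$, $\sigma \in \{0.5, 2\}$, three seeds). These sizes were chosen
to match the simulation designs the package reproduces while keeping a
full run of the suite in the tens of minutes on a single core; unit tests
use miniatures of the same generators.

## Known limitations

- $d$ must be supplied; a mischosen $d$ manifests as a small spectral gap
  (warned) and degraded fits.
- Missing genotypes are either rejected or mean-imputed per SNP; the
  imputation is a convenience outside the model, appropriate only for
  low missingness.
- ALS convergence slows markedly when populations are weakly diverged
  (see above) or when admixture columns concentrate on a low-dimensional
  curve (spatial model with large $\sigma$, where fits can fail outright
  — reproduced deliberately in the acceptance tests).
- Monomorphic SNPs are retained (they carry no structure information but
  do not bias the subspace); multi-allelic sites, half-calls and phased
  haplotype structure are out of scope, as are PLINK binary formats.
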