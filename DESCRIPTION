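Package: alstruct
Title: Likelihood-Free Estimation of Global Ancestry Under the Admixture Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits the admixture model to SNP genotype matrices without using
    the likelihood surface. Individual-specific allele frequencies are
    estimated by projecting genotypes onto a consistently estimated latent
    subspace (a heteroscedasticity-adjusted PCA of the sample covariance),
    then factored into ancestral allele frequencies and admixture
    proportions by alternating least squares under probabilistic
    constraints. Includes Pritchard-Stephens-Donnelly (Dirichlet plus
    Balding-Nichols) and spatial-diffusion simulators with ground truth,
    permutation-aligned error metrics, anchor diagnostics, and a
    command-line interface for the simulate/fit/evaluate workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    Matrix,
    optparse,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
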