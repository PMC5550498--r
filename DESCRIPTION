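Package: stpois
Title: Bayesian Spatiotemporal Poisson Models for Areal Count Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hierarchical Bayesian Poisson space-time regression for areal
    count panels (disease mapping). Implements BYM-type convolution models
    with intrinsic CAR spatial effects, a parametric linear time trend with
    area-specific differential deviations, second-order random-walk (RW2)
    non-linear covariate effects and a dynamic RW2 time trend, fitted by an
    adaptive Metropolis-within-Gibbs sampler with conjugate precision
    updates and DIC model comparison. Also provides exploratory spatial
    statistics (univariate and bivariate Moran's I with permutation
    inference, Spearman screening), queen-contiguity weights from polygons
    or GAL files, GMRF structure matrices with null-space constraints and
    geometric-mean variance scaling, and a synthetic-panel generator for
    simulation studies and parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
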