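Package: matevolve
Title: Joint Evolution of Maternal Effects, Plasticity and Genetic
    Adaptation in Changing Environments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative-genetics machinery for studying how maternal
    effect coefficients, within-generation phenotypic plasticity and
    genetic reaction-norm elevation evolve jointly under Gaussian
    stabilizing selection on a moving optimum.  Provides a deterministic
    recursion engine based on the multivariate breeder's equation with a
    Gaussian moment closure for the maternal-inheritance variance
    cascade, an individual-based forward simulator (diploid
    hermaphrodites, three unlinked loci, continuum-of-alleles mutation),
    generators for constant, step, sinusoidal, stochastic and two-patch
    environments with autocorrelated background noise, scenario presets,
    parameter sweeps, and steady-cycle summary statistics.  The two
    engines cross-validate each other.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
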