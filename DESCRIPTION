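Package: thccorrect
Title: Machine-Learned Correction of Tensor-Hypercontraction Errors in
    MP2/MP3 Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Least-squares tensor hypercontraction (LS-THC) approximations to
    density-fitted second- and third-order Moller-Plesset perturbation theory
    (DF-MP2/MP3) with the full ten-component diagrammatic decomposition of the
    MP3 correlation energy, and a regression layer (component-scaled linear
    models, multiple linear regression, and RBF-kernel ridge regression) that
    learns and removes the THC factorization error in molecular and reaction
    energies. Includes seeded synthetic-system generators, grid pruning by
    pivoted Cholesky factorization, HDF5 system archives, cross-validated
    model evaluation, and a one-command experiment pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rhdf5,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
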