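Package: ramanvirocell
Title: Virocell Identification from Single-Cell Raman Microspectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Chemometric analysis of single-cell Raman spectra for
    distinguishing virus-infected cells (virocells) from uninfected cells
    (ribocells). Provides spectral preprocessing (window trimming, SNIP
    baseline estimation, total-ion-current normalization, quality control
    for cosmic rays and low-intensity spectra), multivariate group
    comparison (PCA, spectral contrast angle, principal coordinates, Ward
    D2 clustering, contrast profiles, multiresponse permutation
    procedure), orthogonal projections to latent structures with variable
    importance on projection, marker-band selection, a nucleic-acid to
    protein band ratio with control-calibrated cutoff classification, and
    a seeded synthetic single-cell spectrum generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
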