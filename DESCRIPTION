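Package: clineshift
Title: Geographic Cline Fitting and Coincidence Testing for Moving Hybrid Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits sigmoid (hyperbolic-tangent) geographic clines to 0-1 scaled
    trait data by maximum likelihood using a Metropolis-Hastings stochastic
    search with deterministic polishing, builds center-position log-likelihood
    profiles with 2-unit support limits, and tests coincidence between pairs of
    clines with a composite-profile likelihood-ratio test under sequential
    Bonferroni correction. Includes a spherical gnomonic projection for planar
    transect coordinates, morphometric normalization and univariate discriminant
    screening of diagnostic characters, forest-cover quantification from
    land-cover quadrats, a synthetic-data generator emulating a moving hybrid
    zone between the American toad (Anaxyrus americanus) and the Canadian toad
    (A. hemiophrys) across the Manitoba forest-prairie ecotone, and an
    end-to-end pipeline producing cline-center trajectories and pairwise
    concordance matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
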