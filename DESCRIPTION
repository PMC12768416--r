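Package: confdyn
Title: Multiscale Conformational-Dynamics Analysis for Two-Domain Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the conformational dynamics of multidomain
    proteins from elastic-network models and simulation ensembles: anisotropic
    network model (ANM) normal modes, mode-guided iterative ensemble generation
    with clustering and relaxation, essential-dynamics principal component
    analysis with cosine-content and bootstrap-normalized block covariance
    overlap convergence diagnostics, membrane and binding-site collective
    variables with funnel and upper-wall restraint energies, Hamiltonian
    replica-exchange lambda-ladder design from quadratic-in-lambda energy
    models, and free-energy surfaces from bias reweighting and binless WHAM.
    Synthetic-data generators with known ground truth support validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    cluster,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
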