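Package: nanosite
Title: Trajectory Analysis of Catalytic Sites on Monolayer-Protected Nanozymes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse molecular-dynamics trajectories of
    monolayer-protected gold nanoparticles carrying Zn(II)-TACN headgroups
    (nanozymes). Provides monolayer structural descriptors (radial
    distribution functions, cumulative coordination numbers, RMSF,
    rotational autocorrelation, radius of gyration, eccentricity, hydrogen
    bonds, contacts, solvent shells), hydrogen-bonded ligand bundle
    detection, detection and lifetime analysis of transient bimetallic
    Zn-Zn sites and substrate binding / precatalytic complexes with
    single-exponential population decay fits, and prediction of 13C T1
    relaxation times via the Lipari-Szabo model-free approach. A synthetic
    trajectory generator plants ground-truth events so every stage of the
    pipeline can be verified without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
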