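Package: uteromag
Title: Multiscale Forward Modeling of Uterine Magnetomyograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiscale forward electromagnetic model of uterine contractions
    during pregnancy. Implements a generalized FitzHugh-Nagumo myocyte model
    with a bifurcation-derived stimulus window for bursting action potentials,
    a random anisotropic fiber and conductivity model on arbitrary triangulated
    uterine surfaces, an anisotropic monodomain reaction-diffusion solver on
    the myometrial surface with pacemaker forcing, an analytic traveling-wave
    speed for the bistable front, and a quasi-static magnetic forward
    computation sampled by a 151-channel SQUID gradiometer array of the kind
    used for abdominal magnetomyography. Includes configuration-driven
    scenario runs, SARA-style signal preprocessing, and procedural geometry
    (spherical and pear-shaped uterus, spherical and concave-cap abdomen).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Matrix,
    signal,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
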