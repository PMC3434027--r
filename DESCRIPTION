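Package: cryptdyn
Title: Coupled Cell-Lineage and Wnt/BMP Reaction-Diffusion Dynamics of
    Intestinal Crypts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates de novo formation, regeneration, multiplication and
    stability of intestinal crypts with a continuum two-stage cell lineage
    (progenitor and terminally differentiated cells) on a growing periodic
    one-dimensional tissue. Progenitor replication probability is set by a
    Wnt/Wnt-inhibitor/BMP signalling system solved at quasi-steady state on
    a Fourier spectral grid; crypt shape follows a gradient flow of an
    energy functional whose minimum tracks the progenitor pattern. Includes
    linear stability (Turing) analysis of the Wnt/inhibitor pair, scenario
    runners for formation, ablation/regeneration, BMP knockout, localized
    seeding and exogenous Wnt sources, and a phase-diagram classifier of
    crypt outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
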