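Package: glycophase
Title: Conformational Phase-Space Analysis of Glycans from Enhanced-Sampling Trajectories
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the conformational phase space of N-glycans
    sampled by molecular dynamics: Cremer-Pople ring-puckering coordinates
    with canonical IUPAC shape naming and equal-area Mollweide landscapes,
    free-energy reconstruction from unbiased replica samples with
    block-averaged errors, dihedral-basin conformer-string classification,
    principal-component latent spaces over periodicity-aware sin/cos dihedral
    features, conformer-pucker Pearson correlation analysis, planning and
    exchange diagnostics for combined solute-tempering/metadynamics replica
    ladders, and a synthetic trajectory generator with known coupling between
    linkage conformers and ring pucker for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'colvar-io.R'
    'free-energy.R'
    'conformers.R'
    'glycophase-package.R'
    'methods.R'
    'phase-space.R'
    'puckering.R'
    'plots.R'
    'rest-rect.R'
    'synthetic.R'
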