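Package: CardioT2Star
Title: Simulation and Analysis of Cardiac-Triggered Multi-Echo T2* Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Physics-based simulation and analysis pipeline for myocardial
    T2* relaxation mapping with cardiac-triggered, segmented multi-echo
    spoiled gradient-echo imaging at ultrahigh field. Provides digital
    phantoms (uniform cylinders with susceptibility inclusions and a
    contracting mid-ventricular heart with segment-specific T2*), a
    segmented k-space acquisition engine covering single-phase and CINE
    strategies with echo interleaving and multi-breath-hold partitioning,
    intravoxel-dephasing signal physics, dual-echo B0 field mapping and
    volume-selective shim optimization, log-linear plus bounded
    nonlinear mono-exponential T2* fitting, landmark-based affine
    registration of breath-held series, and AHA mid-ventricular segmental
    analysis across the cardiac cycle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    RNifti,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
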