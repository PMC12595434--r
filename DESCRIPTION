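Package: engagekit
Title: Target-Engagement Analytics for Thermal Proteome Profiling and
    Inhibitor Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for small-molecule target-engagement
    studies built around thermal proteome profiling (TPP/CETSA).
    Implements precursor-depth scaling, per-protein median and
    reference-sample normalization of DIA protein reports, melting
    temperature (Tm) estimation by direct lookup or spline
    interpolation, delta-Tm hit calling with replicate statistics and
    coefficient-of-variation filtering; biochemical screen analytics
    (kinetic velocities, control-anchored hit cutoffs, four-parameter
    logistic IC50 fits, binding isotherms, inhibition-mode
    diagnostics); and virtual-screen triage (physicochemical windows,
    combined docking ranks, circular-fingerprint Tanimoto diversity
    selection). Includes a seeded synthetic-data generator so the full
    pipeline is testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    ChemmineR,
    ChemmineOB,
    methods,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
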