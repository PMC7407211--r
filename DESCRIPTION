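Package: aifquant
Title: Targeted and Untargeted Profiling of Bile Acids and
    Lysophospholipids from All-Ion-Fragmentation LC-HRMS Runs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for combined targeted/untargeted profiling of bile
    acids and lysophospholipids from negative-mode all-ion-fragmentation
    (AIF) LC-HRMS data. Provides exact-mass and diagnostic-fragment
    arithmetic, extracted-ion chromatograms with peak detection and
    signal-to-noise estimation, three-criteria identity confirmation and
    untargeted class screening with sn-positional-isomer assignment,
    internal-standard quantification with the full bioanalytical
    validation calculus (1/x-weighted calibration, LOD/LOQ, recovery,
    matrix effect, trueness and precision), cohort feature-table quality
    control with Tukey-fence outlier filtering, and a seeded synthetic
    AIF-run generator so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mzR,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
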