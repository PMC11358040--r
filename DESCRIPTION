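Package: trsaxs
Title: Time-Resolved High-Throughput SAXS Conformational Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for time-resolved high-throughput small-angle
    X-ray scattering (TR-HT-SAXS) conformational screens of ligand libraries.
    Reads 1-D scattering profiles and plate manifests, performs time-matched
    buffer subtraction, Guinier and normalized Kratky analysis, Z-factor assay
    quality statistics, volatility-of-ratio (V_R) similarity matrices and
    time-resolved V_R traces with replicate-derived significance envelopes,
    chemotype clustering (single-linkage AHC, k-means with Krzanowski-Lai and
    elbow cluster-number selection), first-order kinetic fitting of V_R and
    I(0) transitions (k_VR), and orthogonal-assay triage from differential
    scanning fluorimetry melt curves and microscale thermophoresis traces.
    Includes a synthetic two-state (monomer/dimer) data generator for
    validation of the full screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
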