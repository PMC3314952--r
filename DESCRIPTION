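Package: ucoil
Title: Quantifying Residual Structure in Unfolded Protein Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising the unfolded states of proteins from
    solution biophysics data. Implements a sequence-dependent random-coil
    baseline for backbone 15N transverse relaxation rates with detection of
    hydrophobic clusters as deviations from that baseline, secondary
    chemical-shift and secondary-structure-propensity (SSP) helicity
    analysis against replaceable random-coil reference tables, extraction
    of three-bond HN-HA scalar couplings from HNHA cross/diagonal peak
    intensities, the Svedberg-to-Stokes hydrodynamic chain from
    sedimentation velocity data with empirical compact- and denatured-state
    radius predictions and compaction metrics, circular-dichroism helical
    content, two-state equilibrium denaturation fitting, fluorescence
    emission maxima, and a colicin-protection gamma statistic. Seeded
    synthetic-data generators reproduce the statistical structure of every
    supported input so each analysis stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
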