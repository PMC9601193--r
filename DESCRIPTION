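Package: effluxsig
Title: Metabolomic Signatures of Efflux-Transporter Inhibition in Caco-2 Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for flagging Pgp (ABCB1), BCRP (ABCG2) and MRP2 (ABCC2)
    efflux-transporter inhibitors from intracellular targeted LC-MS
    metabolomics acquired alongside routine Caco-2 permeability screens.
    Implements total-sum normalization of peak-area tables with instrument
    and monolayer QC, orthogonal partial least squares discriminant
    analysis (OPLS-DA) with VIP scores, DModX and Hotelling T-squared
    outlier diagnostics, cross-validated component selection and
    label-permutation validation, consensus signature derivation across
    inhibitor and knockout experiments, a summed percent-change inhibition
    score with transporter-specific classification ranges, transwell
    apparent-permeability and efflux-ratio arithmetic, and a seeded
    synthetic-data generator emulating treated/control peak-area
    experiments for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
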