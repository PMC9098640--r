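Package: hrpfscore
Title: Hydroxyl Radical Protein Footprinting Quantification and
    Structure Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processes high-resolution hydroxyl radical protein
    footprinting (HR-HRPF) data from fragment-ion and peptide
    isotopologue intensity tables to per-residue protection factors
    (lnPF), and scores candidate protein structural models against the
    footprinting data using a conical neighbor count burial metric.
    Includes dose-response regression with zero intercept, a
    footprinting reward score for model ranking, Kabsch C-alpha RMSD,
    decoy-set funnel reports, and a deterministic synthetic-data
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
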