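Package: halbs
Title: Detection and Geometric Validation of Ligand-Protein Halogen Bonds
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate halogen bonds between halogen-containing
    compounds and protein residues in macromolecular structure models
    (mmCIF and legacy PDB), computes their geometric descriptors
    (donor-acceptor distance, Van der Waals overlap, the theta1 and theta2
    angles, and ring-centroid geometry for halogen-pi interactions), and
    scores each bond with HalBS, an interquartile-range based outlier
    score against per-category reference quartile statistics. Includes the
    calibration machinery that derives those reference statistics from a
    structure corpus under B-factor, real-space correlation and resolution
    quality filters, a synthetic-fixture generator that emits valid mmCIF
    files with exactly prescribed bond geometry, and report writers (TSV,
    JSON, and an mmCIF-style summary block).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
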