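Package: glyconet
Title: Glycopeptide Network Assignment and Quantitation from LC-MS1 Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Semi-automated identification and relative quantitation of
    protein glycoforms from deconvoluted LC-MS1 feature tables (neutral
    monoisotopic mass, retention time, intensity), as produced for tryptic
    digests of antibodies. Features are linked into networks by
    monosaccharide mass-difference edges under retention-time windows; the
    lowest-mass (reference) node of each network is matched against a
    glycopeptide candidate database built from peptide backbones and a
    glycan composition library, and compositions are propagated to the
    remaining nodes along the edges. Per-peptide glycoform relative
    abundances and glycosylation attribute summaries (fucosylation,
    sialylation, galactosylation, bisecting, high mannose) are reported.
    Includes a synthetic feature-table generator with planted ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
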