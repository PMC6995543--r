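Package: earlyfold
Title: Early-Stage Structural Codes and Fuzzy-Oil-Drop Compliance for
    Protein Backbones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes protein backbone conformations into a seven-letter
    structural alphabet by projecting (phi, psi) dihedral angles onto an
    elliptical early-stage path on the Ramachandran map, scores protein
    domains against the fuzzy-oil-drop hydrophobic-core model with a
    Kullback-Leibler based relative-distance (RD) statistic including the
    iterative worst-residue trimming classifier, and screens tetrapeptide
    sequences whose structural-code distributions differ between
    core-compliant and noncompliant chain fragments via sequence-structure
    contingency tables and a correlation-significance test. Includes a
    fully seeded synthetic-data generator (Ramachandran torsion mixtures,
    backbone reconstruction from internal coordinates, planted hydrophobic
    cores, planted tetrapeptide signals) so the whole pipeline is testable
    without external structure databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
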