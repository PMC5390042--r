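Package: phytokappa
Title: Categorical Correlation Screening of Plant-Extract Bioactivity
    Against Binarized LC-MS Phytochemical Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links plant-extract bioactivity assays (agar-diffusion
    antimicrobial activity and MTT cytotoxicity toward two mammalian cell
    lines) to presence/absence profiles of LC-MS features across a species
    panel.  Provides per-feature Cohen's kappa screening against binary
    bioactivity classifications, a combined antimicrobial-but-non-cytotoxic
    score with competition ranking, an exhaustive Boolean AND/OR pairwise
    screen for synergy and functional-redundancy candidates, Fritz-Purvis
    D-statistics for phylogenetic signal of binary bioactivity traits, and a
    synthetic-data generator with planted causal features, synergy pairs and
    redundancy pairs so the whole analysis is testable end to end with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
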