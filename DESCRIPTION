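Package: refoldr
Title: Self-Consistency Refolding Metrics for Protein Design Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Folding-model-agnostic evaluation of designed proteins by
    structural self-consistency. Implements rigid-body Kabsch superposition of
    C-alpha traces with median/MAD outlier rejection and realignment (the
    corrected self-consistency RMSD), pLDDT aggregation and designability
    verdicts, randomized mutagenesis panel generation, multiple sequence
    alignment column masking and effective sequence count (Neff) analytics,
    simplified 3-state secondary-structure assignment from backbone geometry,
    and oracle-performance statistics (ROC/AUC, precision/F1 threshold grids,
    Fisher's exact test). A synthetic-data module generates target backbones,
    perturbed "predicted" models with flexible tails, confidence profiles,
    alignments and binary experimental outcomes, so every stage is testable
    without GPU folding models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
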