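Package: linrob
Title: Robustness of Determinative Developmental Cell Lineages to Cell Death
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how robust a determinative (mosaic) developmental
    cell lineage is to random cell death (necrosis) and to the failure of
    cell-division programs. Provides a rooted binary cell-lineage data model
    with typed terminal cells, the multiplicative cell-type survival index f
    and its expectations under single-cell necrosis (f_n) and binomial
    program failure (f_p), eight constrained lineage-randomization null
    models with empirical P-values and Z-scores, lineage feature statistics
    (clonality, rare-early correlation, twin cells, physical-versus-lineal
    distance correlation), transcriptome-based terminal-cell
    reclassification, and a macroevolution simulator that grows lineages by
    stepwise bifurcation under truncation selection for robustness and/or
    simplicity. Synthetic-data generators emulate the census composition,
    depth range, clonality and spatial structure of real invertebrate
    lineages so every analysis can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
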