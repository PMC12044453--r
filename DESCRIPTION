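Package: fragcompare
Title: Comparative Chemoinformatic Analysis of Fragment Libraries
Version: 0.1.0
Authors@R:
    person("fragcompare", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for building and comparing small-molecule fragment
    libraries. Compound collections given as SMILES tables or SDF files are
    curated with a standardization protocol (element whitelist, largest
    component, reionization, neutralization, canonical tautomer,
    deduplication), decomposed into fragments with the eleven RECAP
    retrosynthetic cleavage rules, profiled with rule-of-three filters,
    constitutional and complexity descriptors and the Ertl-Schuffenhauer
    synthetic accessibility score, and compared across libraries via
    fingerprint-based Tanimoto diversity distributions, overlap tables,
    Bemis-Murcko scaffold censuses and chemical-space embeddings (tree-map
    and t-SNE). A synthetic-library generator emulating natural-product-like
    and synthetic-like populations makes the whole pipeline testable without
    external downloads. Molecular-graph primitives are delegated to a
    bundled Python RDKit backend.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.8) with the RDKit and scikit-learn
    packages available on the PATH as 'python'.
Imports:
    graphics,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
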