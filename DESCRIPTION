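Package: essalign
Title: Extraction and Alignment of Enzymatic Step Sequences from
    Metabolic Maps
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Converts KEGG-style metabolic maps (KGML) into reaction
    graphs, extracts linear enzymatic step sequences (ESS) along
    breadth-first-search trees, and compares them with a minimizing
    Needleman-Wunsch aligner driven by an entropy-based,
    hierarchy-aware dissimilarity matrix over three-level Enzyme
    Commission numbers.  Includes a relational SQLite store for
    non-redundant sequences, all-vs-all batch alignment with threshold
    filtering, and shuffled-database null distributions for assessing
    the significance of alignment scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    parallel,
    RSQLite,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
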