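Package: cifsem
Title: Semantic Tools for Crystallographic Information Files
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A toolkit for working with Crystallographic Information Files
    (CIF) as semantically rich documents.  Provides a strict CIF 1.1 style
    reader and writer with lexical numeric typing and standard-uncertainty
    notation, machine-readable data dictionaries with dictionary-driven
    validation, a derivation engine that deduces missing data items from
    related items, crystallographic geometry and symmetry (cell metrics,
    distances, angles, torsions, orbits, structure factors), checkcif-style
    structure validation alerts with submission gating on author responses,
    chemical connectivity inference from coordinates with connection-table
    write-back, and glossary/geometry annotation of free article text.
    Deterministic fixture generators make the whole stack testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
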