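Package: teloscan
Title: De Novo Telomeric Repeat Discovery, Search and Visualization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies candidate telomeric repeat units de novo in genome
    assemblies and long reads by scanning sequences in non-overlapping
    k-chunks, collapsing identical consecutive chunks into tandem runs,
    and aggregating run counts under a canonical representation (the
    lexicographically smallest rotation over both strands). Also counts
    exact occurrences of a known telomeric motif in fixed-width windows
    across each sequence, ships a small clade-to-repeat lookup table,
    renders window counts as deterministic SVG line plots, and provides a
    sequencing-error simulation harness for benchmarking the discovery
    algorithm on synthetic telomeric arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
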