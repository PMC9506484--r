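Package: kozakscan
Title: Kozak Similarity Scoring and Ranking of Translation Initiation Codons
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing canonical and noncanonical translation
    initiation codons (TICs) in mRNA transcripts. Scores the ten nucleotides
    flanking either side of a codon against a Kozak-derived position bits
    matrix (the Kozak Similarity Score), enumerates and ranks ATG and
    near-cognate start-codon candidates within transcript regions, infers
    initiation codons from N-terminal peptide evidence with
    methionine-excision handling, compares score and 5'UTR-length
    distributions between cohorts with one-sided Mann-Whitney tests, and
    simulates transcript cohorts with planted initiation codons in contexts
    of controllable Kozak similarity for benchmarking. Includes a
    colour-binned transcript annotation report and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
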