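Package: identmix
Title: Pattern-Guided Identification of Isomeric Metabolites with
    Combinatorial Standard Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating combinatorial standard
    mixtures ("Ident-Mixes") for reliable identification of isomeric and
    isobaric metabolites in GC-MS and LC-MS workflows. Each compound is
    spiked into exactly two of k pooled mixtures, so its presence/absence
    pattern across the runs forms a pair-code that discriminates up to
    choose(k, 2) chemically similar compounds by the principle of
    exclusion. Includes retention-index computation from n-alkane ladders,
    cross-setup retention-shift diagnostics (including elution-order
    inversions), mass-spectral match factors (forward and reverse weighted
    cosine), NIST msp library reading and writing with an encoded-name
    codec, isobar-density statistics over metabolite database exports, a
    seeded synthetic-batch generator for validation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
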