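Package: chemtagr
Title: Phrase-Based Semantic Parsing of Chemical Synthesis Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A medium-depth, rule-based natural-language pipeline for the
    experimental sections of chemistry articles and patents. Normalises and
    tokenises synthesis prose while preserving character offsets, tags every
    token through a three-step cascade (chemical named-entity recognition,
    domain regular expressions, English part-of-speech), chunks the tagged
    tokens into a phrase tree with a deterministic recursive-descent grammar,
    labels 21 types of procedural Action phrase, infers compound roles
    (solvent, reactant, product) from linguistic context, and serialises the
    result as XML. Also exports reaction graphs linking reactants to products
    by compound reference number, an inter-annotator agreement toolkit (Dice
    coefficient, exact and filtered phrase matching, Needleman-Wunsch
    alignment of span annotations), and a seeded generator of synthetic
    experimental paragraphs with gold annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
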