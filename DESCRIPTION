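Package: dilinet
Title: Drug Similarity Networks for Drug-Induced Liver Injury Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Top-down systems-pharmacology toolkit for studying drug-induced
    liver injury (DILI) through polypharmacology. Filters ChEMBL-style
    bioactivity records into per-drug protein target profiles, infers
    drug-Pfam-domain associations by binomial over-representation with
    Benjamini-Hochberg correction, integrates protein- and domain-channel
    hypergeometric similarity indices into a weighted drug similarity
    network, characterises its topology (degree distribution against a
    discrete power law, nominal assortativity by toxicity class, modularity,
    degree-preserving rewired reference extremes), detects overlapping drug
    communities by clustering links with a partition-density cut, and scores
    communities for liver-toxicity enrichment (DILI score). Includes a
    synthetic cohort generator with planted target-sharing modules for
    end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
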