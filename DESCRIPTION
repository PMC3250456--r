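Package: storyline
Title: Storytelling Across Biomedical Abstracts via Clique-Chain Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Literature-based discovery by "connecting the dots" between
    biomedical abstracts. Given a corpus of abstracts and a start/end document
    pair with disjoint content, finds chains of intermediate documents in which
    every consecutive pair satisfies a Soergel distance threshold and is
    supported by a k-clique of neighboring documents. Includes a tf-idf vector
    space model with Porter stemming, a closed-itemset concept lattice for
    approximate nearest-neighbor candidate generation, an A* search with an
    admissible straight-line Soergel heuristic, Monte-Carlo clique significance
    testing with false-discovery-rate control, naive-Bayes context/result
    sentence classification, context-overlap and entity-cohesion story filters,
    dispersion-coefficient story scoring, and a deterministic synthetic-corpus
    generator with planted bridge chains for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
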