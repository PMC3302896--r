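Package: sheettopo
Title: Beta-Sheet Topology Prediction by Integer Linear Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the beta-sheet topology of beta and mixed alpha/beta
    proteins from sequence and secondary structure alone. Strand pairs are
    scored by sliding gapless alignments under a pluggable residue-pair
    contact potential, and a binary linear optimization model -- strand
    contact variables, orientation exclusivity, contact cardinality,
    residue budgets, hydrogen-bond budgets, non-local contact hierarchy,
    pretzel and interlock restrictions -- is solved repeatedly with integer
    cuts to produce a rank-ordered list of biologically plausible
    topologies. Barrel-like (cyclic) arrangements are eliminated by subtour
    cuts and every topology is checked for two-colorability of its
    contact-incompatibility graph. Includes exact motif-space combinatorics,
    a brute-force enumeration oracle for small instances, contact-map
    evaluation metrics (precision, recall, Matthews correlation), a
    deterministic synthetic-fixture generator with planted topologies, and
    distance-restraint export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
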