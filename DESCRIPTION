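Package: mutexquad
Title: De Novo Cancer Driver Gene-Set Discovery by Quadratic
    Mutual-Exclusivity Penalties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers putative cancer driver gene sets from binary
    patient-by-gene somatic mutation matrices by searching for sets that
    cover many patients while penalizing excess (non-exclusive) mutations
    quadratically.  The objective is minimized with a hybrid of
    Metropolis-style stochastic search over candidate gene sets and exact
    branch-and-bound solution of the binary quadratic subproblem restricted
    to each candidate.  Includes column-permutation significance testing,
    a synthetic-data generator with planted mutually exclusive gene sets,
    readers and writers for common mutation-matrix formats, a gene
    filtering step for hypermutated non-driver genes, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
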