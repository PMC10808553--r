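Package: latticeGC
Title: Agent-Based Germinal Center Simulation with a Lattice-Protein
    Affinity Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates germinal center (GC) reactions in which B cells
    proliferate, hypermutate and compete for antigen displayed on
    follicular dendritic cells.  Antibody-antigen affinity is computed
    from a coarse-grained structural model: antigens and B-cell receptor
    (BCR) peptides are self-avoiding chains on a cubic lattice, every
    binding conformation of the BCR around the antigen is enumerated
    exhaustively, and the energetic optimum under an empirical amino-acid
    contact potential defines the binding energy and affinity.  The
    package generates synthetic lattice antigens, scores their
    immunogenicity against random naive BCR panels, builds founder B-cell
    pools by affinity filtering, and runs seeded stochastic GC
    simulations with multi-domain antigens to study immunodominance
    between antigen domains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    seqinr,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
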