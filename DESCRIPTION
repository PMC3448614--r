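Package: paleosize
Title: Parsimony Phylogenetics, Paleontological Tree Time-Scaling and
    Body-Size Evolution in Fossil Ornithopods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative reconstruction of body-size evolution in
    fossil vertebrates, developed around the rhabdodontid ornithopod
    dinosaurs of the European Late Cretaceous archipelago.  Provides a
    maximum-parsimony engine for morphological character matrices (Fitch and
    ordered Sankoff optimisation, random-addition TBR heuristic search with a
    parsimony ratchet, branch-and-bound for small instances, ensemble
    consistency/retention indices, strict and reduced consensus,
    nonparametric bootstrap, unambiguous synapomorphy mapping), the "equal"
    paleontological time-scaling method (range-midpoint tip ages, arbitrary
    root length shared equally along zero-length branch chains), exact
    weighted squared-change parsimony ancestral-state reconstruction of
    continuous traits on dated trees, ratio-based estimation of femoral and
    total body length from incomplete skeletal elements, and seeded
    generators for synthetic trees, Brownian traits and discrete character
    matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    phytools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
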