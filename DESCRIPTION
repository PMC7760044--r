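Package: infodelta
Title: Partial Information Decomposition and Information-Delta Coordinates
    for Discrete Variable Triples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the dependency structure of three
    discrete variables (two sources X, Y and a target Z). Computes classical
    Shannon measures, normalised information-delta coordinates, and the
    partial information decomposition (PID) into unique, redundant and
    synergistic components by two routes: constrained optimisation over the
    set of distributions preserving the source-target marginals
    (Bertschinger-style unique information), and the pointwise
    specificity/ambiguity decomposition of Finn and Lizier. Enumerates all
    discrete functions Z = f(X, Y) for small alphabets, maps them onto the
    delta-coordinate function plane, and supports a library-and-query
    workflow that matches empirical delta coordinates to the nearest
    function family and returns its decomposition, accommodating dependent
    sources such as genetic loci in linkage disequilibrium.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
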