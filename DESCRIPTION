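Package: nusstile
Title: Nussinov RNA Folding Under Iteration-Space-Sliced Tiled Schedules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-base-pair RNA secondary structure prediction (Nussinov's
    dynamic program) executed under several schedules: the reference serial
    fill, a diagonal-synchronized parallel fill, a cache-efficient fill that
    mirrors the upper triangle into the lower one, and a tiled wavefront
    schedule built by iteration space slicing (ISS). The ISS machinery
    enumerates statement instances of the folding loop nest, builds the exact
    instance-level dependence graph, computes its transitive closure (both a
    brute-force oracle and a closed form), corrects rectangular tiles into
    valid ones, and verifies schedule validity against the dependence oracle.
    The package also fits the sparse integer factor model that lifts two
    fixed-tile-size codes into one parametric code, and runs tile-size
    selection searches over candidate grids with an injectable timer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
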