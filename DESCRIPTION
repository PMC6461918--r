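Package: moob
Title: Multi-Objective Optimized Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-objective optimized breeding: non-dominated
    sorting of multi-trait breeding values, Pareto-optimal parental
    contribution vectors balancing per-trait genetic gain against group
    co-ancestry (with an optional genetic-correlation penalty), multi-objective
    genomic mating, frontier decision support (ideal point, global criterion,
    knee detection, self-organizing maps), and a forward-in-time breeding
    simulator comparing these strategies against tandem selection, independent
    culling, and index selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
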