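Package: cfnsim
Title: Evolutionary Assembly of Microbial Cross-Feeding Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the evolutionary assembly of microbial cross-feeding
    networks on a bipartite consumer-resource graph. Stationary resource flows
    are obtained from a linear network-flow balance; community change is driven
    by flow-weighted speciation with mutation and trait substitution, and by
    threshold extinctions iterated to stability. Includes analytic capacity
    bounds, a suite of community observables (similarity-sensitive diversity,
    evolutionary potential, evenness, displacement statistics, degree and flow
    distributions), dynamic similarity clustering with cluster lineages, and a
    seeded experiment runner for reference runs and parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    igraph,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
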