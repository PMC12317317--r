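Package: rpigraphlets
Title: Graphlets and Node Orbits in Mixed Regulatory and Physical
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Morgan", "Hale", email = "morgan.hale@example.org",
           role = c("aut", "cre"))
Description: Enumerates, canonically encodes and counts the 2-node and
    3-node graphlets of mixed interaction networks that combine
    undirected physical (protein-protein) edges with directed regulatory
    (transcription-factor to target) edges.  Node pairs are collapsed to
    a single labelled edge drawn from a five-type alphabet, yielding 5
    two-node and 98 three-node graphlets with 7 and 259 automorphism
    orbits respectively.  Includes a degree-preserving edge-swap null
    model for graphlet overrepresentation, a median-sampling test for
    node-orbit overrepresentation of a protein set, random-walk-with-
    restart extraction of seed-covering subnetworks, a synthetic mixed-
    network generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
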