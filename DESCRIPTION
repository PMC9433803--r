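Package: meaburst
Title: Network-Burst and Learning-Population Analysis for High-Density
    Microelectrode Array Spike Trains
Version: 0.1.0
Authors@R:
    person("MEA", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for spike-train recordings from high-density
    microelectrode arrays (HD-MEA) of cultured cortical networks. Localizes
    stimulus-defined "learning populations" from response/stimulus ratios and
    response latencies across a structured stimulation protocol, detects
    synchronized network bursts from binned population activity, maps burst
    initiation and propagation via first-spike rank order, builds directed
    functional graphs from spike-train cross-correlograms, computes
    graph-theoretic hub measures (degree, betweenness centrality, modularity,
    global efficiency, small-worldness), and quantifies the association
    between functional hubs and burst-onset sites. Ships a phenomenological
    synthetic spike-train generator emulating spontaneous bursting, evoked
    learning responses, and a disinhibited regime, so every stage is testable
    without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
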