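Package: sigmachrom
Title: Stochastic Lineage Simulation of Heritable Terminus DNA Loss in
    Recombination-Deficient Escherichia coli
Version: 1.0.0
Authors@R:
    person("sigmachrom", "developers", email = "sigmachrom@posteo.net",
           role = c("aut", "cre"))
Description: Generation-stepped stochastic simulator of sigma-replicating
    chromosomes in Escherichia coli recombination mutants: replication fork
    breakage, RecBCD (Exo V) rescue, septum-induced cleavage of the linear
    tail at dif, exponential end resection, and heritable per-generation
    transmission of terminus DNA loss. Computes the observables measured in
    time-lapse and snapshot fluorescence microscopy (initial and transmitted
    event fractions, per-locus focus-less cell fractions) and in marker
    frequency analysis (binned, total-normalized read coverage profiles over
    the circular 4,641 kb genome), together with a closed-form
    branching-process steady state, Wilson-interval event-rate estimation,
    per-fork breakage rates, and exponential degradation-scale fitting that
    connect per-division event rates to population-level focus-less
    fractions. Includes seeded synthetic-data generators (event tables,
    snapshot tables, bedGraph coverage) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
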