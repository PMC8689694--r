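Package: ribotraffic
Title: Whole-Cell Simulation and Optimization of mRNA Translation with a
    Finite Ribosome Pool
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven and fixed-step simulation of mRNA translation in a
    whole cell where all transcripts compete for a finite pool of ribosomes
    (a TASEP-like model with codon-specific delays, ribosome footprint
    exclusion, initiation and diffusion delays). Includes deterministic
    round-robin and uniform-random ribosome arbitration policies with bias
    diagnostics, construction of full-cycle GF(2) matrix pseudorandom number
    generators of the kind used in hardware arbiters, abstract hardware
    resource-planning calculations (buffer allocation, ROM bit accounting,
    speed factors), greedy forward/backward synonymous-mutation optimization
    of the free ribosomal pool, and a seeded synthetic-cell generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
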