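Package: fragphylo
Title: Locating Genome Rearrangement Events on a Phylogeny from a
    Fragmented Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring on which branches of a phylogeny genome
    rearrangement events occurred, using only the breakpoints observable
    between one highly fragmented genome assembly and a set of completely
    assembled genomes.  Genomes are modelled as signed gene orders evolving
    by chromosomal inversion.  Each scaffold of the fragmented genome is
    labelled split / not split / can't tell against every complete genome,
    and a small-parsimony dynamic programme with a wildcard state locates
    the minimal set of event branches, enumerates all optimal placements,
    and scores candidate tree topologies.  Includes the inversion
    simulator, scaffold fragmentation model, exhaustive unrooted-topology
    enumeration, and runners for the rate, fragmentation, tree-ranking and
    can't-tell degradation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
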