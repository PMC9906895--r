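Package: karyohic
Title: Karyotype Analysis from Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of Hi-C contact maps for karyotype
    characterization in genomes with many chromosomes, modeled on avian
    (chicken-like) karyotypes.  Provides a rearrangement-aware contact-map
    simulator (translocations, duplications, deletions, inversions,
    whole-chromosome gains, heterozygous derivative chromosomes mixed with
    wild-type homologues), map-level quality statistics (cis/trans ratio,
    replicate correlation, coverage tracks), A/B compartment calling by
    eigenvector decomposition, topological domain calling by an
    Armatus-style dynamic program with segmentation-comparison metrics,
    detection of inter- and intrachromosomal structural variants from
    contact-enrichment patterns and coverage, and reconstruction of
    derivative chromosomes from breakpoint evidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    igraph,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
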