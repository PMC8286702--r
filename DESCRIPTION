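Package: mipfam
Title: Genome-Wide Identification and Evolutionary Analysis of MIP/Aquaporin Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for the genome-wide characterization of
    major intrinsic protein (MIP/aquaporin) gene families in plant genomes:
    homology-based candidate screening with structural sanity checks
    (transmembrane segments, NPA motifs), physicochemical profiling
    (molecular weight, isoelectric point, GRAVY), neighbor-joining
    phylogeny with bootstrap and reference-guided subfamily naming,
    extraction of ar/R selectivity-filter and Froger's residues, tandem
    and segmental duplicate classification via collinearity, Nei-Gojobori
    Ka/Ks estimation with Jukes-Cantor correction and divergence-time
    dating, and correlation of expression with tissue water accumulation.
    Ships deterministic synthetic-genome, codon-evolution and expression
    simulators with truth labels so the whole pipeline is testable without
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    seqinr
Config/testthat/edition: 3
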