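Package: mirdiv
Title: Comparative Analysis of miRNA Expression and Regulatory Divergence
        in Primate Brains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Tools for comparative small-RNA transcriptomics across closely
        related species: 5'-anchored miRNA quantification from aligned read
        stacks, consensus ortholog assignment of miRNA precursors with mature
        coordinate projection, count- and intensity-based differential
        expression with outgroup lineage assignment, statistics linking miRNA
        expression divergence to mRNA and protein divergence of predicted
        targets (rank shift tests, association counting, permutation FDR),
        derivation of experimentally verified targets from transfection
        experiments via a proportion-based FDR, and a sliding-window scan for
        local excess of derived alleles upstream of miRNA precursors with a
        feature-anchored permutation null. A seeded synthetic-data generator
        produces every input with known ground truth, so the complete pipeline
        is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, S4Vectors, IRanges, GenomicRanges,
        SummarizedExperiment, Biostrings, limma, ape, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
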