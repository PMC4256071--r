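Package: draftgauge
Title: Quantifying and Correcting Gene-Count Inflation in Fragmented Draft Genome Assemblies
Version: 0.1.0
Authors@R: person("draftgauge", "maintainers", email = "draftgauge@example.org", role = c("aut", "cre"))
Description: Simulates draft-genome fragmentation from an intact reference
    genome, emulates the gene-prediction errors that fragmentation induces
    (genes cleaved across contigs, invented start/stop codons), clusters gene
    models into families by sequence similarity with Markov clustering,
    classifies excess draft genes as cleaved fragments versus split alleles,
    and corrects fragmentation-induced gene-count inflation using paired-end
    RNA-seq evidence via set merging of connected gene models. Includes a
    synthetic-data generator with full ground-truth provenance so every step
    can be validated against known answers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
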