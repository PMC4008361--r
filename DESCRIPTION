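Package: annotforge
Title: Multi-Omics Re-Annotation of Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evidence-driven re-annotation of high-G+C bacterial genomes
    from layered omics data. Discovers novel open reading frames by mapping
    peptide identifications onto six-frame translations of intergenic
    regions, detects transcribed intergenic regions from strand-specific
    RNA-seq coverage, annotates ribosome binding sites from the termini of
    ribosome-protected small-RNA degradation fragments (Shine-Dalgarno
    protection and 3-nt codon periodicity), and assigns candidate genes to
    orphan metabolic reactions by protein-domain requirement matching and
    gene synteny. Ships a fully deterministic synthetic-data generator that
    plants hidden genes, ribosome binding sites, frameshift mis-annotations
    and decoy peptides in a toy high-G+C genome, so that every stage of the
    pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
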