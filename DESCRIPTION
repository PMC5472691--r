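Package: hyenabiome
Title: Multi-Amplicon Metabarcoding of the Spotted Hyena Intestinal Biome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable re-implementation of a multi-amplicon
    (16S/18S) fecal metabarcoding analysis for a social carnivore: quality
    filtering and zero-mismatch primer-pair demultiplexing of paired reads,
    simplified ribosomal sequence variant (RSV) inference with de novo bimera
    removal, naive-Bayes k-mer taxonomy with bootstrap confidence, genus-level
    agglomeration with phylum accounting, McMaster coprology with a
    correlation screen against sequence counts, rarefaction-based diversity
    statistics with exact tie-aware Mann-Whitney tests, Bray-Curtis
    ordination, PLS-DA with leave-one-out axis selection and quartile-loading
    enrichment, and negative-binomial differential abundance with
    Benjamini-Hochberg correction. A bundled synthetic-data generator emulates
    the study design (48 wells by 48 amplicons, technical replicates, PCR
    failures, water controls, chimeras, and egg counts log-linearly coupled to
    taxon abundance) so the whole pipeline runs and is tested without any
    external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    vegan,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    dada2
Config/testthat/edition: 3
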