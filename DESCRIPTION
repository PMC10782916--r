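Package: sbclone
Title: Single-Cell Genotyping of Sleeping Beauty Transposon Insertions and
    Clonal Co-Occurrence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to reconstruct the clonal architecture of transposon
    mutagenized tumors from barcoded single-cell sequencing reads. Processes
    paired reads carrying a 16-base cell barcode and a transposon tag into
    genome-mapped TA-dinucleotide insertion sites, aggregates per-cell
    insertion profiles with quality filtering, clusters co-occurring sites
    into subclones via an insertion-site adjacency matrix, annotates driver
    genes (gene body plus promoter window), and evaluates recurrent
    co-occurring gene-pair mutations with a structure-preserving permutation
    test that replaces observed sites by random genomic TA sites, with
    Benjamini-Hochberg correction. Includes a fully seeded synthetic-data
    generator (genomes, planted subclones, paired FASTQ) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    Matrix,
    jsonlite,
    graphics,
    methods,
    stats,
    utils
Suggests:
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
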