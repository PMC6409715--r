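Package: ClassiPhage
Title: Taxon-Specific Profile HMM Libraries for Phage Classification
    and Prophage Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds taxon-specific profile hidden Markov model (HMM)
    libraries from classified bacteriophage genomes, refines model
    membership to a fixpoint, and applies the libraries to classify
    phage genomes into families, to recover unannotated coding
    sequences from intergenic regions, and to identify and classify
    prophage loci inside bacterial host genomes. Protein families are
    defined by Markov clustering (MCL) of an all-vs-all protein
    similarity graph after greedy redundancy removal; profile HMMs are
    built, emitted and scanned with HMMER3. A deterministic synthetic
    fixture generator produces phage families, phage genomes and host
    genomes with implanted prophages so the whole pipeline can be
    exercised without downloads.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr
SystemRequirements: HMMER3 (hmmbuild, hmmsearch, hmmemit), BLAST+
    (makeblastdb, blastp), MAFFT
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
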