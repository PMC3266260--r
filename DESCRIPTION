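Package: madsplice
Title: Alternative Splicing Analysis of Plant MIKC MADS-Domain Proteins
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and types alternative splicing (AS) events between
    transcript isoforms of plant MIKC-type MADS-box genes, filters
    transcripts under the 55-nt premature-termination-codon rule for
    nonsense-mediated decay, maps events onto the M/I/K/C protein domain
    architecture, identifies AS-induced polymorphisms (AIPs) and their
    conservation across species by intron-position transfer through global
    protein alignments, scans introns for cryptic-exon exonization
    remnants, and classifies events as putatively functional against
    interaction-motif annotations. Includes a seeded generator of
    MIKC-like loci with implanted AS events, NMD variants and diverged
    orthologs that serves as a ground-truth test substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
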