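---
title: "Methods: alternative splicing analysis of MIKC MADS-domain proteins"
author: "madsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alternative splicing analysis of MIKC MADS-domain proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(madsplice)
```

## The problem

Plant MIKC-type MADS-domain transcription factors work as dimers and
higher-order complexes. Their modular architecture — MADS (M) domain for
DNA binding, intervening (I) domain for dimer specificity, keratin-like
(K) box whose K1/K2 helices mediate dimerization and whose C-terminal K3
helix mediates multimerization, and a C-terminal (C) domain — means that
a short insertion or deletion produced by alternative splicing (AS) can
selectively remove or add an interaction surface. `madsplice` implements
a desk-scale, fully testable version of the analysis chain needed to
find such events: event detection and typing, nonsense-mediated decay
(NMD) filtering, domain-level placement, cross-species conservation of
AS-induced polymorphisms (AIPs), and functional classification against
externally supplied interaction-motif coordinates. Motif prediction
itself and EST assembly are out of scope: motif tables and per-species
transcript contigs are inputs.

## Coordinates and containers

Genomic coordinates are 0-based half-open internally; GFF3 I/O converts
to and from the 1-based inclusive convention at the boundary
(`read_gene_models`, `write_gff3`); protein coordinates are 1-based
inclusive. Exon lists are stored in transcription order, so minus-strand
transcripts hold descending genomic intervals, and all intron phases and
protein positions are computed on the coding strand. An intron's
`protein_position` is the number of complete codons upstream of it: the
junction falls between residues `p` and `p + 1`. These conventions are
asserted by the type constructors rather than assumed.

## Event detection and typing

Isoform pairs are compared by their exon chains. Introns shared exactly
between the chains anchor identical regions; the non-shared introns of
both chains are grouped by single-linkage interval overlap into
*difference regions*, each classified independently (a greedy 5′→3′
decomposition; the alternative — global joint typing — is unnecessary
when regions do not overlap, and overlapping multi-intron differences
are deliberately reported as `complex` rather than guessed):

* one intron per chain, shared acceptor → `alt_donor`; shared donor →
  `alt_acceptor`;
* an intron of one chain fully exonic in the other →
  `intron_retention`;
* the reference carries an exon absent from the other chain, with outer
  boundaries shared → `exon_skip`; mirrored, a novel exon of the other
  chain inside a reference intron → `cryptic_exon`;
* two adjacent internal exons, each on exactly one chain, outer
  boundaries shared and exons disjoint → `mutually_exclusive`;
* anything else → `complex`.

Exon skipping and cryptic-exon inclusion have identical pairwise
geometry; they are distinguished by orientation, with the first
argument of `detect_events` acting as the reference isoform. This is a
convention, not an inference — with more than two isoforms the caller
decides which chain is the reference.

Intron clustering for prevalence statistics uses single linkage under
≥1-nt genomic overlap. Exact-coordinate grouping would separate a
retained or alternative-site intron from its fully spliced counterpart,
which is precisely the signal being counted; the overlap rule keeps
them together. A cluster is an AS cluster when it holds two distinct
intervals, or when its single intron is retained inside an exon of
another isoform.

Per-domain enrichment uses a two-sided Fisher's exact test of each
domain against all other domains combined. The contingency framing and
sidedness are an analysis choice; domain-versus-rest two-sided is the
most conservative standard reading, and the test is computed exactly
(`stats::fisher.test` on 2×2 tables; an independent hypergeometric
enumeration oracle in the test suite agrees to 1e-12). Degenerate
tables with a zero margin return p = 1.

## NMD filtering

A transcript is a putative NMD target when its PTC lies *more than*
55 nt upstream of the last exon–exon junction. Two details are not
fixed by the rule as usually stated and are made explicit here:

* the distance is anchored at the **first** nucleotide of the stop
  codon (boundary cases in the tests — distances 54/55/56 — classify
  coding/coding/target under this choice);
* a transcript whose PTC triggers the rule is downgraded to
  `ambiguous` when a downstream ATG-initiated ORF of at least
  `min_orf_aa` (default 30) residues exists whose own stop does not
  trigger the rule; such transcripts may be translated from the
  downstream start rather than degraded. The criterion is configurable
  because the underlying biology ("difficult to determine") has no
  sharp rule.

Single-exon transcripts have no junction and are never NMD targets.

## Alignments

All protein alignments use BLOSUM62 with gap open 10 and extension 0.5
(needle-style defaults); nucleotide local alignments use +5/−4 with the
same gap costs (megablast-style weights). Domain boundaries are
transferred through global alignments; a boundary landing in a query
gap snaps to the nearest aligned query residue toward the domain
interior, and queries below 30% identity are refused
(`unannotatable`) rather than annotated badly. Since only pairwise
transfer is implemented (no multiple alignment engine), boundary
placement inside long indels is approximate by construction; the snap
direction keeps domains nested and ordered.

E-values are not used anywhere: at desk scale the database is a handful
of sequences and e-value calibration is meaningless. The exonization
scan instead applies a raw score floor (default 100, i.e. 20 identical
bases) chosen above the maximal local alignment score observed between
unrelated exon/intron pairs of these lengths.

## AIP detection and conservation

Homolog assignment accepts a six-frame translated fragment when a local
alignment against the reference protein reaches ≥40% identity (over
aligned columns, gaps excluded; X from fuzzy codons never matches) and
covers ≥60% of the reference residues. Intron positions are transferred
through global alignments; positions falling where the subject is
gapped stay unmapped.

An indel between two isoforms is an AIP when:

* it coincides with a mapped intron position. Coincidence allows
  `aip_junction_slack_cols` (default 3) columns of slack because
  co-optimal alignments slide a gap run along repeated flank residues —
  an indel beginning with the same residue as its flank can be placed
  one column to either side of the true junction. Non-intron indels in
  the specificity tests sit ≥10 residues from any intron, so the slack
  cannot create false positives there;
* the 10 alignment columns flanking the polymorphic region (read as 5
  per side; configurable) contain at least 4 identical residue pairs
  and at most 1 gapped position;
* one of the isoforms aligns gaplessly to the reference within ±5
  residues of the intron position, so the AIP can be represented by an
  amino-acid sequence.

Two AIPs are *conserved* when the global alignment of their
longer-isoform sequences is at least 40% similar. "Similar" is
operationalized as the fraction of alignment columns with a positive
BLOSUM62 score, with gap columns counted in the denominator — the
strictest of the common readings. The pair is aligned in a canonical
order so the call is exactly symmetric. No length constraint is placed
on the subject indel relative to the query indel (homologous AIPs of
slightly different sizes still count); a length tolerance could be
added at the call site by comparing `indel_peptide` lengths.

## Exonization scanning

`exonization_scan` locally aligns a (cryptic) exon against an intron.
When a homologous region exists, the nearest AG dinucleotide at or
upstream of the region's 5′ edge is taken as the available acceptor;
the offset between that acceptor and the region determines whether
splicing there preserves the exon's frame (`offset %% 3 == 0`), and the
region is translated in the exon's frame to detect in-frame stops. A
region is `translatable` only when the frame is preserved and no stop
occurs — the two failure modes correspond to a remnant whose nearest
acceptor sits 2 nt upstream (frameshift followed by a PTC) and a
remnant carrying an in-frame termination codon.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the structure of
MIKC loci, not their evolution:

* **Architecture**: 240-residue proteins (M 60, I 30, K 90, C 60
  residues by default), seven coding exons — one long first exon
  spanning the MADS domain and the proximal I-domain, short internal
  exons through the I-domain and K-box, C-terminal exons — plus 60/120
  nt UTRs and canonical GT..AG introns of 90–200 nt. Exon boundaries
  fall on codon boundaries (phase-0 introns), so frame-preserving
  events have sizes divisible by 3; this simplification keeps implanted
  truth unambiguous and is stated here because real MIKC introns also
  occur in phases 1 and 2.
* **Implants**: alternative donor/acceptor variants are inclusion-type
  (the alternative isoform gains intronic sequence), so implants only
  rewrite intron sequence and never perturb the reference protein.
  Retained introns are stop-free and length-divisible-by-3 for coding
  variants; NMD variants retain a frame-shifting intron carrying an
  early stop. Mutually exclusive and cryptic exons are written into an
  intron with their own AG/GT boundaries.
* **Orthologs**: protein-level substitutions at a target divergence d
  (uniform across sites, each substituted residue drawn uniformly from
  the other 19), back-translated with uniform synonymous codon choice;
  ±5 residues around intron positions are spared so that flank quality
  reflects splicing history rather than substitution noise. No indel
  process exists apart from the implanted AIP (and the non-intron decoy
  indel used as a negative control), which keeps the ground truth
  exact. Divergences ≥0.6 warn: the homolog filter is designed to
  reject them.
* **NMD boundary constructs**: `simulate_nmd_transcript` places a stop
  at an exact signed distance from the last junction by padding the
  penultimate exon; its 3′ sequence is A-free so no downstream ATG can
  rescue the verdict, making the boundary tests sharp.

What passing tests on this substrate do **not** show: performance on
real loci with phase-1/2 introns, non-canonical splice sites,
alternative transcription starts/ends (reported as `complex`),
paralogous gene families confounding best-homolog assignment, or EST
contigs with sequencing errors and chimerism. The generator also makes
no attempt at realistic codon usage or rate heterogeneity.

## Problem sizes and determinism

Everything is seeded; a fixed seed reproduces loci, orthologs and all
downstream numbers byte-for-byte. The benchmark drivers run 1,000
isoform pairs for event-type recovery and 500 ortholog replicates at
divergences 0.05 and 0.1 for AIP precision/recall — sizes at which the
binomial uncertainty on the reported rates is below one percentage
point, while a full run stays in the minutes range on one CPU. The
oracle-equivalence suites use exhaustive enumeration at small n
(transitive-closure clustering for up to 20 introns, hypergeometric
enumeration for tables up to N ≈ 60), where brute force is exact and
fast.

## Known limitations

* Event decomposition is pairwise; loci are analysed as reference
  versus each alternative isoform, and multi-isoform reconciliation
  (counting one biological event seen in several pairs once) is left to
  the caller, as is any distinction between per-pair and per-locus
  event counts.
* Domain transfer by pairwise alignment is an approximation to
  profile-based boundary annotation; boundaries inside indels are
  snapped, not inferred.
* The K-box C-terminal region defaults to the distal half of the K-box
  when no explicit K3 interval is supplied; supplied annotations
  override it per protein.
* The NMD model covers only the 55-nt junction rule: no uORFs, no
  long-3′UTR triggers, no decay-efficiency modelling.
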