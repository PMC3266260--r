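# madsplice

Alternative splicing (AS) analysis for plant MIKC-type MADS-domain
transcription factors.

MIKC proteins — the floral regulators SEP3, SVP, STK, ABS, the FLC/MAF
clade and their relatives — act as di- and multimeric complexes whose
composition is determined by the M (MADS, DNA binding), I (intervening,
dimer specificity), K (keratin-like coiled coil, helices K1–K3) and C
(C-terminal) domains. Alternative splicing that survives
nonsense-mediated decay (NMD) can delete or insert short protein
segments in these domains and thereby rewire protein–protein
interactions. `madsplice` implements the complete in-silico pipeline for
asking, for each MIKC locus, *does an AS event change the protein, and
is that change plausibly functional?*

The pipeline, for users who work from gene models (GFF3 + genome FASTA),
domain-boundary tables and interaction-motif coordinate tables:

1. **Event detection and typing** (`detect_events`): pairwise exon-chain
   comparison between isoforms of a locus, decomposed 5′→3′ into local
   events typed as alternative donor/acceptor, exon skipping, intron
   retention, mutually exclusive exons or cryptic exon inclusion;
   intron clustering (`cluster_introns`, single linkage under ≥1-nt
   genomic overlap) with the rule that multi-intron clusters are AS and
   singleton clusters are AS only when the intron is retained elsewhere
   (`cluster_is_as`).
2. **NMD filtering** (`classify_nmd`): a transcript is a putative NMD
   target when its premature termination codon (PTC) lies more than
   55 nt upstream of the last exon–exon junction (strict inequality,
   measured from the first base of the stop codon); candidates with a
   downstream ATG-initiated ORF that escapes the rule are "ambiguous".
3. **Protein-level effects** (`event_effect`, `assign_domain`): global
   BLOSUM62 alignment of the isoform proteins (gap open 10 / extend
   0.5); the amino-acid difference is the number of gapped or
   mismatched alignment columns within the event's footprint; effects
   are placed on the M/I/K/C architecture (`transfer_domains` moves
   reference boundaries through alignments onto new isoforms).
4. **AS-induced polymorphisms and conservation** (`six_frame_orfs`,
   `best_homolog`, `map_intron_positions`, `detect_aips`,
   `call_conservation`): cross-species transcript contigs are translated
   in six frames, assigned to a reference protein when a local alignment
   reaches ≥40% identity over ≥60% of the reference residues, intron
   positions are transferred through Needleman–Wunsch alignments, and an
   indel between two isoforms is an AIP when it coincides with a mapped
   intron position, its 10 flanking alignment columns contain ≥4
   identical pairs and ≤1 gap, and one isoform aligns gaplessly to the
   reference around the position. Two AIPs are conserved when their
   longer-isoform sequences are ≥40% similar (positive BLOSUM62 columns
   over all columns).
5. **Functional classification** (`classify_functional`, `make_report`):
   an event is putatively functional when it overlaps a predicted
   interaction motif, falls in the C-terminal (K3) region of the K-box,
   or has a conserved AIP.
6. **Exonization scanning** (`exonization_scan`): local alignment of a
   (cryptic) exon against an intron, locating the nearest upstream AG
   acceptor, and reporting whether splicing there preserves frame and
   whether the region carries an in-frame stop.
7. **Synthetic data** (`simulate_locus`, `simulate_orthologs`,
   `simulate_nmd_transcript`, `implant_cryptic_exon_remnant`): a seeded
   generator of MIKC-like loci (long first exon spanning M and part of
   I, short internal exons, K-box over several exons, canonical GT..AG
   sites) with implanted events of all six types, NMD variants, and
   diverged orthologs with ground-truth AIP labels — the test substrate
   for every module.

## Worked example

```r
library(madsplice)

# a MIKC-like locus with one in-frame exon-skipping event in the K-box
loc <- simulate_locus(sim_config(
  events = list(event_spec("exon_skip", target_domain = "K"))), seed = 42)

ev  <- detect_events(loc$transcripts[[1]], loc$transcripts[[2]])[[1]]
eff <- event_effect(ev, loc$proteins[[1]], loc$proteins[[2]],
                    loc$transcripts[[1]], loc$transcripts[[2]])
ev
#> <as_event> exon_skip at locusA [705,980) +
#>    locusA.1 vs locusA.2 (locus locusA )
eff
#> <as_effect> 12 aa difference; in frame; 0 aa truncation
assign_domain(eff, loc$domains)
#> [1] "K"
```

The skipped 36-nt exon removes 12 residues from the K-box without
shifting the frame. The three functionality criteria are then applied;
this particular event sits in the N-terminal half of the K-box, away
from interaction motifs and the K3 region, and carries no conserved
AIP, so it is not called functional:

```r
classify_functional(ev, eff, loc$domains)
#> <functional_call> not functional
#>   motif overlap: FALSE | K-box C-term: FALSE | conserved AIP: FALSE
```

Enrichment of AS across domains uses exact Fisher tests on intron-cluster
counts (each domain against all others combined, two sided):

```r
counts <- data.frame(domain = c("I", "K", "C"),
                     n_clusters_total = c(46L, 147L, 22L),
                     n_clusters_as   = c(11L, 16L, 2L))
fisher_domain_enrichment(counts)
#>   domain n_clusters_total n_clusters_as    p_value
#> 1      I               46            11 0.02773186
#> 2      K              147            16 0.13183815
#> 3      C               22             2 0.74571112
```

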