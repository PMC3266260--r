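# shared fixture builders for the test suite

aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa_str <- function(n) paste(sample(aa_alphabet, n, TRUE), collapse = "")

# a plain two-exon plus-strand transcript on its own chromosome
make_two_exon_tx <- function(exon1, intron, exon2, id = "tx1",
                             locus = "loc1", chrom = "chr1") {
  gseq <- paste0(exon1, intron, exon2)
  e1 <- c(0L, nchar(exon1))
  e2 <- c(nchar(exon1) + nchar(intron), nchar(gseq))
  list(tx = transcript_model(id, locus, chrom, "+", rbind(e1, e2)),
       genome = Biostrings::DNAStringSet(stats::setNames(gseq, chrom)))
}

# brute-force single-linkage closure over pairwise interval overlap:
# the independent oracle for cluster_introns
brute_force_clusters <- function(introns) {
  n <- nrow(introns)
  if (n == 0) return(list())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- introns$start[i] < introns$end[j] &&
      introns$start[j] < introns$end[i]
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[pmin(comp[i], comp[j]) == comp | comp == pmax(comp[i], comp[j])] <-
          min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(seq_len(n), comp), function(rows)
    sort(paste(introns$start[rows], introns$end[rows], introns$transcript_id[rows]))))
}

# canonical representation of cluster_introns output for comparison
cluster_keys <- function(clusters) {
  unname(lapply(clusters, function(cl)
    sort(paste(cl$members$start, cl$members$end, cl$members$transcript_id))))
}

sort_cluster_sets <- function(x) x[order(vapply(x, paste, character(1),
                                                collapse = "|"))]

# exact two-sided Fisher p by full hypergeometric enumeration (the
# independent oracle for fisher_domain_enrichment)
fisher_enum_p <- function(a, b, c_, d) {
  m1 <- a + b; m2 <- c_ + d; k <- a + c_
  lo <- max(0, k - m2); hi <- min(k, m1)
  probs <- stats::dhyper(lo:hi, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

all_event_types <- c("alt_donor", "alt_acceptor", "exon_skip",
                     "intron_retention", "mutually_exclusive",
                     "cryptic_exon")
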