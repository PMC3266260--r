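#' Genomic interval
#'
#' Internal coordinates are 0-based half-open on the chromosome; strand is
#' "+" or "-". GFF3 input/output converts to/from the 1-based inclusive
#' convention at the boundary.
#'
#' @param chrom chromosome / contig identifier.
#' @param start 0-based inclusive start (nt).
#' @param end exclusive end (nt); must exceed \code{start}.
#' @param strand "+" or "-".
#' @return an object of class \code{genomic_interval}.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end)
    stop("invalid interval: require 0 <= start < end")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

# exon/cds matrices: integer matrices with columns start, end (0-based
# half-open, genomic), rows in transcription order (descending genomic
# coordinates for minus-strand transcripts).
validate_interval_matrix <- function(m, strand, what) {
  if (nrow(m) == 0) stop(what, ": at least one interval required")
  if (any(m[, 1] < 0) || any(m[, 2] <= m[, 1]))
    stop(what, ": require 0 <= start < end for every interval")
  g <- m[order(m[, 1]), , drop = FALSE]
  if (nrow(g) > 1 && any(g[-1, 1] < g[-nrow(g), 2]))
    stop(what, ": intervals overlap")
  tx_order <- if (strand == "+") order(m[, 1]) else order(-m[, 1])
  if (!identical(tx_order, seq_len(nrow(m))))
    stop(what, ": intervals must be in transcription order")
  invisible(m)
}

#' Transcript model
#'
#' One isoform of a locus: ordered exons (and optionally CDS sub-intervals)
#' on one chromosome and strand. Exons are stored in transcription order,
#' i.e. by descending genomic coordinate for minus-strand transcripts.
#'
#' @param transcript_id,locus_id identifiers.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons integer matrix (columns start, end; 0-based half-open) in
#'   transcription order.
#' @param cds optional CDS intervals, same convention; each CDS interval
#'   must be contained in an exon.
#' @return an object of class \code{transcript_model}.
#' @export
transcript_model <- function(transcript_id, locus_id, chrom, strand, exons,
                             cds = NULL) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  validate_interval_matrix(exons, strand, "exons")
  if (!is.null(cds)) {
    cds <- matrix(as.integer(cds), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
    validate_interval_matrix(cds, strand, "cds")
    for (i in seq_len(nrow(cds))) {
      inside <- any(exons[, 1] <= cds[i, 1] & cds[i, 2] <= exons[, 2])
      if (!inside) stop("cds interval not nested within an exon")
    }
  }
  structure(list(transcript_id = transcript_id, locus_id = locus_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model>", x$transcript_id, "(locus", x$locus_id, ")\n")
  cat("  ", x$chrom, x$strand, ":", nrow(x$exons), "exon(s),",
      if (is.null(x$cds)) "no CDS" else paste(nrow(x$cds), "CDS segment(s)"),
      "\n")
  invisible(x)
}

#' Protein isoform
#'
#' @param protein_id,transcript_id identifiers.
#' @param sequence amino-acid string without a stop symbol.
#' @param orf_tx_start,orf_tx_end 1-based inclusive transcript coordinates
#'   of the translated ORF (including the stop codon).
#' @return object of class \code{protein_isoform}.
#' @export
protein_isoform <- function(protein_id, transcript_id, sequence,
                            orf_tx_start = NA_integer_,
                            orf_tx_end = NA_integer_) {
  if (grepl("\\*", sequence)) stop("protein sequence contains a stop symbol")
  if (!is.na(orf_tx_start) && !is.na(orf_tx_end)) {
    if ((orf_tx_end - orf_tx_start + 1L) / 3L - 1L != nchar(sequence))
      stop("ORF length inconsistent with protein length")
  }
  structure(list(protein_id = protein_id, transcript_id = transcript_id,
                 sequence = sequence, orf_tx_start = as.integer(orf_tx_start),
                 orf_tx_end = as.integer(orf_tx_end)),
            class = "protein_isoform")
}

#' MIKC domain annotation
#'
#' Residue intervals (1-based inclusive) of the M, I, K and C domains of a
#' MIKC protein, plus the C-terminal sub-region of the K-box implicated in
#' higher-order complex formation (helix K3). When \code{kbox_cterm} is not
#' supplied, it defaults to the distal half of the K-box.
#'
#' @param protein_id identifier.
#' @param m,i,k,c length-2 integer vectors (start, end), ordered
#'   M < I < K < C and non-overlapping.
#' @param kbox_cterm optional sub-interval of \code{k}.
#' @return object of class \code{domain_annotation}.
#' @export
domain_annotation <- function(protein_id, m, i, k, c, kbox_cterm = NULL) {
  iv <- rbind(m = m, i = i, k = k, c = c)
  if (any(iv[, 1] > iv[, 2]) || any(iv[, 1] < 1))
    stop("domain intervals must satisfy 1 <= start <= end")
  if (any(iv[-1, 1] <= iv[-4, 2]))
    stop("domains must be ordered M < I < K < C and non-overlapping")
  if (is.null(kbox_cterm))
    kbox_cterm <- c(k[1] + floor((k[2] - k[1] + 1) / 2), k[2])
  if (kbox_cterm[1] < k[1] || kbox_cterm[2] > k[2])
    stop("kbox_cterm must lie within the K-box interval")
  structure(list(protein_id = protein_id, m = as.integer(m), i = as.integer(i),
                 k = as.integer(k), c = as.integer(c),
                 kbox_cterm = as.integer(kbox_cterm)),
            class = "domain_annotation")
}

#' @export
print.domain_annotation <- function(x, ...) {
  cat("<domain_annotation>", x$protein_id, "\n")
  cat(sprintf("  M %d-%d | I %d-%d | K %d-%d (K3 %d-%d) | C %d-%d\n",
              x$m[1], x$m[2], x$i[1], x$i[2], x$k[1], x$k[2],
              x$kbox_cterm[1], x$kbox_cterm[2], x$c[1], x$c[2]))
  invisible(x)
}

exon_lengths <- function(tx) tx$exons[, 2] - tx$exons[, 1]

#' Spliced transcript sequence
#'
#' Concatenates exon sequences in transcription order; minus-strand
#' transcripts are reverse-complemented.
#'
#' @param transcript a \code{transcript_model}.
#' @param genome a named \code{DNAStringSet} (or named character vector).
#' @param use_cds if TRUE, splice the CDS intervals instead of the exons.
#' @return a character string of nucleotides.
#' @export
spliced_sequence <- function(transcript, genome, use_cds = FALSE) {
  iv <- if (use_cds) transcript$cds else transcript$exons
  if (use_cds && is.null(iv)) stop("transcript has no CDS annotation")
  if (!transcript$chrom %in% names(genome))
    stop("unknown chromosome: ", transcript$chrom)
  chr <- if (is.character(genome)) genome[[transcript$chrom]] else
    as.character(genome[[transcript$chrom]])
  if (any(iv[, 2] > nchar(chr)))
    stop("exon outside chromosome bounds on ", transcript$chrom)
  g <- iv[order(iv[, 1]), , drop = FALSE]
  s <- paste(substring(chr, g[, 1] + 1L, g[, 2]), collapse = "")
  if (transcript$strand == "-") s <- revcomp_str(s)
  s
}

#' Introns of a transcript
#'
#' Returns the introns between consecutive exons, with splicing phase and
#' protein position when the transcript has a CDS. The phase is the number
#' of CDS nucleotides upstream of the intron modulo 3; \code{protein_position}
#' is the number of complete codons upstream of the intron, i.e. the intron
#' junction falls between residues \code{protein_position} and
#' \code{protein_position + 1}. Both are NA for introns outside the CDS.
#'
#' @param transcript a \code{transcript_model}.
#' @return data.frame with columns \code{intron_index}, \code{start},
#'   \code{end} (genomic, 0-based half-open), \code{phase},
#'   \code{protein_position}, \code{transcript_id}.
#' @export
get_introns <- function(transcript) {
  ex <- transcript$exons
  n <- nrow(ex)
  if (n < 2)
    return(data.frame(intron_index = integer(), start = integer(),
                      end = integer(), phase = integer(),
                      protein_position = integer(),
                      transcript_id = character()))
  if (transcript$strand == "+") {
    start <- ex[-n, 2]; end <- ex[-1, 1]
  } else {
    start <- ex[-1, 2]; end <- ex[-n, 1]
  }
  phase <- rep(NA_integer_, n - 1)
  ppos <- rep(NA_integer_, n - 1)
  if (!is.null(transcript$cds)) {
    cds <- transcript$cds
    total <- sum(cds[, 2] - cds[, 1])
    for (j in seq_len(n - 1)) {
      # CDS nucleotides strictly 5' (in transcription order) of the intron
      if (transcript$strand == "+") {
        up <- sum(pmax(0L, pmin(cds[, 2], start[j]) - cds[, 1]))
      } else {
        up <- sum(pmax(0L, cds[, 2] - pmax(cds[, 1], end[j])))
      }
      if (up > 0 && up < total) {
        phase[j] <- up %% 3L
        ppos[j] <- up %/% 3L
      }
    }
  }
  data.frame(intron_index = seq_len(n - 1), start = start, end = end,
             phase = phase, protein_position = ppos,
             transcript_id = transcript$transcript_id,
             stringsAsFactors = FALSE)
}

#' Find ATG-initiated open reading frames
#'
#' Scans all three forward frames of a (spliced) transcript sequence for
#' ORFs running from an ATG to the first in-frame stop codon; ORFs reaching
#' the end of the sequence without a stop are reported as incomplete.
#' Nested ATGs sharing a stop are each reported.
#'
#' @param mrna_seq nucleotide string over A, C, G, T, N.
#' @param min_aa minimum number of encoded residues (stop excluded).
#' @return data.frame with 1-based inclusive transcript coordinates
#'   \code{start}, \code{end} (end of stop codon, or of the last complete
#'   codon when incomplete), \code{frame} (0, 1, 2), \code{n_aa},
#'   \code{incomplete}; ordered longest first, ties by 5'-most start.
#' @export
find_orfs <- function(mrna_seq, min_aa = 30) {
  s <- toupper(mrna_seq)
  n <- nchar(s)
  out <- list()
  if (n >= 3) {
    chars <- strsplit(s, "")[[1]]
    for (f in 0:2) {
      starts <- seq.int(1 + f, n - 2, by = 3)
      codons <- paste0(chars[starts], chars[starts + 1], chars[starts + 2])
      is_atg <- codons == "ATG"
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      stop_idx <- which(is_stop)
      for (ai in which(is_atg)) {
        nxt <- stop_idx[stop_idx > ai]
        if (length(nxt)) {
          k <- nxt[1]
          n_aa <- k - ai
          out[[length(out) + 1]] <- data.frame(
            start = starts[ai], end = starts[k] + 2L, frame = f,
            n_aa = n_aa, incomplete = FALSE)
        } else {
          n_aa <- length(codons) - ai + 1L
          out[[length(out) + 1]] <- data.frame(
            start = starts[ai], end = starts[length(codons)] + 2L, frame = f,
            n_aa = n_aa, incomplete = TRUE)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), end = integer(), frame = integer(),
               n_aa = integer(), incomplete = logical())
  res <- res[res$n_aa >= min_aa, , drop = FALSE]
  res <- res[order(-res$n_aa, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Translate a coding sequence
#'
#' Standard genetic code; the trailing stop codon, if present, is removed.
#' An internal stop codon or a length not divisible by 3 raises an error.
#' Codons containing N translate to X.
#'
#' @param nt_seq nucleotide string with length divisible by 3.
#' @return amino-acid string (possibly empty).
#' @export
translate_cds <- function(nt_seq) {
  if (nchar(nt_seq) == 0) return("")
  if (nchar(nt_seq) %% 3 != 0) stop("sequence length not divisible by 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt_seq),
                                           if.fuzzy.codon = "solve", no.init.codon = TRUE))
  n <- nchar(aa)
  if (substr(aa, n, n) == "*") aa <- substr(aa, 1, n - 1)
  if (grepl("\\*", aa)) stop("internal stop codon in coding sequence")
  aa
}

#' Transfer MIKC domain boundaries to a query protein
#'
#' Maps the reference domain boundaries through a global pairwise alignment
#' onto the query protein. Boundaries falling on columns where the query is
#' gapped are snapped to the nearest aligned query residue toward the
#' domain interior. If the alignment identity is below the configured
#' floor the query is flagged unannotatable.
#'
#' @param query_protein,reference_protein amino-acid strings (or
#'   \code{protein_isoform} objects).
#' @param reference_domains \code{domain_annotation} of the reference.
#' @param query_id identifier for the result (defaults to the query's
#'   protein_id when available).
#' @param config a \code{pipeline_config}.
#' @return a \code{domain_annotation} for the query, or an object of class
#'   \code{unannotatable} carrying the alignment identity.
#' @export
transfer_domains <- function(query_protein, reference_protein,
                             reference_domains, query_id = NULL,
                             config = NULL) {
  config <- default_config(config)
  q <- if (inherits(query_protein, "protein_isoform"))
    query_protein$sequence else query_protein
  r <- if (inherits(reference_protein, "protein_isoform"))
    reference_protein$sequence else reference_protein
  if (is.null(query_id))
    query_id <- if (inherits(query_protein, "protein_isoform"))
      query_protein$protein_id else "query"
  aln <- align_global_aa(r, q, config)
  ident <- alignment_identity_pct(aln$a, aln$b)
  if (ident < config$domain_transfer_min_identity_pct)
    return(structure(list(protein_id = query_id, identity_pct = ident),
                     class = "unannotatable"))
  qidx <- alignment_index_map(aln$b)
  ridx <- alignment_index_map(aln$a)
  nq <- sum(aln$b != "-")
  map_boundary <- function(rpos, side) {
    col <- column_of_residue(aln$a, rpos)
    if (is.na(col) || col == 0) return(NA_integer_)
    if (!is.na(qidx[col])) return(qidx[col])
    # query gapped here: snap toward the domain interior
    if (side == "start") {
      later <- qidx[seq(col, length(qidx))]
      later <- later[!is.na(later)]
      if (length(later)) later[1] else nq
    } else {
      earlier <- qidx[seq_len(col)]
      earlier <- earlier[!is.na(earlier)]
      if (length(earlier)) earlier[length(earlier)] else 1L
    }
  }
  tr <- function(iv) c(map_boundary(iv[1], "start"), map_boundary(iv[2], "end"))
  d <- reference_domains
  domain_annotation(query_id, m = tr(d$m), i = tr(d$i), k = tr(d$k),
                    c = tr(d$c), kbox_cterm = tr(d$kbox_cterm))
}

#' @export
print.unannotatable <- function(x, ...) {
  cat("<unannotatable>", x$protein_id,
      sprintf("(alignment identity %.1f%% below floor)\n", x$identity_pct))
  invisible(x)
}
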