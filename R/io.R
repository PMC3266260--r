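#' Read gene models from GFF3 + genome FASTA
#'
#' Parses gene/mRNA/exon/CDS features into \code{transcript_model} objects
#' grouped by locus, converting from the GFF3 1-based inclusive convention
#' to internal 0-based half-open coordinates.
#'
#' @param gff3_path path to a GFF3 file with gene, mRNA, exon and CDS
#'   features linked by ID/Parent attributes.
#' @param fasta_path path to the genome FASTA; sequence names must match
#'   the GFF3 seqids.
#' @return list with elements \code{loci} (named list; each locus a named
#'   list of \code{transcript_model}s) and \code{genome} (DNAStringSet).
#' @export
read_gene_models <- function(gff3_path, fasta_path) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(gff3_path)
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)
  first_parent <- function(p) vapply(p, function(v)
    if (length(v)) v[[1]] else NA_character_, character(1))
  mrna_rows <- which(typ == "mRNA")
  loci <- list()
  for (mi in mrna_rows) {
    tid <- md$ID[mi]
    lid <- first_parent(md$Parent)[mi]
    if (is.na(lid)) lid <- tid
    chrom <- as.character(GenomicRanges::seqnames(gr)[mi])
    strand <- as.character(BiocGenerics::strand(gr)[mi])
    if (!strand %in% c("+", "-")) strand <- "+"
    if (!chrom %in% names(genome))
      stop("unknown chromosome in GFF3: ", chrom)
    child <- which(first_parent(md$Parent) == tid)
    pick <- function(what) {
      rows <- child[typ[child] == what]
      if (!length(rows)) return(NULL)
      m <- cbind(BiocGenerics::start(gr)[rows] - 1L, BiocGenerics::end(gr)[rows])
      m <- m[order(m[, 1]), , drop = FALSE]
      if (strand == "-") m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
      m
    }
    exons <- pick("exon")
    if (is.null(exons)) stop("mRNA ", tid, " has no exon features")
    if (any(exons[, 2] > length(genome[[chrom]])))
      stop("exon outside chromosome bounds for ", tid)
    cds <- pick("CDS")
    tx <- transcript_model(tid, lid, chrom, strand, exons, cds)
    if (is.null(loci[[lid]])) loci[[lid]] <- list()
    loci[[lid]][[tid]] <- tx
  }
  list(loci = loci, genome = genome)
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/exon/CDS features (1-based inclusive coordinates) for a
#' set of transcripts; used by the locus simulator and round-trip tests.
#'
#' @param transcripts list of \code{transcript_model}s.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_gff3 <- function(transcripts, path) {
  lines <- "##gff-version 3"
  by_locus <- split(transcripts,
                    vapply(transcripts, function(t) t$locus_id, character(1)))
  for (lid in names(by_locus)) {
    txs <- by_locus[[lid]]
    ex_all <- do.call(rbind, lapply(txs, function(t) t$exons))
    chrom <- txs[[1]]$chrom; strand <- txs[[1]]$strand
    lines <- c(lines, paste(chrom, "madsplice", "gene",
                            min(ex_all[, 1]) + 1L, max(ex_all[, 2]), ".",
                            strand, ".", paste0("ID=", lid), sep = "\t"))
    for (t in txs) {
      lines <- c(lines, paste(chrom, "madsplice", "mRNA",
                              min(t$exons[, 1]) + 1L, max(t$exons[, 2]), ".",
                              strand, ".",
                              paste0("ID=", t$transcript_id, ";Parent=", lid),
                              sep = "\t"))
      feat <- function(m, what, phase = ".") {
        vapply(seq_len(nrow(m)), function(j)
          paste(chrom, "madsplice", what, m[j, 1] + 1L, m[j, 2], ".",
                strand, if (identical(phase, ".")) "." else phase[j],
                paste0("ID=", t$transcript_id, ":", what, j,
                       ";Parent=", t$transcript_id), sep = "\t"),
          character(1))
      }
      lines <- c(lines, feat(t$exons, "exon"))
      if (!is.null(t$cds)) {
        # GFF3 CDS phase: nucleotides to discard before the first full codon
        lens <- t$cds[, 2] - t$cds[, 1]
        up <- c(0L, cumsum(lens)[-length(lens)])
        lines <- c(lines, feat(t$cds, "CDS", as.character((3L - up %% 3L) %% 3L)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or DNAStringSet.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a domain-boundary TSV
#'
#' Expected columns: protein_id, domain, start, end (1-based inclusive
#' residues); domain labels M, I, K, C and optionally KBOX_CTERM.
#'
#' @param path TSV file with header.
#' @return named list of \code{domain_annotation} objects.
#' @export
read_domains_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "domain", "start", "end")
  if (!all(need %in% names(d))) stop("domain TSV must have columns: ",
                                     paste(need, collapse = ", "))
  out <- list()
  for (pid in unique(d$protein_id)) {
    s <- d[d$protein_id == pid, ]
    get <- function(lbl) {
      r <- s[toupper(s$domain) == lbl, ]
      if (nrow(r) != 1) stop("protein ", pid, ": need exactly one ", lbl, " row")
      c(r$start, r$end)
    }
    kc <- s[toupper(s$domain) == "KBOX_CTERM", ]
    out[[pid]] <- domain_annotation(
      pid, m = get("M"), i = get("I"), k = get("K"), c = get("C"),
      kbox_cterm = if (nrow(kc) == 1) c(kc$start, kc$end) else NULL)
  }
  out
}

#' Write domain annotations to TSV
#' @param domains named list of \code{domain_annotation}s.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_domains_tsv <- function(domains, path) {
  rows <- do.call(rbind, lapply(domains, function(d)
    data.frame(protein_id = d$protein_id,
               domain = c("M", "I", "K", "C", "KBOX_CTERM"),
               start = c(d$m[1], d$i[1], d$k[1], d$c[1], d$kbox_cterm[1]),
               end = c(d$m[2], d$i[2], d$k[2], d$c[2], d$kbox_cterm[2]))))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interaction-motif TSV
#'
#' Expected columns: protein_id, motif_id, start, end (1-based inclusive
#' residues). Motif coordinates come from an upstream interaction-motif
#' predictor and are consumed as-is.
#'
#' @param path TSV file with header.
#' @return data.frame sorted by protein_id and start.
#' @export
read_motifs_tsv <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "motif_id", "start", "end")
  if (!all(need %in% names(m))) stop("motif TSV must have columns: ",
                                     paste(need, collapse = ", "))
  m[order(m$protein_id, m$start), need]
}
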