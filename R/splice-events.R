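#' Cluster introns by genomic overlap
#'
#' Single-linkage partition of a locus's introns under interval overlap
#' (two introns sharing at least one nucleotide join the same cluster).
#' Identical intervals contributed by different transcripts remain
#' distinct members of their cluster. Overlap clustering (rather than
#' exact-coordinate grouping) keeps retained and alternative-site introns
#' together with their fully spliced counterparts.
#'
#' @param introns data.frame as returned by \code{\link{get_introns}},
#'   possibly row-bound over the isoforms of one locus; may carry a
#'   \code{locus_id} column (mixed loci raise an error).
#' @return list of clusters, each a list with \code{members} (data.frame)
#'   and \code{span} (c(start, end), 0-based half-open).
#' @export
cluster_introns <- function(introns) {
  if (nrow(introns) == 0) return(list())
  if ("locus_id" %in% names(introns) &&
      length(unique(introns$locus_id)) > 1)
    stop("cluster_introns: introns from more than one locus")
  o <- order(introns$start, introns$end)
  introns <- introns[o, , drop = FALSE]
  cl <- integer(nrow(introns))
  cur <- 0L
  cur_end <- -1L
  for (j in seq_len(nrow(introns))) {
    if (introns$start[j] < cur_end) {
      cl[j] <- cur
      cur_end <- max(cur_end, introns$end[j])
    } else {
      cur <- cur + 1L
      cl[j] <- cur
      cur_end <- introns$end[j]
    }
  }
  lapply(split(seq_len(nrow(introns)), cl), function(rows) {
    m <- introns[rows, , drop = FALSE]
    rownames(m) <- NULL
    list(members = m, span = c(min(m$start), max(m$end)))
  })
}

#' Is an intron cluster an AS cluster?
#'
#' A cluster corresponds to an alternative splicing event when it contains
#' at least two distinct intron intervals, or when its single intron is
#' retained (fully exonic) in another transcript of the locus.
#'
#' @param cluster one element of \code{\link{cluster_introns}} output.
#' @param transcripts list of the locus's \code{transcript_model}s.
#' @return logical.
#' @export
cluster_is_as <- function(cluster, transcripts) {
  m <- cluster$members
  if (nrow(unique(m[, c("start", "end")])) >= 2) return(TRUE)
  s <- m$start[1]; e <- m$end[1]
  src <- unique(m$transcript_id)
  for (t in transcripts) {
    if (t$transcript_id %in% src) next
    if (any(t$exons[, 1] <= s & e <= t$exons[, 2])) return(TRUE)
  }
  FALSE
}

# Orient coordinates so transcription runs left to right: identity on "+",
# x -> -x reflection on "-" (half-open (s,e) -> (-e,-s)).
orient_matrix <- function(m, strand) {
  if (strand == "+") return(m[order(m[, 1]), , drop = FALSE])
  m2 <- cbind(-m[, 2], -m[, 1])
  m2[order(m2[, 1]), , drop = FALSE]
}

deorient_span <- function(span, strand) {
  if (strand == "+") span else c(-span[2], -span[1])
}

introns_from_chain <- function(ex) {
  n <- nrow(ex)
  if (n < 2) return(matrix(integer(), ncol = 2))
  cbind(ex[-n, 2], ex[-1, 1])
}

#' Detect and type AS events between two isoforms
#'
#' Compares the exon chains of two isoforms of one locus and decomposes
#' their differences 5' to 3' into independent local events, each typed as
#' one of: \code{alt_donor}, \code{alt_acceptor}, \code{exon_skip},
#' \code{intron_retention}, \code{mutually_exclusive}, \code{cryptic_exon};
#' unresolvable differences are labelled \code{complex}. Typing is relative
#' to \code{isoform_a} as the reference: an exon present in the reference
#' and absent from the other isoform is an exon skip, while an extra exon
#' of the other isoform lying inside a reference intron is a cryptic exon.
#'
#' @param isoform_a,isoform_b \code{transcript_model}s from the same locus
#'   and strand; \code{isoform_a} is treated as the reference.
#' @return list of \code{as_event} objects (possibly empty), ordered 5' to
#'   3' in transcription order. Each event carries \code{event_type},
#'   \code{locus_id}, \code{isoform_a}, \code{isoform_b}, \code{chrom},
#'   \code{strand}, \code{start}, \code{end} (genomic footprint, 0-based
#'   half-open) and \code{intron_index_a} (reference intron index the event
#'   touches, NA when none).
#' @export
detect_events <- function(isoform_a, isoform_b) {
  if (isoform_a$locus_id != isoform_b$locus_id ||
      isoform_a$strand != isoform_b$strand ||
      isoform_a$chrom != isoform_b$chrom)
    stop("isoforms must come from the same locus, chromosome and strand")
  strand <- isoform_a$strand
  ea <- orient_matrix(isoform_a$exons, strand)
  eb <- orient_matrix(isoform_b$exons, strand)
  if (nrow(ea) == nrow(eb) && all(ea == eb)) return(list())
  ia <- introns_from_chain(ea)
  ib <- introns_from_chain(eb)
  key <- function(m) paste(m[, 1], m[, 2])
  shared <- intersect(key(ia), key(ib))
  da <- ia[!key(ia) %in% shared, , drop = FALSE]
  db <- ib[!key(ib) %in% shared, , drop = FALSE]
  events <- list()
  mk_event <- function(type, span) {
    gspan <- deorient_span(span, strand)
    # reference intron index overlapping the event footprint, if any
    ridx <- NA_integer_
    if (nrow(ia) > 0) {
      ov <- which(ia[, 1] < span[2] & span[1] < ia[, 2])
      if (length(ov)) {
        # indices follow transcription order of the reference
        ridx <- ov[1]
      }
    }
    structure(list(event_type = type, locus_id = isoform_a$locus_id,
                   isoform_a = isoform_a$transcript_id,
                   isoform_b = isoform_b$transcript_id,
                   chrom = isoform_a$chrom, strand = strand,
                   start = gspan[1], end = gspan[2],
                   intron_index_a = ridx),
              class = "as_event")
  }
  if (nrow(da) == 0 && nrow(db) == 0) {
    # identical intron chains but differing exon chains: terminal difference
    span <- range(c(ea, eb))
    return(list(mk_event("complex", c(span[1], span[2]))))
  }
  # group non-shared introns of both chains into difference regions by
  # single-linkage overlap
  all_d <- rbind(cbind(da, rep(0L, nrow(da))),
                 cbind(db, rep(1L, nrow(db))))
  o <- order(all_d[, 1], all_d[, 2])
  all_d <- all_d[o, , drop = FALSE]
  comp <- integer(nrow(all_d)); cur <- 0L; cur_end <- -Inf
  for (j in seq_len(nrow(all_d))) {
    if (all_d[j, 1] < cur_end) {
      comp[j] <- cur; cur_end <- max(cur_end, all_d[j, 2])
    } else {
      cur <- cur + 1L; comp[j] <- cur; cur_end <- all_d[j, 2]
    }
  }
  inside_exon <- function(ex, iv)
    any(ex[, 1] <= iv[1] & iv[2] <= ex[, 2])
  inside_intron <- function(intr, iv)
    nrow(intr) > 0 && any(intr[, 1] <= iv[1] & iv[2] <= intr[, 2])
  for (cc in split(seq_len(nrow(all_d)), comp)) {
    g <- all_d[cc, , drop = FALSE]
    ga <- g[g[, 3] == 0L, , drop = FALSE]
    gb <- g[g[, 3] == 1L, , drop = FALSE]
    span <- c(min(g[, 1]), max(g[, 2]))
    na <- nrow(ga); nb <- nrow(gb)
    type <- "complex"
    if (na == 1 && nb == 1) {
      if (ga[1, 2] == gb[1, 2] && ga[1, 1] != gb[1, 1]) type <- "alt_donor"
      else if (ga[1, 1] == gb[1, 1] && ga[1, 2] != gb[1, 2]) type <- "alt_acceptor"
    } else if (na == 1 && nb == 0) {
      if (inside_exon(eb, ga[1, 1:2])) type <- "intron_retention"
    } else if (na == 0 && nb == 1) {
      if (inside_exon(ea, gb[1, 1:2])) type <- "intron_retention"
    } else if (na == 2 && nb == 1) {
      mid <- c(ga[1, 2], ga[2, 1])  # reference exon between its two introns
      if (ga[1, 1] == gb[1, 1] && ga[2, 2] == gb[1, 2] &&
          inside_intron(gb[, 1:2, drop = FALSE], mid))
        type <- "exon_skip"
    } else if (na == 1 && nb == 2) {
      mid <- c(gb[1, 2], gb[2, 1])  # novel exon of b inside a's intron
      if (gb[1, 1] == ga[1, 1] && gb[2, 2] == ga[1, 2] &&
          inside_intron(ga[, 1:2, drop = FALSE], mid))
        type <- "cryptic_exon"
    } else if (na == 2 && nb == 2) {
      mida <- c(ga[1, 2], ga[2, 1]); midb <- c(gb[1, 2], gb[2, 1])
      outer_ok <- ga[1, 1] == gb[1, 1] && ga[2, 2] == gb[2, 2]
      disjoint <- mida[2] <= midb[1] || midb[2] <= mida[1]
      if (outer_ok && disjoint && !identical(mida, midb))
        type <- "mutually_exclusive"
    }
    events[[length(events) + 1]] <- mk_event(type, span)
  }
  # components were visited in oriented coordinate order, i.e. 5' to 3'
  events
}

#' @export
print.as_event <- function(x, ...) {
  cat("<as_event>", x$event_type, "at", x$chrom,
      paste0("[", x$start, ",", x$end, ")"), x$strand, "\n")
  cat("  ", x$isoform_a, "vs", x$isoform_b, "(locus", x$locus_id, ")\n")
  invisible(x)
}

# Transcript coordinates (1-based) of the exonic nucleotides of tx that
# fall inside the genomic interval [gstart, gend).
tx_positions_in_interval <- function(tx, gstart, gend) {
  lens <- exon_lengths(tx)
  offs <- c(0L, cumsum(lens))
  pos <- integer()
  for (j in seq_len(nrow(tx$exons))) {
    s <- max(tx$exons[j, 1], gstart); e <- min(tx$exons[j, 2], gend)
    if (s >= e) next
    if (tx$strand == "+") {
      rel <- (s:(e - 1)) - tx$exons[j, 1]
    } else {
      rel <- tx$exons[j, 2] - ((e - 1):s) - 1L
    }
    pos <- c(pos, offs[j] + rel + 1L)
  }
  sort(pos)
}

#' Protein-level effect of an AS event
#'
#' Globally aligns the two protein isoforms and measures the difference
#' within the event's footprint: \code{aa_difference} counts alignment
#' columns in the affected region that are gapped or mismatched;
#' \code{frame_shift} is TRUE when the event changes the coding length by
#' a non-multiple of 3; \code{truncation_aa} counts residues of the longer
#' protein beyond the last aligned column.
#'
#' @param event an \code{as_event}.
#' @param protein_a,protein_b \code{protein_isoform}s of the two isoforms.
#' @param tx_a,tx_b the corresponding \code{transcript_model}s (used to
#'   project the genomic footprint onto protein coordinates).
#' @param config a \code{pipeline_config}.
#' @return object of class \code{as_effect} with fields \code{region_a},
#'   \code{region_b} (residue intervals, possibly zero-length),
#'   \code{aa_difference}, \code{frame_shift}, \code{truncation_aa}.
#' @export
event_effect <- function(event, protein_a, protein_b, tx_a, tx_b,
                         config = NULL) {
  config <- default_config(config)
  if (!inherits(protein_a, "protein_isoform") ||
      !inherits(protein_b, "protein_isoform"))
    stop("protein_a/protein_b must be protein_isoform objects")
  aln <- align_global_aa(protein_a$sequence, protein_b$sequence, config)
  region_for <- function(prot, tx) {
    txpos <- tx_positions_in_interval(tx, event$start, event$end)
    txpos <- txpos[txpos >= prot$orf_tx_start & txpos <= prot$orf_tx_end - 3L]
    if (!length(txpos)) return(integer())
    res <- unique((txpos - prot$orf_tx_start) %/% 3L + 1L)
    res[res >= 1 & res <= nchar(prot$sequence)]
  }
  ra <- region_for(protein_a, tx_a)
  rb <- region_for(protein_b, tx_b)
  ia <- alignment_index_map(aln$a)
  ib <- alignment_index_map(aln$b)
  cols <- which((!is.na(ia) & ia %in% ra) | (!is.na(ib) & ib %in% rb))
  if (length(cols)) {
    lo <- min(cols); hi <- max(cols)
    # include whole gap runs straddling the projected region: the aligner
    # may slide an indel by a few columns when flanking residues repeat
    any_gap <- aln$a == "-" | aln$b == "-"
    while (lo > 1 && any_gap[lo - 1]) lo <- lo - 1
    while (hi < length(any_gap) && any_gap[hi + 1]) hi <- hi + 1
    cols <- seq(lo, hi)
  }
  aa_diff <- sum(aln$a[cols] == "-" | aln$b[cols] == "-" |
                   aln$a[cols] != aln$b[cols])
  nt_a <- length(tx_positions_in_interval(tx_a, event$start, event$end))
  nt_b <- length(tx_positions_in_interval(tx_b, event$start, event$end))
  frame_shift <- ((nt_a - nt_b) %% 3L) != 0L
  both <- which(aln$a != "-" & aln$b != "-")
  trunc <- 0L
  if (length(both)) {
    last <- max(both)
    tail_cols <- seq_len(length(aln$a)) > last
    longer <- if (nchar(protein_a$sequence) >= nchar(protein_b$sequence))
      aln$a else aln$b
    trunc <- sum(longer[tail_cols] != "-")
  }
  structure(list(event = event,
                 region_a = if (length(ra)) range(ra) else integer(),
                 region_b = if (length(rb)) range(rb) else integer(),
                 aa_difference = as.integer(aa_diff),
                 frame_shift = frame_shift,
                 truncation_aa = as.integer(trunc)),
            class = "as_effect")
}

#' @export
print.as_effect <- function(x, ...) {
  cat("<as_effect>", x$aa_difference, "aa difference;",
      if (x$frame_shift) "frame shift;" else "in frame;",
      x$truncation_aa, "aa truncation\n")
  invisible(x)
}

#' Assign a protein-domain label to an effect region
#'
#' The label is the unique domain containing the affected residue
#' interval; an interval including the last residue of one domain and the
#' first residue of the next is a border ("border-X/Y"); an interval
#' outside every domain is "outside".
#'
#' @param effect an \code{as_effect}, or a length-2 residue interval on the
#'   annotated (reference) isoform.
#' @param domains a \code{domain_annotation} for the reference isoform.
#' @return character domain label: "M", "I", "K", "C", "border-X/Y" or
#'   "outside".
#' @export
assign_domain <- function(effect, domains) {
  iv <- if (inherits(effect, "as_effect")) {
    if (length(effect$region_a)) effect$region_a else effect$region_b
  } else effect
  if (!length(iv)) return("outside")
  iv <- as.integer(range(iv))
  doms <- list(M = domains$m, I = domains$i, K = domains$k, C = domains$c)
  labs <- names(doms)
  for (j in seq_len(length(doms) - 1)) {
    if (iv[1] <= doms[[j]][2] && iv[2] >= doms[[j + 1]][1])
      return(paste0("border-", labs[j], "/", labs[j + 1]))
  }
  for (j in seq_along(doms)) {
    if (iv[1] >= doms[[j]][1] && iv[2] <= doms[[j]][2]) return(labs[j])
  }
  ov <- vapply(doms, function(d)
    max(0L, min(iv[2], d[2]) - max(iv[1], d[1]) + 1L), integer(1))
  if (all(ov == 0)) return("outside")
  labs[which.max(ov)]
}

#' Domain label for an intron cluster
#'
#' Labels a cluster by where its introns interrupt the reference protein:
#' the junction after residue p lies in domain X when both p and p+1 fall
#' inside X, on a border when p ends one domain and p+1 starts the next.
#'
#' @param cluster an intron cluster (see \code{\link{cluster_introns}}).
#' @param domains \code{domain_annotation} of the reference protein.
#' @return character label.
#' @export
label_cluster_domain <- function(cluster, domains) {
  p <- cluster$members$protein_position
  p <- p[!is.na(p)]
  if (!length(p)) return("outside")
  p <- as.integer(round(stats::median(p)))
  doms <- list(M = domains$m, I = domains$i, K = domains$k, C = domains$c)
  labs <- names(doms)
  for (j in seq_len(length(doms) - 1)) {
    if (p == doms[[j]][2] && p + 1L == doms[[j + 1]][1])
      return(paste0("border-", labs[j], "/", labs[j + 1]))
  }
  for (j in seq_along(doms)) {
    if (p >= doms[[j]][1] && p + 1L <= doms[[j]][2]) return(labs[j])
  }
  "outside"
}

#' Per-domain AS prevalence counts
#'
#' @param labels character vector of cluster domain labels.
#' @param as_flags logical vector (same length): is the cluster involved in
#'   an AS event?
#' @return data.frame of class \code{domain_as_counts} with columns
#'   \code{domain}, \code{n_clusters_total}, \code{n_clusters_as},
#'   \code{fraction}; labels with zero clusters are omitted.
#' @export
domain_as_counts <- function(labels, as_flags) {
  stopifnot(length(labels) == length(as_flags))
  tot <- table(labels)
  as_n <- tapply(as_flags, labels, sum)
  out <- data.frame(domain = names(tot),
                    n_clusters_total = as.integer(tot),
                    n_clusters_as = as.integer(as_n[names(tot)]),
                    stringsAsFactors = FALSE)
  out$fraction <- out$n_clusters_as / out$n_clusters_total
  class(out) <- c("domain_as_counts", "data.frame")
  out
}

#' Fisher's exact test for per-domain AS enrichment
#'
#' For each domain D, a two-sided Fisher's exact test on the 2x2 table
#' (AS / non-AS clusters) x (D / all other domains combined), computed
#' exactly from the hypergeometric distribution. Degenerate tables with a
#' zero margin give p = 1.
#'
#' @param counts a \code{domain_as_counts} data.frame (or any data.frame
#'   with columns domain, n_clusters_total, n_clusters_as).
#' @return the input with an added \code{p_value} column.
#' @export
fisher_domain_enrichment <- function(counts) {
  if (nrow(counts) < 2)
    stop("need at least two domain labels with nonzero totals")
  tot_as <- sum(counts$n_clusters_as)
  tot_all <- sum(counts$n_clusters_total)
  counts$p_value <- vapply(seq_len(nrow(counts)), function(j) {
    a <- counts$n_clusters_as[j]
    b <- counts$n_clusters_total[j] - a
    c_ <- tot_as - a
    d <- (tot_all - counts$n_clusters_total[j]) - c_
    m <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
    stats::fisher.test(m, alternative = "two.sided")$p.value
  }, numeric(1))
  counts
}
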