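#' Six-frame stop-to-stop translation of a contig
#'
#' Translates a nucleotide contig in all six reading frames and reports
#' every stop-to-stop open reading frame encoding at least
#' \code{min_orf_aa} residues, with the nucleotide interval it occupies on
#' the input contig (1-based inclusive, forward-strand coordinates).
#'
#' @param contig nucleotide string.
#' @param min_orf_aa minimum peptide length.
#' @param contig_id,species identifiers carried through to the output.
#' @return data.frame with columns \code{contig_id}, \code{species},
#'   \code{frame} (+1,+2,+3,-1,-2,-3), \code{nt_start}, \code{nt_end},
#'   \code{peptide}.
#' @export
six_frame_orfs <- function(contig, min_orf_aa = 30, contig_id = "contig",
                           species = NA_character_) {
  n <- nchar(contig)
  out <- list()
  scan_strand <- function(seq, sign) {
    for (off in 0:2) {
      len <- (nchar(seq) - off) %/% 3 * 3
      if (len < 3) next
      aa <- translate_str(substr(seq, off + 1, off + len))
      # split on stops, tracking residue offsets
      segs <- strsplit(aa, "\\*")[[1]]
      pos <- 0L
      for (sg in segs) {
        # segments of only X (e.g. runs of N) are not ORFs
        if (nchar(sg) >= min_orf_aa && grepl("[^X]", sg)) {
          aa_start <- pos + 1L
          nt_start_f <- off + (aa_start - 1L) * 3L + 1L  # on this strand
          nt_end_f <- nt_start_f + nchar(sg) * 3L - 1L
          if (sign > 0) {
            s <- nt_start_f; e <- nt_end_f
          } else {
            s <- n - nt_end_f + 1L; e <- n - nt_start_f + 1L
          }
          out[[length(out) + 1]] <<- data.frame(
            contig_id = contig_id, species = species,
            frame = sign * (off + 1L), nt_start = s, nt_end = e,
            peptide = sg, stringsAsFactors = FALSE)
        }
        pos <- pos + nchar(sg) + 1L
      }
    }
  }
  scan_strand(contig, +1L)
  scan_strand(revcomp_str(contig), -1L)
  if (length(out)) do.call(rbind, out) else
    data.frame(contig_id = character(), species = character(),
               frame = integer(), nt_start = integer(), nt_end = integer(),
               peptide = character(), stringsAsFactors = FALSE)
}

#' Best homolog of a translated fragment
#'
#' Local (Smith-Waterman) alignment of the fragment against every protein
#' of the reference proteome; the highest-scoring hit wins, ties broken by
#' higher identity and then lexicographic protein id. The hit is returned
#' only when identity is at least \code{homolog_min_identity_pct} (default
#' 40%) over the aligned columns and at least
#' \code{homolog_min_coverage_pct} (default 60%) of the reference residues
#' are covered.
#'
#' @param fragment peptide string (one row of \code{\link{six_frame_orfs}}
#'   output, or a plain string).
#' @param reference_proteome named character vector (or AAStringSet) of
#'   reference protein sequences.
#' @param config a \code{pipeline_config}.
#' @return object of class \code{homolog_hit} (fields \code{protein_id},
#'   \code{identity_pct}, \code{coverage_pct}, \code{score}), or NULL when
#'   no hit passes the filter.
#' @export
best_homolog <- function(fragment, reference_proteome, config = NULL) {
  config <- default_config(config)
  pep <- if (is.data.frame(fragment)) fragment$peptide[1] else
    as.character(fragment)
  if (length(reference_proteome) == 0) stop("empty reference proteome")
  prot <- as.character(reference_proteome)
  names(prot) <- names(reference_proteome)
  if (is.null(names(prot))) names(prot) <- paste0("ref", seq_along(prot))
  hits <- lapply(names(prot), function(pid) {
    aln <- align_local_aa(pep, prot[[pid]], config)
    list(protein_id = pid,
         score = aln$score,
         identity_pct = alignment_identity_pct(aln$a, aln$b),
         coverage_pct = 100 * (aln$b_end - aln$b_start + 1) / nchar(prot[[pid]]))
  })
  score <- vapply(hits, `[[`, numeric(1), "score")
  ident <- vapply(hits, `[[`, numeric(1), "identity_pct")
  ids <- vapply(hits, `[[`, character(1), "protein_id")
  best <- order(-score, -ident, ids)[1]
  h <- hits[[best]]
  if (h$identity_pct < config$homolog_min_identity_pct ||
      h$coverage_pct < config$homolog_min_coverage_pct) return(NULL)
  structure(h, class = "homolog_hit")
}

#' Map reference intron positions onto a subject protein
#'
#' Transfers intron positions (expressed as the number of complete codons
#' upstream of each intron on the reference protein, see
#' \code{\link{get_introns}}) through a Needleman-Wunsch global alignment
#' onto subject-protein residue coordinates. An intron whose junction falls
#' where the subject is gapped is flagged unmapped. For each intron the map
#' also records whether the alignment is gap-free within a window of
#' \code{gapless_window_aa} residues around the position (the gapless
#' anchor used by AIP detection).
#'
#' @param subject_protein subject amino-acid string (or
#'   \code{protein_isoform}).
#' @param reference_protein reference amino-acid string (or
#'   \code{protein_isoform}).
#' @param reference_introns data.frame with columns \code{intron_index} and
#'   \code{protein_position} (and optionally \code{phase}).
#' @param protein_id identifier of the subject protein in the map.
#' @param config a \code{pipeline_config}.
#' @return object of class \code{intron_position_map}: list with
#'   \code{protein_id}, \code{identity_pct} and \code{positions}, a
#'   data.frame (intron_index, ref_position, subject_position, phase,
#'   mapped, gapless_window).
#' @export
map_intron_positions <- function(subject_protein, reference_protein,
                                 reference_introns, protein_id = NULL,
                                 config = NULL) {
  config <- default_config(config)
  s <- if (inherits(subject_protein, "protein_isoform"))
    subject_protein$sequence else subject_protein
  r <- if (inherits(reference_protein, "protein_isoform"))
    reference_protein$sequence else reference_protein
  if (is.null(protein_id))
    protein_id <- if (inherits(subject_protein, "protein_isoform"))
      subject_protein$protein_id else "subject"
  aln <- align_global_aa(r, s, config)
  ident <- alignment_identity_pct(aln$a, aln$b)
  ok <- ident >= config$homolog_min_identity_pct
  ri <- reference_introns[!is.na(reference_introns$protein_position), ,
                          drop = FALSE]
  sidx <- alignment_index_map(aln$b)
  w <- config$gapless_window_aa
  rows <- lapply(seq_len(nrow(ri)), function(j) {
    p <- ri$protein_position[j]
    colp <- column_of_residue(aln$a, p)
    colp1 <- column_of_residue(aln$a, p + 1L)
    mapped <- FALSE; spos <- NA_integer_; gapless <- FALSE
    if (ok && !is.na(colp1)) {
      gap_at_junction <-
        (colp > 0 && aln$b[colp] == "-") || aln$b[colp1] == "-"
      if (!gap_at_junction) {
        mapped <- TRUE
        spos <- if (colp == 0) 0L else sidx[colp]
        lo <- column_of_residue(aln$a, max(1L, p - w + 1L))
        hi <- column_of_residue(aln$a, min(sum(aln$a != "-"), p + w))
        if (!is.na(lo) && !is.na(hi) && lo >= 1) {
          win <- seq(lo, hi)
          gapless <- !any(aln$a[win] == "-" | aln$b[win] == "-")
        }
      }
    }
    data.frame(intron_index = ri$intron_index[j], ref_position = p,
               subject_position = spos,
               phase = if ("phase" %in% names(ri)) ri$phase[j] else NA_integer_,
               mapped = mapped, gapless_window = gapless)
  })
  positions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(intron_index = integer(), ref_position = integer(),
               subject_position = integer(), phase = integer(),
               mapped = logical(), gapless_window = logical())
  structure(list(protein_id = protein_id, identity_pct = ident,
                 positions = positions),
            class = "intron_position_map")
}

#' @export
print.intron_position_map <- function(x, ...) {
  cat("<intron_position_map>", x$protein_id,
      sprintf("(identity %.1f%%): %d position(s), %d mapped\n",
              x$identity_pct, nrow(x$positions), sum(x$positions$mapped)))
  invisible(x)
}

#' Detect AS-induced polymorphisms between two protein isoforms
#'
#' Globally aligns the two isoforms and inspects every maximal gap run
#' (indel). A run is an AIP candidate when a mapped intron position
#' coincides with it: the junction of the intron, transferred onto either
#' isoform's coordinates, falls inside or within
#' \code{aip_junction_slack_cols} columns of the run (slack absorbs
#' co-optimal gap placements that slide an indel along repeated flank
#' residues). A
#' candidate is kept when (i) the 10 alignment columns immediately
#' flanking the polymorphic region (5 on each side) contain at least 4
#' identical residue pairs and at most 1 gapped position, and (ii) at
#' least one of the isoforms aligns to the reference without gaps in a
#' window around the intron position (the \code{gapless_window} flag of
#' the supplied maps).
#'
#' @param isoform_a,isoform_b amino-acid strings or \code{protein_isoform}s
#'   of two isoforms of the same (subject) gene.
#' @param intron_map an \code{intron_position_map} for \code{isoform_a}
#'   (positions in isoform_a residue coordinates), or a list of one or two
#'   maps whose \code{protein_id}s identify the isoform they refer to.
#' @param config a \code{pipeline_config}.
#' @return list of objects of class \code{aip}: fields \code{isoform_a},
#'   \code{isoform_b}, \code{intron_index}, \code{indel_peptide},
#'   \code{longer_isoform_seq}, \code{columns} (alignment column range),
#'   \code{flank_identical}, \code{flank_gapped}, \code{passes_flank_rule},
#'   \code{gapless_anchor}.
#' @export
detect_aips <- function(isoform_a, isoform_b, intron_map, config = NULL) {
  config <- default_config(config)
  ida <- if (inherits(isoform_a, "protein_isoform")) isoform_a$protein_id else "isoform_a"
  idb <- if (inherits(isoform_b, "protein_isoform")) isoform_b$protein_id else "isoform_b"
  sa <- if (inherits(isoform_a, "protein_isoform")) isoform_a$sequence else isoform_a
  sb <- if (inherits(isoform_b, "protein_isoform")) isoform_b$sequence else isoform_b
  if (nchar(sa) == 0 || nchar(sb) == 0) stop("empty isoform sequence")
  maps <- if (inherits(intron_map, "intron_position_map"))
    list(intron_map) else intron_map
  aln <- align_global_aa(sa, sb, config)
  ncol_aln <- length(aln$a)
  gapped <- aln$a == "-" | aln$b == "-"
  if (!any(gapped)) return(list())
  r <- rle(gapped)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  half <- config$flank_window_cols %/% 2
  out <- list()
  # junction columns of each mapped intron position on each isoform
  junctions <- list()
  for (m in maps) {
    row_chars <- if (identical(m$protein_id, idb)) aln$b else aln$a
    pos <- m$positions
    for (j in seq_len(nrow(pos))) {
      if (!pos$mapped[j]) next
      p <- pos$subject_position[j]
      cl <- column_of_residue(row_chars, p)
      cr <- column_of_residue(row_chars, p + 1L)
      if (is.na(cr)) cr <- ncol_aln + 1L
      junctions[[length(junctions) + 1]] <-
        list(intron_index = pos$intron_index[j], left = cl, right = cr,
             gapless = pos$gapless_window[j])
    }
  }
  if (!length(junctions)) return(list())
  slack <- config$aip_junction_slack_cols
  for (ri in seq_len(nrow(runs))) {
    c1 <- runs[ri, 1]; c2 <- runs[ri, 2]
    hit <- NULL
    for (jn in junctions) {
      # the junction interval (left, right) intersects the run, allowing
      # a few columns of slack for co-optimal gap placements that slide
      # an indel past the junction along a repeated residue
      if (jn$left <= c2 + slack && jn$right >= c1 - slack) { hit <- jn; break }
    }
    if (is.null(hit)) next
    left <- seq(max(1, c1 - half), c1 - 1)
    right_ <- seq(c2 + 1, min(ncol_aln, c2 + half))
    left <- left[left >= 1]; right_ <- right_[right_ <= ncol_aln]
    fl <- c(left, right_)
    flank_identical <- sum(aln$a[fl] != "-" & aln$b[fl] != "-" &
                             aln$a[fl] == aln$b[fl])
    flank_gapped <- sum(aln$a[fl] == "-" | aln$b[fl] == "-")
    passes <- flank_identical >= config$flank_min_identical &&
      flank_gapped <= config$flank_max_gapped
    if (!passes) next
    if (!isTRUE(hit$gapless)) next
    longer <- if (nchar(sa) >= nchar(sb)) sa else sb
    indel_chars <- if (all(aln$b[c1:c2] == "-")) aln$a[c1:c2] else aln$b[c1:c2]
    out[[length(out) + 1]] <- structure(
      list(isoform_a = ida, isoform_b = idb,
           intron_index = hit$intron_index,
           indel_peptide = paste(indel_chars[indel_chars != "-"],
                                 collapse = ""),
           longer_isoform_seq = longer,
           columns = c(c1, c2),
           flank_identical = as.integer(flank_identical),
           flank_gapped = as.integer(flank_gapped),
           passes_flank_rule = passes,
           gapless_anchor = TRUE),
      class = "aip")
  }
  out
}

#' @export
print.aip <- function(x, ...) {
  cat("<aip>", x$isoform_a, "vs", x$isoform_b, "at intron",
      x$intron_index, ": indel", x$indel_peptide,
      sprintf("(flanks %d identical / %d gapped)\n",
              x$flank_identical, x$flank_gapped))
  invisible(x)
}

#' Conservation call between two AIPs
#'
#' Two AIPs (typically one from the focal species, one from another
#' species, at homologous intron positions) are considered conserved when
#' the global alignment between the corresponding longer-isoform sequences
#' is at least \code{aip_conservation_min_similarity_pct} (default 40%)
#' similar. Similarity is the percentage of alignment columns with a
#' positive BLOSUM62 score, gap columns counting in the denominator.
#'
#' @param query_aip,subject_aip \code{aip} objects.
#' @param config a \code{pipeline_config}.
#' @return object of class \code{aip_conservation}: \code{similarity_pct},
#'   \code{conserved}.
#' @export
call_conservation <- function(query_aip, subject_aip, config = NULL) {
  config <- default_config(config)
  # canonical argument order keeps the call exactly symmetric even when
  # the aligner would report different co-optimal paths for (a, b) and
  # (b, a)
  x <- query_aip$longer_isoform_seq
  y <- subject_aip$longer_isoform_seq
  if (x > y) { tmp <- x; x <- y; y <- tmp }
  aln <- align_global_aa(x, y, config)
  sim <- alignment_similarity_pct(aln$a, aln$b)
  structure(list(query = query_aip, subject = subject_aip,
                 similarity_pct = sim,
                 conserved = sim >= config$aip_conservation_min_similarity_pct),
            class = "aip_conservation")
}

#' @export
print.aip_conservation <- function(x, ...) {
  cat("<aip_conservation>", sprintf("similarity %.1f%% -> %s\n",
                                    x$similarity_pct,
                                    if (x$conserved) "conserved" else
                                      "not conserved"))
  invisible(x)
}

#' Scan an intron for a cryptic-exon remnant (exonization potential)
#'
#' Locally aligns an exon against an intron sequence. When a homologous
#' region is found, the scan locates the nearest AG acceptor dinucleotide
#' at or upstream of the region's 5' edge, reports the offset between that
#' acceptor and the homologous region (in nt), whether splicing at it
#' would preserve the exon's reading frame (offset divisible by 3), and
#' whether the homologous region contains an in-frame termination codon
#' when translated in the exon's frame. The region is deemed translatable
#' only when the frame is preserved and no in-frame stop is present.
#'
#' @param exon_nt,intron_nt nucleotide strings (each at least 20 nt).
#' @param config a \code{pipeline_config}.
#' @return object of class \code{exonization_report}: \code{hit},
#'   \code{score}, \code{identity_pct}, \code{exon_interval},
#'   \code{intron_interval} (1-based), \code{acceptor_offset_nt},
#'   \code{frame_preserved}, \code{in_frame_stop}, \code{translatable}.
#' @export
exonization_scan <- function(exon_nt, intron_nt, config = NULL) {
  config <- default_config(config)
  if (nchar(exon_nt) < 20 || nchar(intron_nt) < 20)
    stop("exon and intron sequences must be at least 20 nt")
  aln <- align_local_nt(exon_nt, intron_nt, config)
  no_hit <- structure(list(hit = FALSE, score = aln$score,
                           identity_pct = NA_real_,
                           exon_interval = NULL, intron_interval = NULL,
                           acceptor_offset_nt = NA_integer_,
                           frame_preserved = NA, in_frame_stop = NA,
                           translatable = NA),
                      class = "exonization_report")
  if (aln$score < config$nt_score_floor) return(no_hit)
  a_chars <- strsplit(aln$a_aln, "")[[1]]
  b_chars <- strsplit(aln$b_aln, "")[[1]]
  ident <- alignment_identity_pct(a_chars, b_chars)
  # nearest AG ending at or upstream of the homologous region's 5' edge
  start_i <- aln$b_start
  intron_chars <- strsplit(toupper(intron_nt), "")[[1]]
  offset <- NA_integer_
  j <- start_i - 2L
  while (j >= 1) {
    if (intron_chars[j] == "A" && intron_chars[j + 1] == "G") {
      offset <- start_i - j - 2L
      break
    }
    j <- j - 1L
  }
  frame_preserved <- !is.na(offset) && offset %% 3L == 0L
  # translate the homologous intron region in the exon's frame: shift to
  # the first position matching a codon boundary of the aligned exon region
  f <- (aln$a_start - 1L) %% 3L
  shift <- (3L - f) %% 3L
  t_start <- aln$b_start + shift
  t_len <- (aln$b_end - t_start + 1L) %/% 3L * 3L
  in_frame_stop <- FALSE
  if (t_len >= 3) {
    aa <- translate_str(substr(intron_nt, t_start, t_start + t_len - 1L))
    in_frame_stop <- grepl("\\*", aa)
  }
  structure(list(hit = TRUE, score = aln$score, identity_pct = ident,
                 exon_interval = c(aln$a_start, aln$a_end),
                 intron_interval = c(aln$b_start, aln$b_end),
                 acceptor_offset_nt = offset,
                 frame_preserved = frame_preserved,
                 in_frame_stop = in_frame_stop,
                 translatable = frame_preserved && !in_frame_stop),
            class = "exonization_report")
}

#' @export
print.exonization_report <- function(x, ...) {
  if (!x$hit) {
    cat("<exonization_report> no homologous region found (score",
        x$score, ")\n")
    return(invisible(x))
  }
  cat("<exonization_report> hit",
      sprintf("intron %d-%d (%.0f%% identity), acceptor offset %d nt\n",
              x$intron_interval[1], x$intron_interval[2], x$identity_pct,
              x$acceptor_offset_nt))
  cat("  frame preserved:", x$frame_preserved,
      "| in-frame stop:", x$in_frame_stop,
      "| translatable:", x$translatable, "\n")
  invisible(x)
}
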