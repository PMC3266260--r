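#' Transcript coordinate of the last exon-exon junction
#'
#' Position, in spliced-transcript nucleotides, of the boundary between the
#' last two exons: the junction lies after this many transcript
#' nucleotides. NA for single-exon transcripts.
#'
#' @param transcript a \code{transcript_model}.
#' @return integer nt coordinate, or NA.
#' @export
last_junction_tx_coord <- function(transcript) {
  lens <- exon_lengths(transcript)
  if (length(lens) < 2) return(NA_integer_)
  as.integer(sum(lens) - lens[length(lens)])
}

#' Classify a transcript under the 55-nt NMD rule
#'
#' A transcript is a putative nonsense-mediated decay (NMD) target when its
#' premature termination codon lies more than \code{nmd_distance_nt}
#' (default 55) nucleotides upstream of the last exon-exon junction. The
#' distance is measured from the first nucleotide of the stop codon to the
#' junction, in spliced coordinates. An NMD candidate is downgraded to
#' "ambiguous" when a downstream ATG-initiated ORF of at least
#' \code{min_orf_aa} residues exists whose own stop does not satisfy the
#' rule: such transcripts may escape decay by translation from the
#' downstream start. Single-exon transcripts are never NMD targets.
#'
#' @param transcript a \code{transcript_model}.
#' @param orf one row of \code{\link{find_orfs}} output on the spliced
#'   sequence (1-based transcript coordinates; \code{end} is the last
#'   nucleotide of the stop codon). If NULL, the longest ORF is used.
#' @param genome genome sequences, required when \code{orf} is NULL or for
#'   the downstream-ORF rescue scan.
#' @param config a \code{pipeline_config}.
#' @return object of class \code{nmd_verdict}: \code{transcript_id},
#'   \code{status} ("coding", "nmd_target" or "ambiguous"),
#'   \code{ptc_tx_pos} (1-based first nt of the stop codon, NA when no
#'   ORF), \code{distance_to_last_junction} (nt, positive = stop upstream
#'   of the junction), \code{no_orf} flag.
#' @export
classify_nmd <- function(transcript, orf = NULL, genome = NULL,
                         config = NULL) {
  config <- default_config(config)
  seq <- NULL
  if (is.null(orf) || !is.null(genome))
    seq <- spliced_sequence(transcript, genome)
  orfs <- NULL
  if (is.null(orf)) {
    orfs <- find_orfs(seq, config$min_orf_aa)
    if (nrow(orfs) == 0)
      return(structure(list(transcript_id = transcript$transcript_id,
                            status = "ambiguous", ptc_tx_pos = NA_integer_,
                            distance_to_last_junction = NA_integer_,
                            no_orf = TRUE), class = "nmd_verdict"))
    orf <- orfs[1, ]
  }
  junction <- last_junction_tx_coord(transcript)
  stop_start0 <- orf$end - 3L          # 0-based coordinate of the stop codon
  distance <- if (is.na(junction)) NA_integer_ else
    as.integer(junction - stop_start0)
  status <- "coding"
  if (!is.na(distance) && !isTRUE(orf$incomplete) &&
      distance > config$nmd_distance_nt) {
    status <- "nmd_target"
    # downstream-ATG rescue: an ORF starting 3' of this stop whose own stop
    # does not trigger the rule
    if (is.null(orfs)) {
      if (is.null(seq))
        stop("genome required to scan for downstream rescue ORFs")
      orfs <- find_orfs(seq, config$min_orf_aa)
    }
    down <- orfs[orfs$start > stop_start0, , drop = FALSE]
    if (nrow(down) > 0) {
      d2 <- junction - (down$end - 3L)
      # an incomplete downstream ORF has no stop at all, so it cannot
      # trigger the rule either
      if (any(down$incomplete | d2 <= config$nmd_distance_nt))
        status <- "ambiguous"
    }
  }
  structure(list(transcript_id = transcript$transcript_id, status = status,
                 ptc_tx_pos = as.integer(orf$end - 2L),
                 distance_to_last_junction = distance,
                 no_orf = FALSE),
            class = "nmd_verdict")
}

#' @export
print.nmd_verdict <- function(x, ...) {
  cat("<nmd_verdict>", x$transcript_id, ":", x$status)
  if (!is.na(x$distance_to_last_junction))
    cat(" (stop", x$distance_to_last_junction,
        "nt upstream of last junction)")
  cat("\n")
  invisible(x)
}
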