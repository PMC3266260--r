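#' Interaction motifs overlapping an effect region
#'
#' @param effect an \code{as_effect}, or a length-2 residue interval on the
#'   annotated isoform.
#' @param motifs data.frame with columns protein_id, motif_id, start, end
#'   (1-based inclusive residues); typically read with
#'   \code{\link{read_motifs_tsv}}.
#' @param protein_id optional filter on the motif table.
#' @return the subset of \code{motifs} whose interval intersects the
#'   effect interval by at least one residue.
#' @export
motif_overlap <- function(effect, motifs, protein_id = NULL) {
  iv <- if (inherits(effect, "as_effect")) {
    if (length(effect$region_a)) effect$region_a else effect$region_b
  } else effect
  if (!is.null(protein_id))
    motifs <- motifs[motifs$protein_id == protein_id, , drop = FALSE]
  if (!length(iv) || nrow(motifs) == 0)
    return(motifs[0, , drop = FALSE])
  iv <- range(iv)
  motifs[motifs$start <= iv[2] & motifs$end >= iv[1], , drop = FALSE]
}

#' Classify an AS event under the three functionality criteria
#'
#' An AS event is called putatively functional when at least one of three
#' independent criteria holds: (1) its protein effect overlaps a predicted
#' interaction motif; (2) it falls in the C-terminal region of the K-box,
#' the region implicated in higher-order complex formation; (3) the
#' corresponding AS-induced polymorphism is conserved in another species.
#'
#' @param event an \code{as_event} (must have passed the NMD filter).
#' @param effect its \code{as_effect}.
#' @param domains \code{domain_annotation} of the reference isoform.
#' @param motifs motif data.frame (see \code{\link{motif_overlap}}).
#' @param conservation_calls list of \code{aip_conservation} objects whose
#'   query AIPs carry \code{intron_index}; a call supports the event when
#'   it is conserved and its intron index equals the event's
#'   \code{intron_index_a}.
#' @return object of class \code{functional_call}: the three criterion
#'   flags, \code{functional} (their OR) and the overlapping motifs.
#' @export
classify_functional <- function(event, effect, domains, motifs = NULL,
                                conservation_calls = list()) {
  mo <- if (is.null(motifs)) NULL else
    motif_overlap(effect, motifs, protein_id = domains$protein_id)
  c1 <- !is.null(mo) && nrow(mo) > 0
  iv <- if (length(effect$region_a)) range(effect$region_a) else
    if (length(effect$region_b)) range(effect$region_b) else NULL
  c2 <- !is.null(iv) && iv[1] <= domains$kbox_cterm[2] &&
    iv[2] >= domains$kbox_cterm[1]
  c3 <- FALSE
  if (length(conservation_calls) && !is.na(event$intron_index_a)) {
    for (call in conservation_calls) {
      if (isTRUE(call$conserved) &&
          identical(call$query$intron_index, event$intron_index_a)) {
        c3 <- TRUE; break
      }
    }
  }
  structure(list(event = event,
                 criterion_motif_overlap = c1,
                 criterion_kbox_cterm = c2,
                 criterion_conserved = c3,
                 functional = c1 || c2 || c3,
                 overlapping_motifs = mo),
            class = "functional_call")
}

#' @export
print.functional_call <- function(x, ...) {
  cat("<functional_call>", if (x$functional) "FUNCTIONAL" else
    "not functional", "\n")
  cat("  motif overlap:", x$criterion_motif_overlap,
      "| K-box C-term:", x$criterion_kbox_cterm,
      "| conserved AIP:", x$criterion_conserved, "\n")
  invisible(x)
}

#' Interaction-motif architecture of a protein
#'
#' Flags each motif as junction-spanning when an intron position (number
#' of complete codons upstream of the junction) lies strictly inside the
#' motif interval: the junction between residues p and p+1 spans motif
#' [s, e] when s <= p < e, so a motif ending exactly at a junction is not
#' spanning.
#'
#' @param protein_id identifier.
#' @param motifs motif data.frame (filtered to this protein).
#' @param intron_positions integer vector of intron protein positions.
#' @return data.frame of motifs sorted by start with a
#'   \code{junction_spanning} logical column; class
#'   \code{motif_architecture}.
#' @export
motif_architecture <- function(protein_id, motifs, intron_positions) {
  m <- motifs[motifs$protein_id == protein_id, , drop = FALSE]
  m <- m[order(m$start), , drop = FALSE]
  m$junction_spanning <- vapply(seq_len(nrow(m)), function(j)
    any(intron_positions >= m$start[j] & intron_positions < m$end[j]),
    logical(1))
  rownames(m) <- NULL
  class(m) <- c("motif_architecture", "data.frame")
  m
}

#' Tabular report of classified AS events
#'
#' One row per event with its type, domain label, protein-level effect,
#' criterion flags, functional verdict and the species in which the
#' corresponding AIP was found conserved.
#'
#' @param calls list of \code{functional_call}s.
#' @param effects list of matching \code{as_effect}s (same order).
#' @param domain_labels character vector of domain labels (same order).
#' @param conserved_species optional list (same order) of character
#'   vectors of species names with a conserved AIP for the event.
#' @param symbols optional named character vector mapping locus ids to
#'   gene symbols.
#' @return data.frame with deterministic column order.
#' @export
make_report <- function(calls, effects, domain_labels,
                        conserved_species = NULL, symbols = NULL) {
  cols <- c("locus", "symbol", "event_type", "domain_label",
            "aa_difference", "frame_shift", "truncation_aa",
            "isoform_a", "isoform_b", "criterion_motif_overlap",
            "criterion_kbox_cterm", "criterion_conserved", "functional",
            "conserved_species")
  if (length(calls) == 0) {
    out <- as.data.frame(setNames(replicate(length(cols),
                                            character(0),
                                            simplify = FALSE), cols))
    return(out)
  }
  rows <- lapply(seq_along(calls), function(j) {
    ev <- calls[[j]]$event
    sp <- if (!is.null(conserved_species) &&
              length(conserved_species) >= j)
      paste(sort(unique(conserved_species[[j]])), collapse = ",") else ""
    data.frame(locus = ev$locus_id,
               symbol = if (!is.null(symbols) && ev$locus_id %in% names(symbols))
                 symbols[[ev$locus_id]] else ev$locus_id,
               event_type = ev$event_type,
               domain_label = domain_labels[j],
               aa_difference = effects[[j]]$aa_difference,
               frame_shift = effects[[j]]$frame_shift,
               truncation_aa = effects[[j]]$truncation_aa,
               isoform_a = ev$isoform_a, isoform_b = ev$isoform_b,
               criterion_motif_overlap = calls[[j]]$criterion_motif_overlap,
               criterion_kbox_cterm = calls[[j]]$criterion_kbox_cterm,
               criterion_conserved = calls[[j]]$criterion_conserved,
               functional = calls[[j]]$functional,
               conserved_species = sp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[, cols]
}

#' Write an event report to TSV
#' @param report data.frame from \code{\link{make_report}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_report_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
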