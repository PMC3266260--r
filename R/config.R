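#' Pipeline configuration
#'
#' Collects the thresholds and scoring parameters used across the pipeline.
#' Defaults follow the analysis conventions for plant MIKC MADS-box genes:
#' the 55-nt premature-termination-codon (PTC) rule for nonsense-mediated
#' decay (NMD), the 40% identity / 60% coverage homolog filter, the
#' AS-induced-polymorphism (AIP) flank-quality rule (at least 4 identical
#' residue pairs and at most 1 gapped position among the 10 alignment
#' columns flanking an indel), and the 40% similarity rule for calling an
#' AIP conserved between species.
#'
#' @param nmd_distance_nt NMD rule distance: a transcript is a putative NMD
#'   target when its PTC lies more than this many nucleotides upstream of
#'   the last exon-exon junction (default 55).
#' @param homolog_min_identity_pct minimum percent identity for accepting a
#'   homolog hit (default 40).
#' @param homolog_min_coverage_pct minimum percentage of reference residues
#'   covered by a homolog hit (default 60).
#' @param aip_conservation_min_similarity_pct minimum global-alignment
#'   similarity (percent positive-scoring columns) for calling an AIP
#'   conserved (default 40).
#' @param flank_window_cols total number of alignment columns flanking a
#'   polymorphic region inspected by the flank-quality rule (default 10,
#'   i.e. 5 on each side).
#' @param flank_min_identical minimum identical residue pairs within the
#'   flank window (default 4).
#' @param flank_max_gapped maximum gapped columns within the flank window
#'   (default 1).
#' @param min_orf_aa minimum ORF length in residues for six-frame
#'   translation and ORF finding (default 30).
#' @param gapless_window_aa half-width (residues) of the window around an
#'   intron position that must align without gaps to the reference for the
#'   gapless-anchor requirement (default 5).
#' @param aip_junction_slack_cols alignment columns of slack allowed
#'   between an indel and a mapped intron position when testing
#'   coincidence (default 3): co-optimal alignments can slide a gap run
#'   past the junction when the indel's edge residues repeat in the flank.
#' @param domain_transfer_min_identity_pct identity floor below which
#'   domain-boundary transfer is refused (default 30).
#' @param aa_gap_open,aa_gap_ext protein alignment gap penalties
#'   (defaults 10 and 0.5, with BLOSUM62).
#' @param nt_match,nt_mismatch,nt_gap_open,nt_gap_ext nucleotide local
#'   alignment scoring (defaults +5/-4, gap 10/0.5).
#' @param nt_score_floor minimum local nucleotide alignment score for the
#'   exonization scan to report a hit (default 100, i.e. 20 matching
#'   bases -- above the score reachable by chance between an exon and an
#'   unrelated intron at these sequence lengths).
#' @param seed optional integer seed recorded for downstream use.
#' @return an object of class \code{pipeline_config} (a validated list).
#' @export
pipeline_config <- function(nmd_distance_nt = 55,
                            homolog_min_identity_pct = 40,
                            homolog_min_coverage_pct = 60,
                            aip_conservation_min_similarity_pct = 40,
                            flank_window_cols = 10,
                            flank_min_identical = 4,
                            flank_max_gapped = 1,
                            min_orf_aa = 30,
                            gapless_window_aa = 5,
                            aip_junction_slack_cols = 3,
                            domain_transfer_min_identity_pct = 30,
                            aa_gap_open = 10, aa_gap_ext = 0.5,
                            nt_match = 5, nt_mismatch = -4,
                            nt_gap_open = 10, nt_gap_ext = 0.5,
                            nt_score_floor = 100,
                            seed = NULL) {
  cfg <- list(nmd_distance_nt = nmd_distance_nt,
              homolog_min_identity_pct = homolog_min_identity_pct,
              homolog_min_coverage_pct = homolog_min_coverage_pct,
              aip_conservation_min_similarity_pct = aip_conservation_min_similarity_pct,
              flank_window_cols = flank_window_cols,
              flank_min_identical = flank_min_identical,
              flank_max_gapped = flank_max_gapped,
              min_orf_aa = min_orf_aa,
              gapless_window_aa = gapless_window_aa,
              aip_junction_slack_cols = aip_junction_slack_cols,
              domain_transfer_min_identity_pct = domain_transfer_min_identity_pct,
              aa_gap_open = aa_gap_open, aa_gap_ext = aa_gap_ext,
              nt_match = nt_match, nt_mismatch = nt_mismatch,
              nt_gap_open = nt_gap_open, nt_gap_ext = nt_gap_ext,
              nt_score_floor = nt_score_floor,
              seed = seed)
  num <- vapply(cfg[setdiff(names(cfg), "seed")], is.numeric, logical(1))
  if (!all(num)) stop("all configuration parameters must be numeric")
  if (any(unlist(cfg[setdiff(names(cfg), c("seed", "nt_mismatch"))]) < 0))
    stop("thresholds must be non-negative")
  pct <- c("homolog_min_identity_pct", "homolog_min_coverage_pct",
           "aip_conservation_min_similarity_pct",
           "domain_transfer_min_identity_pct")
  if (any(unlist(cfg[pct]) > 100)) stop("percentage thresholds must be in [0, 100]")
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("MIKC AS pipeline configuration\n")
  cat("  NMD PTC distance      : >", x$nmd_distance_nt, "nt upstream of last junction\n")
  cat("  homolog filter        : identity >=", x$homolog_min_identity_pct,
      "%, coverage >=", x$homolog_min_coverage_pct, "%\n")
  cat("  AIP flank rule        : >=", x$flank_min_identical, "identical, <=",
      x$flank_max_gapped, "gapped in", x$flank_window_cols, "columns\n")
  cat("  AIP conservation      : similarity >=",
      x$aip_conservation_min_similarity_pct, "%\n")
  cat("  min ORF length        :", x$min_orf_aa, "aa\n")
  invisible(x)
}

default_config <- function(config = NULL) {
  if (is.null(config)) pipeline_config() else config
}
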