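# Seeded end-to-end benchmark drivers. These run the full pipeline on
# generated loci and report recovery statistics against the generator's
# ground truth; both the test suite and the acceptance script use them.

#' Event-type recovery benchmark
#'
#' Simulates loci carrying one implanted AS event each, cycling through
#' all six event types, target domains and strands, runs
#' \code{\link{detect_events}} on each reference/alternative isoform pair
#' and tallies exact-type recovery. A detection counts as an exact
#' recovery when exactly one event is returned and its type equals the
#' implanted type; any returned event with a specific (non-complex) type
#' different from the implanted one counts as a mislabel.
#'
#' @param n number of simulated isoform pairs.
#' @param seed integer seed; replicate r uses \code{seed + r}.
#' @return list with \code{n}, \code{exact} (count), \code{exact_pct},
#'   \code{mislabels} (count of wrong specific types), \code{table}
#'   (implanted x detected contingency table).
#' @export
benchmark_event_recovery <- function(n = 1000, seed = 1) {
  types <- c("alt_donor", "alt_acceptor", "exon_skip", "intron_retention",
             "mutually_exclusive", "cryptic_exon")
  sizes <- c(9L, 15L, 21L, 30L, 42L)
  implanted <- character(n)
  detected <- character(n)
  exact <- 0L
  mislabels <- 0L
  for (r in seq_len(n)) {
    tp <- types[(r - 1L) %% 6L + 1L]
    doms <- if (tp %in% c("exon_skip", "mutually_exclusive"))
      c("I", "K") else c("I", "K", "C")
    dm <- doms[(r - 1L) %/% 6L %% length(doms) + 1L]
    sz <- sizes[(r - 1L) %/% 2L %% length(sizes) + 1L]
    strand <- if (r %% 2L == 0L) "+" else "-"
    loc <- simulate_locus(sim_config(
      events = list(event_spec(tp, size_nt = sz, target_domain = dm)),
      strand = strand), seed = seed + r)
    ev <- detect_events(loc$transcripts[[1]], loc$transcripts[[2]])
    got <- vapply(ev, `[[`, character(1), "event_type")
    implanted[r] <- tp
    detected[r] <- paste(got, collapse = "+")
    if (length(got) == 1L && got == tp) exact <- exact + 1L
    if (any(got != "complex" & got != tp)) mislabels <- mislabels + 1L
  }
  list(n = n, exact = exact, exact_pct = 100 * exact / n,
       mislabels = mislabels, table = table(implanted, detected))
}

#' AIP recovery benchmark
#'
#' Runs the full cross-species AS-induced-polymorphism pipeline on
#' simulated loci and diverged ortholog contigs: six-frame translation,
#' best-homolog filtering, intron-position mapping, AIP detection and the
#' conservation call. Each replicate carries one insertion-type AS event,
#' one species with the homologous AIP implanted (a true positive at the
#' given divergence) and one species with an indel away from every intron
#' position (a negative control that must never be called).
#'
#' @param n_replicates number of replicates.
#' @param divergences protein divergences cycled across replicates.
#' @param seed integer seed.
#' @param config a \code{pipeline_config}.
#' @return list with \code{n}, \code{recall}, \code{precision},
#'   \code{true_positives}, \code{false_negatives},
#'   \code{false_positives}, \code{negative_control_calls}.
#' @export
benchmark_aip_recovery <- function(n_replicates = 500,
                                   divergences = c(0.05, 0.1), seed = 1,
                                   config = NULL) {
  config <- default_config(config)
  ins_types <- c("alt_donor", "alt_acceptor", "intron_retention",
                 "cryptic_exon")
  tp <- 0L; fn <- 0L; fp <- 0L; neg_calls <- 0L
  for (r in seq_len(n_replicates)) {
    etype <- ins_types[(r - 1L) %% 4L + 1L]
    d <- divergences[(r - 1L) %% length(divergences) + 1L]
    dm <- c("I", "K", "C")[(r - 1L) %% 3L + 1L]
    sz <- c(9L, 15L, 30L)[(r - 1L) %/% 3L %% 3L + 1L]
    loc <- simulate_locus(sim_config(
      events = list(event_spec(etype, size_nt = sz, target_domain = dm))),
      seed = seed + 7L * r)
    if (is.null(loc$proteins[[2]])) { fn <- fn + 1L; next }
    ref_prot <- loc$proteins[[1]]
    ref_introns <- get_introns(loc$transcripts[[1]])
    proteome <- stats::setNames(ref_prot$sequence, ref_prot$protein_id)
    truth_idx <- loc$truth$events[[1]]$intron

    # query AIP between the focal species' own isoforms
    self_map <- map_intron_positions(ref_prot$sequence, ref_prot$sequence,
                                     ref_introns, protein_id = "isoform_a",
                                     config = config)
    q_aips <- detect_aips(ref_prot$sequence, loc$proteins[[2]]$sequence,
                          self_map, config = config)
    q_aip <- NULL
    for (qa in q_aips) if (qa$intron_index == truth_idx) q_aip <- qa
    if (is.null(q_aip)) { fn <- fn + 1L; next }

    orth <- simulate_orthologs(
      loc, list(list(name = "pos", d = d, conserve_aip = TRUE),
                list(name = "neg", d = d, conserve_aip = FALSE,
                     non_intron_indel = TRUE)),
      seed = seed + 7L * r + 3L)

    # a hit must cover >= 60% of the reference residues, so fragments
    # shorter than that bound can be dropped before aligning
    min_len <- ceiling(config$homolog_min_coverage_pct / 100 *
                         nchar(ref_prot$sequence))
    species_aips <- function(contigs) {
      peps <- lapply(contigs, function(ctg) {
        fr <- six_frame_orfs(ctg, config$min_orf_aa)
        fr <- fr[nchar(fr$peptide) >= min_len, , drop = FALSE]
        best <- NULL; best_score <- -Inf
        for (j in seq_len(nrow(fr))) {
          h <- best_homolog(fr$peptide[j], proteome, config)
          if (!is.null(h) && h$score > best_score) {
            best <- fr$peptide[j]; best_score <- h$score
          }
        }
        best
      })
      if (any(vapply(peps, is.null, logical(1)))) return(list())
      m1 <- map_intron_positions(peps[[1]], ref_prot$sequence, ref_introns,
                                 protein_id = "isoform_a", config = config)
      detect_aips(peps[[1]], peps[[2]], m1, config = config)
    }

    pos_aips <- species_aips(orth$pos$contigs)
    called <- FALSE
    for (sa in pos_aips) {
      if (sa$intron_index == truth_idx &&
          call_conservation(q_aip, sa, config)$conserved) called <- TRUE
    }
    if (called) tp <- tp + 1L else fn <- fn + 1L
    # any AIP call at a non-truth intron in the positive species is false
    for (sa in pos_aips)
      if (sa$intron_index != truth_idx) fp <- fp + 1L

    neg <- species_aips(orth$neg$contigs)
    if (length(neg) > 0) { fp <- fp + length(neg); neg_calls <- neg_calls + 1L }
  }
  list(n = n_replicates,
       recall = tp / (tp + fn),
       precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
       true_positives = tp, false_negatives = fn, false_positives = fp,
       negative_control_calls = neg_calls)
}

#' NMD boundary benchmark
#'
#' Classifies constructed transcripts whose PTC sits at controlled
#' distances from the last exon-exon junction.
#'
#' @param distances integer distances (nt).
#' @param seed integer seed.
#' @return data.frame with \code{distance}, \code{status},
#'   \code{expected} ("nmd_target" iff distance > 55).
#' @export
benchmark_nmd_boundary <- function(distances = c(54L, 55L, 56L, 200L),
                                   seed = 1) {
  rows <- lapply(seq_along(distances), function(i) {
    d <- distances[i]
    s <- simulate_nmd_transcript(d, seed = seed + i)
    v <- classify_nmd(s$transcript, orf = s$orf, genome = s$genome)
    data.frame(distance = d, status = v$status,
               expected = if (d > 55) "nmd_target" else "coding",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
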