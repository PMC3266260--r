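# Seeded generator of MIKC-like loci with implanted AS events, NMD
# variants and diverged orthologs. The generator is the ground-truth test
# substrate for the detection modules: every implanted feature is recorded
# in a truth list.

with_seed <- function(seed, f) {
  if (is.null(seed)) return(f())
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  f()
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

.codon_env <- new.env()
codons_for <- function(aa) {
  if (is.null(.codon_env$tab)) .codon_env$tab <- codon_table()
  .codon_env$tab[[aa]]
}

random_protein <- function(n) paste(c("M", sample(AA20, n - 1, TRUE)),
                                    collapse = "")

# uniform choice among synonymous codons
back_translate <- function(aa) {
  chars <- strsplit(aa, "")[[1]]
  paste(vapply(chars, function(a) {
    cs <- codons_for(a)
    cs[sample.int(length(cs), 1)]
  }, character(1)), collapse = "")
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# n stop-free codons; optional constraints on the first codon (must begin
# "GT", a valine) and the last (must end "AG": K, Q or E)
stop_free_codons <- function(n, first_gt = FALSE, last_ag = FALSE) {
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- unlist(lapply(AA20, codons_for), use.names = FALSE)
  pool <- setdiff(all_codons, stops)
  out <- pool[sample.int(length(pool), n, replace = TRUE)]
  if (first_gt && n >= 1)
    out[1] <- paste0("GT", sample(c("A", "C", "G", "T"), 1))
  if (last_ag && n >= 1)
    out[n] <- paste0(sample(c("A", "C", "G"), 1), "AG")
  paste(out, collapse = "")
}

make_intron_seq <- function(len) {
  stopifnot(len >= 10)
  paste0("GT", random_nt(len - 4L), "AG")
}

#' Simulation configuration for MIKC-like loci
#'
#' Domain lengths follow the canonical MIKC layout: a ~60-residue MADS (M)
#' domain encoded, together with the proximal I-domain, by one long first
#' exon; a short intervening (I) domain; a K-box spread over several short
#' exons; and a C-terminal domain. Splice sites are canonical GT..AG and
#' intron phases are 0 (exon boundaries fall on codon boundaries), so
#' frame-preserving events have sizes divisible by 3.
#'
#' @param n_loci number of loci for \code{\link{simulate_loci}}.
#' @param m_len,i_len,k_len,c_len domain lengths (residues).
#' @param intron_len_range intron length range (nt).
#' @param utr5_len,utr3_len UTR lengths (nt).
#' @param strand "+", "-" or NULL (random per locus).
#' @param events list of event specifications (see
#'   \code{\link{event_spec}}) implanted in every locus.
#' @param seed optional integer seed.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_loci = 1, m_len = 60, i_len = 30, k_len = 90,
                       c_len = 60, intron_len_range = c(90, 200),
                       utr5_len = 60, utr3_len = 120, strand = NULL,
                       events = list(), seed = NULL) {
  stopifnot(m_len > 0, i_len > 0, k_len > 0, c_len > 0,
            all(intron_len_range > 0), utr5_len >= 0, utr3_len > 0)
  structure(list(n_loci = n_loci, m_len = m_len, i_len = i_len,
                 k_len = k_len, c_len = c_len,
                 intron_len_range = intron_len_range,
                 utr5_len = utr5_len, utr3_len = utr3_len,
                 strand = strand, events = events, seed = seed),
            class = "sim_config")
}

#' AS event specification for the simulator
#'
#' @param type one of "alt_donor", "alt_acceptor", "exon_skip",
#'   "intron_retention", "mutually_exclusive", "cryptic_exon".
#' @param size_nt inserted-sequence size for alt-site, retention and
#'   cryptic/mutually-exclusive exons (multiple of 3 when
#'   frame-preserving); ignored for exon_skip, which uses the native exon
#'   size.
#' @param frame_preserving logical.
#' @param target_domain "I", "K" or "C" (exon-based events support I and K).
#' @param ptc implant a premature termination codon (intron retention
#'   only): the retained intron carries an early in-frame stop, making the
#'   isoform an NMD target.
#' @return a list of class \code{event_spec}.
#' @export
event_spec <- function(type, size_nt = 30, frame_preserving = TRUE,
                       target_domain = "K", ptc = FALSE) {
  types <- c("alt_donor", "alt_acceptor", "exon_skip", "intron_retention",
             "mutually_exclusive", "cryptic_exon")
  if (!type %in% types) stop("unknown event type: ", type)
  if (frame_preserving && size_nt %% 3 != 0)
    stop("frame-preserving events need size_nt divisible by 3")
  if (!target_domain %in% c("I", "K", "C"))
    stop("target_domain must be I, K or C")
  if (type %in% c("exon_skip", "mutually_exclusive") &&
      target_domain == "C")
    stop("exon-based events support target domains I and K only")
  structure(list(type = type, size_nt = as.integer(size_nt),
                 frame_preserving = frame_preserving,
                 target_domain = target_domain, ptc = ptc),
            class = "event_spec")
}

# exon boundary skeleton: residue indices after which the six introns fall
mikc_boundaries <- function(cfg) {
  m <- cfg$m_len; i <- cfg$i_len; k <- cfg$k_len; c_ <- cfg$c_len
  b1 <- m + sample(seq(max(2, round(i * 0.12)), round(i * 0.35)), 1)
  b2 <- m + sample(seq(round(i * 0.55), round(i * 0.88)), 1)
  b3 <- m + i + sample(seq(round(k * 0.07), round(k * 0.2)), 1)
  b4 <- b3 + sample(seq(round(k * 0.1), round(k * 0.18)), 1)
  b5 <- b4 + sample(seq(round(k * 0.1), round(k * 0.18)), 1)
  b6 <- m + i + k + sample(seq(round(c_ * 0.15), round(c_ * 0.5)), 1)
  b <- c(b1, b2, b3, b4, b5, b6)
  if (any(diff(b) < 3) || b5 >= m + i + k - 2)
    stop("infeasible exon layout for the given domain budget")
  b
}

#' Simulate one MIKC-like locus
#'
#' Generates a random MIKC-type gene: a coding sequence whose protein has
#' the M/I/K/C domain layout, split over seven exons (one long first exon
#' spanning the MADS domain and part of the I-domain, short internal exons
#' through the I-domain and K-box, and C-terminal exons), with canonical
#' GT..AG introns, plus one alternative isoform per entry of
#' \code{config$events}. Deterministic for a fixed seed.
#'
#' @param config a \code{sim_config}.
#' @param seed integer seed (optional; falls back to \code{config$seed}).
#' @param locus_id identifier (also used as the chromosome name).
#' @return object of class \code{mikc_locus}: \code{genome}
#'   (DNAStringSet), \code{transcripts} (reference first), \code{proteins}
#'   (named list of \code{protein_isoform}, NULL for untranslatable
#'   isoforms), \code{domains} (\code{domain_annotation} of the reference
#'   protein), \code{truth} (implanted-feature records).
#' @export
simulate_locus <- function(config = sim_config(), seed = NULL,
                           locus_id = "locusA") {
  if (is.null(seed)) seed <- config$seed
  with_seed(seed, function() simulate_locus_impl(config, locus_id))
}

simulate_locus_impl <- function(cfg, locus_id) {
  L <- cfg$m_len + cfg$i_len + cfg$k_len + cfg$c_len
  prot <- random_protein(L)
  b <- mikc_boundaries(cfg)
  n_ex <- length(b) + 1L
  bounds <- c(0L, b, L)
  codon_chunks <- vapply(seq_len(n_ex), function(j)
    back_translate(substr(prot, bounds[j] + 1L, bounds[j + 1L])),
    character(1))
  introns <- lapply(seq_len(n_ex - 1L), function(j)
    list(seq = make_intron_seq(sample(seq(cfg$intron_len_range[1],
                                          cfg$intron_len_range[2]), 1)),
         e2 = NULL))
  stop_codon <- "TGA"
  utr5 <- random_nt(cfg$utr5_len)
  # keep the 3' UTR free of ATG so NMD rescue scans are unambiguous
  utr3 <- paste(sample(c("C", "G", "T"), cfg$utr3_len, TRUE), collapse = "")
  flank <- 50L

  domains <- domain_annotation(
    paste0(locus_id, ".1"),
    m = c(1L, cfg$m_len),
    i = c(cfg$m_len + 1L, cfg$m_len + cfg$i_len),
    k = c(cfg$m_len + cfg$i_len + 1L, cfg$m_len + cfg$i_len + cfg$k_len),
    c = c(cfg$m_len + cfg$i_len + cfg$k_len + 1L, L))

  # isoform descriptors; the reference is ".1"
  isoforms <- list(list(id = paste0(locus_id, ".1"), mod = NULL))
  truth_events <- list()
  ev_sites <- list()
  for (en in seq_along(cfg$events)) {
    es <- cfg$events[[en]]
    site <- pick_event_site(es, b, cfg)
    imp <- implant_into_parts(es, site, introns, b, cfg)
    introns <- imp$introns
    iso_id <- paste0(locus_id, ".", en + 1L)
    isoforms[[length(isoforms) + 1L]] <- list(id = iso_id, mod = imp$mod)
    if (es$type == "exon_skip")
      imp$truth$indel_peptide <- substr(prot, b[site$exon - 1L] + 1L,
                                        b[site$exon])
    truth_events[[length(truth_events) + 1L]] <-
      c(list(isoform = iso_id, type = es$type,
             target_domain = es$target_domain, ptc = es$ptc), imp$truth)
    ev_sites[[length(ev_sites) + 1L]] <- site
  }

  strand <- if (is.null(cfg$strand)) sample(c("+", "-"), 1) else cfg$strand
  loc <- materialize_locus(locus_id, strand, utr5, codon_chunks, stop_codon,
                           utr3, introns, isoforms, flank, cfg)
  loc$domains <- domains
  loc$truth <- list(protein = prot, boundaries = b, events = truth_events,
                    domains = domains)
  loc$config <- cfg
  class(loc) <- "mikc_locus"
  loc
}

# choose the intron / exon index an event acts on, by target domain
pick_event_site <- function(es, b, cfg) {
  if (es$type %in% c("exon_skip", "mutually_exclusive")) {
    # internal exon fully inside the target domain
    exon <- switch(es$target_domain, I = 2L, K = 4L,
                   stop("no internal exon available in domain ",
                        es$target_domain))
    list(exon = exon)
  } else {
    intron <- switch(es$target_domain, I = 1L, K = 4L, C = 6L)
    list(intron = intron)
  }
}

# rewrite intron sequences as required and describe the alternative
# isoform; returns updated introns, an isoform modification descriptor and
# the per-event truth entry
implant_into_parts <- function(es, site, introns, b, cfg) {
  s <- es$size_nt
  truth <- list()
  if (es$type == "alt_donor") {
    j <- site$intron
    old_len <- nchar(introns[[j]]$seq)
    if (old_len < s + 40) old_len <- s + 40L
    ext <- stop_free_codons(s %/% 3L, first_gt = TRUE)
    introns[[j]]$seq <- paste0(ext, "GT", random_nt(old_len - s - 4L), "AG")
    mod <- list(op = "donor_ext", intron = j, size = s)
    truth <- list(intron = j, aa_difference = s %/% 3L,
                  indel_peptide = translate_cds(ext),
                  junction_position = b[j])
  } else if (es$type == "alt_acceptor") {
    j <- site$intron
    old_len <- nchar(introns[[j]]$seq)
    if (old_len < s + 40) old_len <- s + 40L
    ext <- stop_free_codons(s %/% 3L, last_ag = TRUE)
    introns[[j]]$seq <- paste0("GT", random_nt(old_len - s - 4L), "AG", ext)
    mod <- list(op = "acceptor_ext", intron = j, size = s)
    truth <- list(intron = j, aa_difference = s %/% 3L,
                  indel_peptide = translate_cds(ext),
                  junction_position = b[j])
  } else if (es$type == "intron_retention") {
    j <- site$intron
    old_len <- nchar(introns[[j]]$seq)
    if (es$ptc) {
      # retained intron shifts the frame (length not divisible by 3) and
      # carries an early in-frame stop: codon 1 is GTx, codon 2 TAA
      len <- (old_len %/% 3L) * 3L + 1L
      x <- sample(c("A", "C", "G", "T"), 1)
      introns[[j]]$seq <- paste0("GT", x, "TAA", random_nt(len - 8L), "AG")
      truth <- list(intron = j, nmd = TRUE, junction_position = b[j])
    } else {
      len <- max(30L, (old_len %/% 3L) * 3L)
      n_cod <- len %/% 3L
      introns[[j]]$seq <- stop_free_codons(n_cod, first_gt = TRUE,
                                           last_ag = TRUE)
      truth <- list(intron = j, aa_difference = n_cod,
                    indel_peptide = translate_cds(introns[[j]]$seq),
                    junction_position = b[j])
    }
    mod <- list(op = "retain", intron = j)
  } else if (es$type == "exon_skip") {
    j <- site$exon
    exon_aa <- b[j] - b[j - 1L]
    mod <- list(op = "skip", exon = j)
    truth <- list(exon = j, aa_difference = exon_aa,
                  junction_position = b[j - 1L])
  } else if (es$type %in% c("mutually_exclusive", "cryptic_exon")) {
    # write a novel exon into the intron downstream of the target exon
    # (mutually_exclusive) or into the target intron (cryptic_exon)
    j <- if (es$type == "mutually_exclusive") site$exon else site$intron
    e2 <- stop_free_codons(s %/% 3L)
    f1 <- random_nt(40L)
    f2 <- random_nt(40L)
    introns[[j]]$seq <- paste0("GT", f1, "AG", e2, "GT", f2, "AG")
    introns[[j]]$e2 <- c(4L + nchar(f1), 4L + nchar(f1) + s)  # 0-based rel
    if (es$type == "mutually_exclusive") {
      mod <- list(op = "mx", exon = j)
      truth <- list(exon = j, intron = j,
                    exon1_aa = b[j] - b[j - 1L], exon2_aa = s %/% 3L,
                    junction_position = b[j - 1L])
    } else {
      mod <- list(op = "cryptic", intron = j)
      truth <- list(intron = j, aa_difference = s %/% 3L,
                    indel_peptide = translate_cds(e2),
                    junction_position = b[j])
    }
  } else stop("unsupported event type: ", es$type)
  list(introns = introns, mod = mod, truth = truth)
}

# assemble genome + transcript models (plus-orientation first, reflected
# for minus-strand loci)
materialize_locus <- function(locus_id, strand, utr5, codon_chunks,
                              stop_codon, utr3, introns, isoforms, flank,
                              cfg) {
  n_ex <- length(codon_chunks)
  exon_seqs <- codon_chunks
  exon_seqs[1] <- paste0(utr5, exon_seqs[1])
  exon_seqs[n_ex] <- paste0(exon_seqs[n_ex], stop_codon, utr3)
  segs <- character(0)
  exon_iv <- matrix(0L, n_ex, 2)
  intron_iv <- matrix(0L, n_ex - 1L, 2)
  pos <- flank
  genome_parts <- list(random_nt(flank))
  for (j in seq_len(n_ex)) {
    exon_iv[j, ] <- c(pos, pos + nchar(exon_seqs[j]))
    genome_parts[[length(genome_parts) + 1L]] <- exon_seqs[j]
    pos <- pos + nchar(exon_seqs[j])
    if (j < n_ex) {
      intron_iv[j, ] <- c(pos, pos + nchar(introns[[j]]$seq))
      genome_parts[[length(genome_parts) + 1L]] <- introns[[j]]$seq
      pos <- pos + nchar(introns[[j]]$seq)
    }
  }
  genome_parts[[length(genome_parts) + 1L]] <- random_nt(flank)
  gseq <- paste(unlist(genome_parts), collapse = "")
  glen <- nchar(gseq)

  # exon chains per isoform, in plus orientation
  chains <- lapply(isoforms, function(iso) {
    ch <- exon_iv
    if (!is.null(iso$mod)) {
      m <- iso$mod
      if (m$op == "donor_ext") {
        ch[m$intron, 2] <- ch[m$intron, 2] + m$size
      } else if (m$op == "acceptor_ext") {
        ch[m$intron + 1L, 1] <- ch[m$intron + 1L, 1] - m$size
      } else if (m$op == "retain") {
        ch[m$intron, 2] <- ch[m$intron + 1L, 2]
        ch <- ch[-(m$intron + 1L), , drop = FALSE]
      } else if (m$op == "skip") {
        ch <- ch[-m$exon, , drop = FALSE]
      } else if (m$op == "mx") {
        e2 <- intron_iv[m$exon, 1] + introns[[m$exon]]$e2
        ch[m$exon, ] <- e2
      } else if (m$op == "cryptic") {
        e2 <- intron_iv[m$intron, 1] + introns[[m$intron]]$e2
        ch <- rbind(ch[seq_len(m$intron), , drop = FALSE], e2,
                    ch[seq(m$intron + 1L, n_ex), , drop = FALSE])
      }
    }
    ch
  })

  if (strand == "-") {
    gseq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(gseq)))
    chains <- lapply(chains, function(ch) {
      ch2 <- cbind(glen - ch[, 2], glen - ch[, 1])
      ch2  # keep row order: transcription order (descending coordinates)
    })
  }
  chrom <- locus_id
  genome <- Biostrings::DNAStringSet(stats::setNames(gseq, chrom))

  utr5_len <- nchar(utr5)
  transcripts <- list()
  proteins <- list()
  for (k in seq_along(isoforms)) {
    id <- isoforms[[k]]$id
    ch <- chains[[k]]
    tx0 <- transcript_model(id, locus_id, chrom, strand, ch)
    txseq <- spliced_sequence(tx0, genome)
    orf_start <- utr5_len + 1L
    orf <- scan_orf_from(txseq, orf_start)
    cds <- NULL
    prot <- NULL
    if (!is.null(orf)) {
      cds <- tx_range_to_genomic(ch, strand, orf_start, orf$end)
      prot <- protein_isoform(id, id, orf$aa, orf_start, orf$end)
    }
    transcripts[[id]] <- transcript_model(id, locus_id, chrom, strand, ch,
                                          cds)
    proteins[[id]] <- prot
  }
  list(locus_id = locus_id, chrom = chrom, strand = strand,
       genome = genome, transcripts = transcripts, proteins = proteins,
       utr5_len = utr5_len)
}

# translate from a fixed start to the first in-frame stop; NULL when the
# reading frame never terminates within the transcript
scan_orf_from <- function(txseq, start) {
  n <- nchar(txseq)
  len <- (n - start + 1L) %/% 3L * 3L
  if (len < 3) return(NULL)
  aa <- translate_str(substr(txseq, start, start + len - 1L))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at < 0) return(NULL)
  list(aa = substr(aa, 1, stop_at - 1L),
       end = start + 3L * stop_at - 1L)
}

# map a 1-based spliced-transcript range to genomic sub-intervals
# (transcription order) given the exon chain
tx_range_to_genomic <- function(exons, strand, s, e) {
  lens <- exons[, 2] - exons[, 1]
  offs <- c(0L, cumsum(lens))
  out <- NULL
  for (j in seq_len(nrow(exons))) {
    a <- max(s, offs[j] + 1L); b <- min(e, offs[j] + lens[j])
    if (a > b) next
    if (strand == "+") {
      iv <- c(exons[j, 1] + (a - offs[j] - 1L), exons[j, 1] + (b - offs[j]))
    } else {
      iv <- c(exons[j, 2] - (b - offs[j]), exons[j, 2] - (a - offs[j] - 1L))
    }
    out <- rbind(out, iv)
  }
  out
}

#' @export
print.mikc_locus <- function(x, ...) {
  cat("<mikc_locus>", x$locus_id, "(", x$strand, "strand,",
      length(x$transcripts), "isoform(s) )\n")
  for (ev in x$truth$events)
    cat("  implanted:", ev$type, "->", ev$isoform, "\n")
  invisible(x)
}

#' Simulate several loci
#'
#' @param config a \code{sim_config} (uses \code{n_loci}).
#' @param seed integer seed; locus k uses \code{seed + k - 1}.
#' @return named list of \code{mikc_locus} objects.
#' @export
simulate_loci <- function(config = sim_config(), seed = 1) {
  out <- list()
  for (k in seq_len(config$n_loci)) {
    id <- sprintf("locus%03d", k)
    out[[id]] <- simulate_locus(config, seed = seed + k - 1L, locus_id = id)
  }
  out
}

#' Add an AS isoform to a simulated locus
#'
#' Convenience wrapper: re-simulates the locus with the extra event
#' appended to its configuration (same seed, so the shared structure is
#' unchanged).
#'
#' @param locus a \code{mikc_locus} simulated with a seed.
#' @param spec an \code{event_spec}.
#' @param seed the seed the locus was simulated with.
#' @return a new \code{mikc_locus} with one more isoform and truth entry.
#' @export
implant_event <- function(locus, spec, seed) {
  cfg <- locus$config
  cfg$events <- c(cfg$events, list(spec))
  simulate_locus(cfg, seed = seed, locus_id = locus$locus_id)
}

#' Simulate a transcript with a PTC at an exact distance from the last
#' exon-exon junction
#'
#' Builds a minimal two-exon transcript whose ORF stop codon starts
#' exactly \code{distance_nt} nucleotides upstream of the last junction
#' (negative distances place the stop in the last exon). The 3' UTR
#' contains no ATG, so no downstream-ORF rescue applies.
#'
#' @param distance_nt signed distance (first nt of the stop codon to the
#'   junction); must be >= 3 - orf length.
#' @param n_aa ORF length in residues (default 60).
#' @param seed integer seed.
#' @return list with \code{transcript} (a \code{transcript_model}),
#'   \code{genome}, \code{orf} (a \code{\link{find_orfs}}-style row) and
#'   \code{truth_status} ("coding" or "nmd_target" under the 55-nt rule).
#' @export
simulate_nmd_transcript <- function(distance_nt, n_aa = 60, seed = NULL) {
  with_seed(seed, function() {
    utr5 <- paste(sample(c("C", "G", "T"), 20, TRUE), collapse = "")
    # TAG: its last base cannot seed a spurious ATG with the A-free UTR
    orf <- paste0("ATG", stop_free_codons(n_aa - 1L), "TAG")
    no_atg <- function(n) paste(sample(c("C", "G", "T"), n, TRUE),
                                collapse = "")
    if (distance_nt >= 3) {
      tail1 <- no_atg(distance_nt - 3L)
      exon1 <- paste0(utr5, orf, tail1)
      exon2 <- no_atg(80L)
    } else {
      # stop inside the last exon: junction upstream of the stop
      exon1 <- utr5
      exon2 <- paste0(orf, no_atg(80L))
    }
    intr <- make_intron_seq(90L)
    gseq <- paste0(exon1, intr, exon2)
    e1 <- c(0L, nchar(exon1))
    e2 <- c(nchar(exon1) + nchar(intr), nchar(gseq))
    tx <- transcript_model("ptc_tx", "ptc_locus", "chrP", "+",
                           rbind(e1, e2))
    genome <- Biostrings::DNAStringSet(c(chrP = gseq))
    txseq <- spliced_sequence(tx, genome)
    orfs <- find_orfs(txseq, min_aa = 10)
    # the annotated ORF is the one starting right after the 5' UTR
    main <- orfs[orfs$start == nchar(utr5) + 1L & orfs$frame ==
                   nchar(utr5) %% 3L, , drop = FALSE]
    truth <- if (distance_nt > 55) "nmd_target" else "coding"
    list(transcript = tx, genome = genome, orf = main[1, ],
         truth_status = truth)
  })
}

#' Simulate diverged ortholog transcript contigs for a locus
#'
#' Emulates per-species EST/cDNA contigs of homologs of a simulated
#' locus. Each species' proteins derive from the reference protein by
#' random substitutions to a target divergence \code{d} (uniform across
#' sites, sparing a window around the AIP intron position so intron-flank
#' quality reflects splicing history rather than substitution noise).
#' When \code{conserve_aip} is set and the locus carries an
#' insertion-type AS event, the species also expresses a second isoform
#' carrying the homologous indel at the homologous intron position. A
#' \code{non_intron_indel} species instead carries an indel away from
#' every intron position (a negative control for AIP specificity).
#'
#' @param locus a \code{mikc_locus} whose first truth event (or
#'   \code{event_index}) is an insertion-type event (alt_donor,
#'   alt_acceptor, intron_retention or cryptic_exon).
#' @param species_specs list of lists with fields \code{name}, \code{d}
#'   (protein divergence in [0, 1)), \code{conserve_aip} (logical),
#'   optional \code{non_intron_indel} (logical).
#' @param seed integer seed.
#' @param event_index which truth event carries the AIP (default 1).
#' @return named list per species: \code{contigs} (named character vector
#'   of nucleotide contigs), \code{truth} (aip_present, indel peptide,
#'   intron index, protein divergence).
#' @export
simulate_orthologs <- function(locus, species_specs, seed = NULL,
                               event_index = 1) {
  with_seed(seed, function() {
    ref_prot <- locus$truth$protein
    ev <- locus$truth$events[[event_index]]
    if (is.null(ev$indel_peptide))
      stop("truth event ", event_index, " is not an insertion-type event")
    ins_pos <- ev$junction_position     # residues upstream of the intron
    indel <- ev$indel_peptide
    introns_ref <- get_introns(locus$transcripts[[1]])
    protected <- unlist(lapply(introns_ref$protein_position[
      !is.na(introns_ref$protein_position)], function(p)
        seq(max(1, p - 5), min(nchar(ref_prot), p + 5))))
    out <- list()
    for (sp in species_specs) {
      if (sp$d >= 0.6)
        warning("divergence ", sp$d,
                " exceeds the homolog filter's working range")
      chars <- strsplit(ref_prot, "")[[1]]
      mutable <- setdiff(seq_along(chars), protected)
      k <- round(sp$d * length(chars))
      k <- min(k, length(mutable))
      if (k > 0) {
        idx <- sample(mutable, k)
        chars[idx] <- vapply(chars[idx], function(a)
          sample(setdiff(AA20, a), 1), character(1))
      }
      short_prot <- paste(chars, collapse = "")
      contigs <- character()
      mk_contig <- function(aa) {
        paste0(random_nt(25L), back_translate(aa), "TGA", random_nt(25L))
      }
      contigs[paste0(sp$name, "_c1")] <- mk_contig(short_prot)
      aip_present <- FALSE
      if (isTRUE(sp$conserve_aip)) {
        long_prot <- paste0(substr(short_prot, 1, ins_pos), indel,
                            substr(short_prot, ins_pos + 1L,
                                   nchar(short_prot)))
        contigs[paste0(sp$name, "_c2")] <- mk_contig(long_prot)
        aip_present <- TRUE
      } else if (isTRUE(sp$non_intron_indel)) {
        # indel midway between intron positions: never an AIP
        ip <- sort(introns_ref$protein_position[
          !is.na(introns_ref$protein_position)])
        gaps <- which(diff(ip) >= 20)
        at <- if (length(gaps)) ip[gaps[1]] + 10L else 10L
        decoy <- paste(sample(AA20, 3, TRUE), collapse = "")
        long_prot <- paste0(substr(short_prot, 1, at), decoy,
                            substr(short_prot, at + 1L, nchar(short_prot)))
        contigs[paste0(sp$name, "_c2")] <- mk_contig(long_prot)
      }
      out[[sp$name]] <- list(contigs = contigs,
                             truth = list(aip_present = aip_present,
                                          indel_peptide = indel,
                                          intron_index = ev$intron,
                                          divergence = sp$d))
    }
    out
  })
}

#' Construct cryptic-exon remnant fixtures inside an intron
#'
#' Copies one of the locus's exons into a freshly built intron with a
#' controlled acceptor-site offset and an optional implanted in-frame
#' stop, for exercising \code{\link{exonization_scan}}: offset 0 with no
#' stop yields a translatable construct, offset 2 a frameshift construct,
#' and an implanted TAA an untranslatable construct.
#'
#' @param locus a \code{mikc_locus} with at least two introns.
#' @param ag_offset nt between the nearest upstream AG acceptor and the
#'   exon-homologous region (default 0).
#' @param implant_stop replace an internal codon of the intronic exon copy
#'   with TAA.
#' @param exon which internal exon to copy (default 4, in the K-box).
#' @param seed integer seed.
#' @return list with \code{exon_nt}, \code{intron_nt} and \code{truth}
#'   (ag_offset, has_stop).
#' @export
implant_cryptic_exon_remnant <- function(locus, ag_offset = 0,
                                         implant_stop = FALSE, exon = 4,
                                         seed = NULL) {
  with_seed(seed, function() {
    tx <- locus$transcripts[[1]]
    if (nrow(tx$exons) < 3) stop("locus must have at least two introns")
    ex <- tx$exons[exon, ]
    chr <- locus$genome[[tx$chrom]]
    exon_nt <- as.character(Biostrings::subseq(chr, ex[1] + 1L, ex[2]))
    if (tx$strand == "-")
      exon_nt <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(exon_nt)))
    copy <- exon_nt
    if (implant_stop) {
      at <- 3L * 2L + 1L  # third codon
      copy <- paste0(substr(copy, 1, at - 1L), "TAA",
                     substr(copy, at + 3L, nchar(copy)))
    }
    no_ag <- function(n) {
      x <- strsplit(random_nt(n), "")[[1]]
      if (n >= 2) for (j in seq_len(n - 1))
        if (x[j] == "A" && x[j + 1] == "G") x[j + 1] <- "C"
      paste(x, collapse = "")
    }
    spacer <- no_ag(ag_offset)
    # guard the AG-free property across the spacer/junk boundary
    intron_nt <- paste0("GT", no_ag(40L), "AG", spacer, copy,
                        random_nt(40L), "AG")
    list(exon_nt = exon_nt, intron_nt = intron_nt,
         truth = list(ag_offset = as.integer(ag_offset),
                      has_stop = implant_stop))
  })
}
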