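test_that("six_frame_orfs finds peptides on both strands", {
  set.seed(21)
  pep <- random_aa_str(40)
  cds <- paste0("TAA", madsplice:::back_translate(pep), "TGA")
  fwd <- six_frame_orfs(paste0("CC", cds, "CC"), min_orf_aa = 30)
  expect_true(pep %in% fwd$peptide)
  expect_true(all(fwd$frame[fwd$peptide == pep] > 0))
  rc <- madsplice:::revcomp_str(paste0("CC", cds, "CC"))
  rev <- six_frame_orfs(rc, min_orf_aa = 30)
  expect_true(pep %in% rev$peptide)
  expect_true(all(rev$frame[rev$peptide == pep] < 0))
  # poly-N translates to X only and yields no ORFs
  expect_equal(nrow(six_frame_orfs(strrep("N", 300), min_orf_aa = 30)), 0)
})

test_that("six_frame_orfs agrees with a brute-force frame scan", {
  brute <- function(contig, min_aa) {
    count <- 0L
    for (strand in 1:2) {
      s <- if (strand == 1) contig else madsplice:::revcomp_str(contig)
      for (off in 0:2) {
        len <- (nchar(s) - off) %/% 3 * 3
        if (len < 3) next
        aa <- madsplice:::translate_str(substr(s, off + 1, off + len))
        for (sg in strsplit(aa, "\\*")[[1]])
          if (nchar(sg) >= min_aa && grepl("[^X]", sg)) count <- count + 1L
      }
    }
    count
  }
  set.seed(23)
  for (r in 1:15) {
    contig <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
    expect_equal(nrow(six_frame_orfs(contig, min_orf_aa = 20)),
                 brute(contig, 20))
  }
})

test_that("best_homolog applies the 40% identity / 60% coverage filter", {
  set.seed(31)
  ref <- random_aa_str(150)
  proteome <- c(refA = ref, refB = random_aa_str(150))
  hit <- best_homolog(ref, proteome)
  expect_equal(hit$protein_id, "refA")
  expect_equal(hit$identity_pct, 100)
  expect_equal(hit$coverage_pct, 100)
  # a fragment covering half the reference fails coverage however identical
  expect_null(best_homolog(substr(ref, 1, 75), proteome["refA"]))
})

test_that("best_homolog acceptance flips around 40% identity", {
  set.seed(37)
  ref <- random_aa_str(200)
  mutate_to <- function(identity_target) {
    n_mut <- round((1 - identity_target / 100) * 200)
    chars <- strsplit(ref, "")[[1]]
    idx <- seq(1, 200, length.out = n_mut)
    for (i in round(idx))
      chars[i] <- sample(setdiff(aa_alphabet, chars[i]), 1)
    paste(chars, collapse = "")
  }
  for (pct in c(25, 30)) {
    expect_null(best_homolog(mutate_to(pct), c(refA = ref)),
                info = paste("identity", pct))
  }
  for (pct in c(50, 60)) {
    expect_false(is.null(best_homolog(mutate_to(pct), c(refA = ref))),
                 info = paste("identity", pct))
  }
})

test_that("map_intron_positions transfers positions through alignments", {
  set.seed(41)
  ref <- random_aa_str(120)
  introns <- data.frame(intron_index = 1:3,
                        protein_position = c(30L, 60L, 90L),
                        phase = 0L)
  self <- map_intron_positions(ref, ref, introns)
  expect_true(all(self$positions$mapped))
  expect_equal(self$positions$subject_position, c(30L, 60L, 90L))
  expect_true(all(self$positions$gapless_window))

  ext <- paste0("WWW", ref)   # 3-residue N-terminal extension
  m <- map_intron_positions(ext, ref, introns)
  expect_equal(m$positions$subject_position, c(33L, 63L, 93L))

  # mapped subject positions are strictly increasing
  expect_true(all(diff(m$positions$subject_position[m$positions$mapped]) > 0))

  # deletion spanning an intron position leaves it unmapped
  del <- paste0(substr(ref, 1, 55), substr(ref, 66, 120))
  md <- map_intron_positions(del, ref, introns)
  expect_false(md$positions$mapped[2])
  expect_true(md$positions$mapped[1])
})

test_that("detect_aips finds an indel at a mapped intron position", {
  iso_a <- "MKTLVQQQEIDRSW"
  iso_b <- "MKTLVEIDRSW"
  map <- structure(list(protein_id = "isoform_b", identity_pct = 100,
                        positions = data.frame(intron_index = 1L,
                                               ref_position = 5L,
                                               subject_position = 5L,
                                               phase = 0L, mapped = TRUE,
                                               gapless_window = TRUE)),
                   class = "intron_position_map")
  aips <- detect_aips(iso_a, iso_b, map)
  expect_length(aips, 1)
  expect_equal(aips[[1]]$indel_peptide, "QQQ")
  expect_equal(aips[[1]]$intron_index, 1L)
  expect_true(aips[[1]]$passes_flank_rule)
  expect_gte(aips[[1]]$flank_identical, 4L)

  # identical isoforms carry no AIP
  expect_length(detect_aips(iso_a, iso_a, map), 0)

  # an indel away from every mapped intron position is not an AIP
  far_map <- map
  far_map$positions$subject_position <- 1L
  far_map$positions$ref_position <- 1L
  expect_length(detect_aips(iso_a, iso_b, far_map), 0)
})

test_that("detect_aips rejects candidates with degraded flanks", {
  # flanks around the indel share fewer than 4 identical residue pairs
  iso_a <- "MKTLVQQQEIDRSWAAAAAA"
  iso_b <- "MHSWPEWHPYAAAAAA"     # flanking residues heavily substituted
  map <- structure(list(protein_id = "x", identity_pct = 100,
                        positions = data.frame(intron_index = 1L,
                                               ref_position = 5L,
                                               subject_position = 5L,
                                               phase = 0L, mapped = TRUE,
                                               gapless_window = TRUE)),
                   class = "intron_position_map")
  aips <- detect_aips(iso_a, iso_b, map)
  expect_length(aips, 0)
})

test_that("the gapless anchor requirement is enforced", {
  iso_a <- "MKTLVQQQEIDRSW"
  iso_b <- "MKTLVEIDRSW"
  map <- structure(list(protein_id = "isoform_b", identity_pct = 100,
                        positions = data.frame(intron_index = 1L,
                                               ref_position = 5L,
                                               subject_position = 5L,
                                               phase = 0L, mapped = TRUE,
                                               gapless_window = FALSE)),
                   class = "intron_position_map")
  expect_length(detect_aips(iso_a, iso_b, map), 0)
})

test_that("call_conservation is symmetric, 100% on self and low on noise", {
  set.seed(51)
  a <- structure(list(longer_isoform_seq = random_aa_str(100)),
                 class = "aip")
  self <- call_conservation(a, a)
  expect_equal(self$similarity_pct, 100)
  expect_true(self$conserved)
  b <- structure(list(longer_isoform_seq = random_aa_str(100)),
                 class = "aip")
  expect_equal(call_conservation(a, b)$similarity_pct,
               call_conservation(b, a)$similarity_pct)
  # empirical null: random pairs sit well below the 40% threshold
  sims <- vapply(1:60, function(i) {
    x <- structure(list(longer_isoform_seq = random_aa_str(100)),
                   class = "aip")
    y <- structure(list(longer_isoform_seq = random_aa_str(100)),
                   class = "aip")
    call_conservation(x, y)$similarity_pct
  }, numeric(1))
  expect_lt(mean(sims), 32)
  expect_gt(mean(sims < 40), 0.95)
})

test_that("exonization_scan reproduces the three construct outcomes", {
  loc <- simulate_locus(sim_config(), seed = 61)
  clean <- implant_cryptic_exon_remnant(loc, ag_offset = 0, seed = 62)
  r1 <- exonization_scan(clean$exon_nt, clean$intron_nt)
  expect_true(r1$hit)
  expect_equal(r1$acceptor_offset_nt, 0L)
  expect_true(r1$frame_preserved)
  expect_false(r1$in_frame_stop)
  expect_true(r1$translatable)

  shifted <- implant_cryptic_exon_remnant(loc, ag_offset = 2, seed = 63)
  r2 <- exonization_scan(shifted$exon_nt, shifted$intron_nt)
  expect_equal(r2$acceptor_offset_nt, 2L)
  expect_false(r2$frame_preserved)
  expect_false(r2$translatable)

  stopped <- implant_cryptic_exon_remnant(loc, ag_offset = 0,
                                          implant_stop = TRUE, seed = 64)
  r3 <- exonization_scan(stopped$exon_nt, stopped$intron_nt)
  expect_true(r3$frame_preserved)
  expect_true(r3$in_frame_stop)
  expect_false(r3$translatable)

  # unrelated sequences give no hit
  set.seed(65)
  r4 <- exonization_scan(paste(sample(c("A", "C", "G", "T"), 60, TRUE),
                               collapse = ""),
                         paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                               collapse = ""))
  expect_false(r4$hit)
})
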