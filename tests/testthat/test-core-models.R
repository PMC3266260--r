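test_that("spliced_sequence concatenates exons and handles the minus strand", {
  genome <- c(chr1 = "ATGCCCAAA")
  plus <- transcript_model("t1", "g1", "chr1", "+",
                           rbind(c(0, 3), c(6, 9)))
  expect_equal(spliced_sequence(plus, genome), "ATGAAA")
  minus <- transcript_model("t2", "g1", "chr1", "-",
                            rbind(c(6, 9), c(0, 3)))
  expect_equal(spliced_sequence(minus, genome), "TTTCAT")
  out_of_bounds <- transcript_model("t3", "g1", "chr1", "+",
                                    rbind(c(0, 50)))
  expect_error(spliced_sequence(out_of_bounds, genome), "bounds")
})

test_that("spliced length equals the sum of exon lengths on random transcripts", {
  set.seed(401)
  for (r in 1:40) {
    n_ex <- sample(1:6, 1)
    strand <- sample(c("+", "-"), 1)
    # random non-overlapping exons
    starts <- sort(sample(seq(0, 900, by = 10), n_ex))
    ends <- starts + sample(3:9, n_ex, TRUE)
    m <- cbind(starts, ends)
    if (strand == "-") m <- m[rev(seq_len(n_ex)), , drop = FALSE]
    tx <- transcript_model("t", "g", "c", strand, m)
    genome <- c(c = paste(sample(c("A", "C", "G", "T"), 1000, TRUE),
                          collapse = ""))
    expect_equal(nchar(spliced_sequence(tx, genome)), sum(ends - starts))
  }
})

test_that("transcript_model validates exon ordering and CDS nesting", {
  expect_error(transcript_model("t", "g", "c", "+",
                                rbind(c(0, 100), c(50, 150))), "overlap")
  expect_error(transcript_model("t", "g", "c", "+",
                                rbind(c(200, 300), c(0, 100))),
               "transcription order")
  expect_error(transcript_model("t", "g", "c", "+", rbind(c(0, 100)),
                                cds = rbind(c(50, 150))), "nested")
})

test_that("get_introns reports phases and protein positions", {
  tx <- transcript_model("t", "g", "c", "+", rbind(c(0, 100), c(200, 300)),
                         cds = rbind(c(0, 100), c(200, 300)))
  intr <- get_introns(tx)
  expect_equal(nrow(intr), 1)
  expect_equal(intr$start, 100)
  expect_equal(intr$end, 200)
  expect_equal(intr$phase, 100 %% 3)
  expect_equal(intr$protein_position, 100 %/% 3)

  single <- transcript_model("t", "g", "c", "+", rbind(c(0, 100)))
  expect_equal(nrow(get_introns(single)), 0)

  # intron entirely within the 5' UTR: phase undefined
  utr <- transcript_model("t", "g", "c", "+",
                          rbind(c(0, 50), c(100, 300)),
                          cds = rbind(c(150, 300)))
  expect_true(is.na(get_introns(utr)$phase))
})

test_that("intron phases agree with brute-force nucleotide counting", {
  for (sd in 1:10) {
    loc <- simulate_locus(sim_config(), seed = 500 + sd)
    tx <- loc$transcripts[[1]]
    intr <- get_introns(tx)
    cds <- tx$cds
    for (j in seq_len(nrow(intr))) {
      # brute force: walk CDS intervals in transcription order, counting
      # nucleotides transcribed before the intron
      up <- 0L
      for (r in seq_len(nrow(cds))) {
        if (tx$strand == "+") {
          up <- up + max(0L, min(cds[r, 2], intr$start[j]) - cds[r, 1])
        } else {
          up <- up + max(0L, cds[r, 2] - max(cds[r, 1], intr$end[j]))
        }
      }
      expect_equal(intr$phase[j], up %% 3L)
      expect_equal(intr$protein_position[j], up %/% 3L)
    }
  }
})

test_that("find_orfs matches its specification on hand cases", {
  one <- find_orfs("ATGAAATAG", min_aa = 2)
  expect_equal(nrow(one), 1)
  expect_equal(one$start, 1)
  expect_equal(one$end, 9)
  expect_false(one$incomplete)
  expect_equal(nrow(find_orfs("CCCCCC", min_aa = 1)), 0)
  # two ATGs sharing a stop: both reported, longest first
  two <- find_orfs("ATGATGAAATAG", min_aa = 2)
  expect_equal(two$start, c(1, 4))
  expect_equal(two$n_aa, c(3, 2))
})

test_that("find_orfs agrees with an exhaustive scan oracle", {
  brute <- function(s, min_aa) {
    n <- nchar(s)
    hits <- NULL
    for (st in seq_len(max(0, n - 2))) {
      if (substr(s, st, st + 2) != "ATG") next
      pos <- st
      found <- FALSE
      while (pos + 2 <= n) {
        cod <- substr(s, pos, pos + 2)
        if (pos > st && cod %in% c("TAA", "TAG", "TGA")) {
          hits <- rbind(hits, data.frame(start = st, end = pos + 2,
                                         n_aa = (pos - st) / 3,
                                         incomplete = FALSE))
          found <- TRUE
          break
        }
        pos <- pos + 3
      }
      if (!found)
        hits <- rbind(hits, data.frame(start = st, end = st - 1 + (n - st + 1) %/% 3 * 3,
                                       n_aa = (n - st + 1) %/% 3,
                                       incomplete = TRUE))
    }
    if (is.null(hits)) return(hits)
    hits <- hits[hits$n_aa >= min_aa, , drop = FALSE]
    hits[order(-hits$n_aa, hits$start), , drop = FALSE]
  }
  set.seed(77)
  for (r in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    got <- find_orfs(s, min_aa = 5)
    want <- brute(s, 5)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_aa, want$n_aa)
      expect_equal(got$incomplete, want$incomplete)
    }
  }
})

test_that("translate_cds follows the standard code and error contract", {
  expect_equal(translate_cds("ATGAAATAG"), "MK")
  expect_error(translate_cds("ATGTAGAAA"), "stop")
  expect_equal(translate_cds(""), "")
  expect_error(translate_cds("ATGA"), "divisible")
  # leucine initiator codons are not special-cased
  expect_equal(translate_cds("TTGCTG"), "LL")
  expect_equal(translate_cds("ATGANATAA"), "MX")
})

test_that("translated spliced CDS equals the generator's ground-truth protein", {
  for (sd in 1:5) {
    loc <- simulate_locus(sim_config(), seed = 600 + sd)
    tx <- loc$transcripts[[1]]
    cds_seq <- spliced_sequence(tx, loc$genome, use_cds = TRUE)
    expect_equal(translate_cds(cds_seq), loc$truth$protein)
  }
})

test_that("transfer_domains is the identity on self and shifts with indels", {
  set.seed(88)
  ref <- random_aa_str(240)
  dom <- domain_annotation("ref", m = c(1, 60), i = c(61, 90),
                           k = c(91, 180), c = c(181, 240))
  self <- transfer_domains(ref, ref, dom, query_id = "q")
  expect_equal(self$m, dom$m)
  expect_equal(self$i, dom$i)
  expect_equal(self$k, dom$k)
  expect_equal(self$c, dom$c)
  expect_equal(self$kbox_cterm, dom$kbox_cterm)

  # 5-residue insertion inside the I-domain shifts K and C by +5
  query <- paste0(substr(ref, 1, 75), "WWWWW", substr(ref, 76, 240))
  tr <- transfer_domains(query, ref, dom, query_id = "q")
  expect_equal(tr$m, dom$m)
  expect_equal(tr$k, dom$k + 5L)
  expect_equal(tr$c, dom$c + 5L)

  # unrelated sequence is unannotatable
  un <- transfer_domains(random_aa_str(240), ref, dom, query_id = "q")
  expect_s3_class(un, "unannotatable")
})

test_that("transfer_domains boundary shifts equal implanted indel lengths", {
  set.seed(89)
  ref <- random_aa_str(240)
  dom <- domain_annotation("ref", m = c(1, 60), i = c(61, 90),
                           k = c(91, 180), c = c(181, 240))
  for (ins in c(3L, 7L, 12L)) {
    q <- paste0(substr(ref, 1, 120), strrep("W", ins),
                substr(ref, 121, 240))  # insertion inside K
    tr <- transfer_domains(q, ref, dom, query_id = "q")
    expect_equal(tr$k[2] - dom$k[2], ins)
    expect_equal(tr$c - dom$c, rep(ins, 2))
    expect_equal(tr$i, dom$i)
  }
})
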