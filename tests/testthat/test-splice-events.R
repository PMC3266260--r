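test_that("cluster_introns groups overlapping intervals by single linkage", {
  intr <- data.frame(intron_index = 1:3, start = c(100L, 100L, 300L),
                     end = c(200L, 250L, 400L), phase = 0L,
                     protein_position = 10L,
                     transcript_id = c("a", "b", "a"))
  cl <- cluster_introns(intr)
  sizes <- unname(sort(vapply(cl, function(x) nrow(x$members), integer(1))))
  expect_equal(sizes, c(1L, 2L))
  expect_equal(length(cluster_introns(intr[2, ])), 1)
  expect_equal(length(cluster_introns(intr[0, ])), 0)
  intr$locus_id <- c("l1", "l1", "l2")
  expect_error(cluster_introns(intr), "locus")
})

test_that("cluster_introns equals brute-force transitive closure", {
  set.seed(1234)
  for (r in 1:60) {
    n <- sample(0:20, 1)
    intr <- data.frame(intron_index = seq_len(n),
                       start = sample(seq(0, 500, 10), n, TRUE),
                       phase = rep(0L, n), protein_position = rep(1L, n),
                       transcript_id = sample(letters[1:4], n, TRUE))
    intr$end <- intr$start + sample(c(20, 50, 120), n, TRUE)
    got <- sort_cluster_sets(cluster_keys(cluster_introns(intr)))
    want <- sort_cluster_sets(brute_force_clusters(intr))
    expect_equal(got, want)
  }
})

test_that("cluster_is_as follows the multi-member / retained-singleton rule", {
  tx_plain <- transcript_model("t1", "l", "c", "+",
                               rbind(c(0, 100), c(200, 400)))
  tx_retaining <- transcript_model("t2", "l", "c", "+",
                                   rbind(c(50, 300)))
  multi <- list(members = data.frame(start = c(100L, 100L),
                                     end = c(200L, 250L),
                                     transcript_id = c("t1", "t3")),
                span = c(100L, 250L))
  expect_true(cluster_is_as(multi, list(tx_plain)))

  singleton <- list(members = data.frame(start = 100L, end = 200L,
                                         transcript_id = "t1"),
                    span = c(100L, 200L))
  expect_true(cluster_is_as(singleton, list(tx_plain, tx_retaining)))
  expect_false(cluster_is_as(singleton, list(tx_plain)))
})

test_that("detect_events types a hand-built alternative donor", {
  a <- transcript_model("t1", "l", "c", "+",
                        rbind(c(0, 100), c(200, 300)))
  b <- transcript_model("t2", "l", "c", "+",
                        rbind(c(0, 130), c(200, 300)))
  ev <- detect_events(a, b)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$event_type, "alt_donor")
  expect_length(detect_events(a, a), 0)
  minus <- transcript_model("t3", "l", "c", "-", rbind(c(0, 100)))
  expect_error(detect_events(a, minus), "strand")
})

test_that("detect_events recovers every implanted event type on both strands", {
  sd <- 1000
  for (tp in all_event_types) {
    for (strand in c("+", "-")) {
      doms <- if (tp %in% c("exon_skip", "mutually_exclusive"))
        c("I", "K") else c("I", "K", "C")
      for (dm in doms) {
        sd <- sd + 1
        loc <- simulate_locus(sim_config(
          events = list(event_spec(tp, target_domain = dm)),
          strand = strand), seed = sd)
        ev <- detect_events(loc$transcripts[[1]], loc$transcripts[[2]])
        expect_equal(vapply(ev, `[[`, character(1), "event_type"), tp,
                     info = paste(tp, strand, dm))
      }
    }
  }
})

test_that("event_effect matches implanted indel sizes for clean in-frame events", {
  sd <- 2000
  for (tp in c("alt_donor", "alt_acceptor", "intron_retention",
               "cryptic_exon", "exon_skip")) {
    sd <- sd + 1
    size <- 42L
    loc <- simulate_locus(sim_config(
      events = list(event_spec(tp, size_nt = size, target_domain = "K"))),
      seed = sd)
    ev <- detect_events(loc$transcripts[[1]], loc$transcripts[[2]])[[1]]
    eff <- event_effect(ev, loc$proteins[[1]], loc$proteins[[2]],
                        loc$transcripts[[1]], loc$transcripts[[2]])
    expect_false(eff$frame_shift)
    expect_equal(eff$truncation_aa, 0L)
    expect_equal(eff$aa_difference, loc$truth$events[[1]]$aa_difference,
                 info = tp)
  }
})

test_that("frame-shifting events are flagged", {
  loc <- simulate_locus(sim_config(
    events = list(event_spec("intron_retention", target_domain = "K",
                             ptc = TRUE, frame_preserving = FALSE))),
    seed = 2100)
  ev <- detect_events(loc$transcripts[[1]], loc$transcripts[[2]])[[1]]
  expect_equal(ev$event_type, "intron_retention")
  # retained intron length is not a multiple of 3
  ilen <- ev$end - ev$start
  expect_true(ilen %% 3 != 0)
})

test_that("assign_domain places effect intervals and borders", {
  dom <- domain_annotation("p", m = c(1, 60), i = c(61, 90),
                           k = c(91, 180), c = c(181, 240))
  expect_equal(assign_domain(c(70, 80), dom), "I")
  expect_equal(assign_domain(c(85, 95), dom), "border-I/K")
  expect_equal(assign_domain(c(90, 91), dom), "border-I/K")
  expect_equal(assign_domain(c(100, 150), dom), "K")
  expect_equal(assign_domain(c(241, 250), dom), "outside")
})

test_that("label_cluster_domain uses junction positions", {
  dom <- domain_annotation("p", m = c(1, 60), i = c(61, 90),
                           k = c(91, 180), c = c(181, 240))
  mk <- function(p) list(members = data.frame(protein_position = p),
                         span = c(0L, 1L))
  expect_equal(label_cluster_domain(mk(75L), dom), "I")
  expect_equal(label_cluster_domain(mk(90L), dom), "border-I/K")
  expect_equal(label_cluster_domain(mk(120L), dom), "K")
  expect_equal(label_cluster_domain(mk(NA_integer_), dom), "outside")
})

test_that("domain_as_counts tallies per label and omits empty labels", {
  labels <- c("I", "I", "K", "K", "K", "C")
  flags <- c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  dc <- domain_as_counts(labels, flags)
  expect_equal(sort(dc$domain), c("C", "I", "K"))
  expect_equal(dc$n_clusters_as[dc$domain == "I"], 1L)
  expect_equal(dc$fraction[dc$domain == "K"], 1 / 3)
  all_as <- domain_as_counts(c("I", "K"), c(TRUE, TRUE))
  expect_equal(all_as$fraction, c(1, 1))
  # the total count is invariant under label permutation
  set.seed(3)
  perm <- sample(length(labels))
  expect_equal(sum(domain_as_counts(labels[perm], flags[perm])$n_clusters_total),
               sum(dc$n_clusters_total))
})

test_that("fisher_domain_enrichment handles degenerate and exact cases", {
  # zero margin: no AS clusters anywhere
  counts <- data.frame(domain = c("I", "K"),
                       n_clusters_total = c(5L, 7L),
                       n_clusters_as = c(0L, 0L))
  expect_equal(fisher_domain_enrichment(counts)$p_value, c(1, 1))
  # [[2,0],[0,2]]: full enumeration gives 1/3
  counts2 <- data.frame(domain = c("I", "K"),
                        n_clusters_total = c(2L, 2L),
                        n_clusters_as = c(2L, 0L))
  expect_equal(fisher_domain_enrichment(counts2)$p_value[1], 1 / 3,
               tolerance = 1e-12)
  expect_error(fisher_domain_enrichment(counts[1, ]), "two")
})

test_that("fisher_domain_enrichment matches hypergeometric enumeration", {
  set.seed(55)
  for (r in 1:80) {
    n_dom <- sample(2:4, 1)
    tot <- sample(1:20, n_dom, TRUE)   # N <= 80, typically <= 60
    as_n <- vapply(tot, function(t) sample(0:t, 1), integer(1))
    counts <- data.frame(domain = LETTERS[seq_len(n_dom)],
                         n_clusters_total = tot, n_clusters_as = as_n)
    got <- fisher_domain_enrichment(counts)
    for (j in seq_len(n_dom)) {
      a <- as_n[j]; b <- tot[j] - a
      c_ <- sum(as_n) - a; d <- sum(tot) - tot[j] - c_
      want <- if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0)
        1 else fisher_enum_p(a, b, c_, d)
      expect_equal(got$p_value[j], want, tolerance = 1e-12)
    }
  }
})
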