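test_that("seed matching equals the brute-force all-pairs word oracle", {
  # repeated-word sequence: the oracle enumerates all pairings, including
  # off-diagonal repeats and reverse-complement palindromes
  s <- "ACGTACGTACGT"
  got <- sort_anchors(find_seed_matches(s, s, word_size = 8))
  want <- sort_anchors(oracle_anchors(s, s, 8))
  expect_equal(got, want)
  # random small pairs, several seeds
  for (seed in 1:6) {
    set.seed(seed)
    nuc <- random_dna_str(80)
    org <- paste0(random_dna_str(20), substr(nuc, 31, 60), random_dna_str(20))
    got <- sort_anchors(find_seed_matches(nuc, org, word_size = 10))
    want <- sort_anchors(oracle_anchors(nuc, org, 10))
    expect_equal(got, want)
  }
})

test_that("words containing N never match and word_size contracts hold", {
  nuc <- "ACGNACGTACGTACGT"
  org <- "ACGTACGTACGTACGT"
  got <- find_seed_matches(nuc, org, word_size = 8)
  want <- oracle_anchors(nuc, org, 8)
  expect_equal(nrow(got), nrow(want))
  expect_true(all(got$n_pos >= 4))  # windows spanning the N are excluded
  expect_warning(a <- find_seed_matches("ACGT", "ACGTACGT", word_size = 8),
                 "word_size")
  expect_equal(nrow(a), 0L)
  expect_error(find_seed_matches(nuc, org, word_size = 4), "word_size")
})

test_that("no shared words means no anchors", {
  expect_equal(nrow(find_seed_matches(strrep("A", 30), strrep("C", 30),
                                      word_size = 8)), 0L)
})

# a nuclear genome with one exact implant of org[51, 170) at position 100,
# flanks forced to mismatch so the planted interval is the maximal match
exact_implant_fixture <- function(seed = 42) {
  set.seed(seed)
  org <- random_dna_str(300)
  nuc <- strsplit(random_dna_str(500), "")[[1]]
  frag <- strsplit(substr(org, 51, 170), "")[[1]]
  nuc[101:220] <- frag
  ob <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  if (nuc[100] == substr(org, 50, 50)) nuc[100] <- ob(substr(org, 50, 50))
  if (nuc[221] == substr(org, 171, 171)) nuc[221] <- ob(substr(org, 171, 171))
  list(nuc = paste(nuc, collapse = ""), org = org)
}

test_that("an exact implanted copy yields one hit with exact coordinates", {
  fx <- exact_implant_fixture()
  anchors <- find_seed_matches(fx$nuc, fx$org, word_size = 16)
  hits <- chain_and_align(anchors, c(n = fx$nuc), c(o = fx$org),
                          word_size = 16)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$o_start, 50L)
  expect_equal(hits$o_end, 170L)
  expect_equal(hits$n_start, 100L)
  expect_equal(hits$n_end, 220L)
  expect_equal(hits$identity_pct, 100)
  expect_equal(hits$strand, "+")
})

test_that("anchor runs far apart on the nuclear side stay separate hits", {
  set.seed(7)
  org <- random_dna_str(400)
  nuc <- paste0(random_dna_str(100), substr(org, 1, 100),
                random_dna_str(500),               # 500 bp gap >> max_join_gap
                substr(org, 101, 200), random_dna_str(100))
  anchors <- find_seed_matches(nuc, org, word_size = 16)
  hits <- chain_and_align(anchors, c(n = nuc), c(o = org), word_size = 16)
  expect_equal(nrow(hits), 2L)
})

test_that("a 10% substituted 200 bp implant gives one hit near identity 90", {
  g <- gen_genome_with_implants(organelle_len = 5000, nuclear_len = 20000,
                                n_implants = 1, length_range = c(200, 200),
                                identity_range = c(90, 90), seed = 5)
  hits <- detect_insertions(g$nuclear, g$organelle, word_size = 12)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity_pct, g$truth$planted_identity_pct, tolerance = 0.02)
})

test_that("hit filtering is strict on identity and inclusive on length", {
  h <- data.frame(identity_pct = c(80, 80.1, 95, 95),
                  length = c(100L, 50L, 49L, 50L))
  kept <- filter_hits(h)
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$identity_pct, c(80.1, 95))
  expect_equal(kept$length, c(50L, 50L))
})

test_that("coverage depth and exchange rate follow the interval algebra", {
  empty <- data.frame(o_start = integer(), o_end = integer())
  p0 <- coverage_profile(empty, 100)
  expect_equal(p0$depth, rep(0L, 100))
  expect_equal(p0$exchange_rate_pct, 0)
  h3 <- data.frame(o_start = rep(10L, 3), o_end = rep(60L, 3))
  p3 <- coverage_profile(h3, 100)
  expect_equal(p3$depth[11:60], rep(3L, 50))
  expect_equal(p3$depth[c(1:10, 61:100)], rep(0L, 50))
  expect_equal(p3$exchange_rate_pct, 50)
  h2 <- data.frame(o_start = c(0L, 40L), o_end = c(50L, 100L))
  p2 <- coverage_profile(h2, 100)
  expect_equal(p2$exchange_rate_pct, 100)
  expect_equal(max(p2$depth), 2L)
  expect_equal(which(p2$depth == 2L), 41:50)
  expect_error(coverage_profile(data.frame(o_start = 0L, o_end = 101L), 100),
               "outside organelle length")
})

test_that("size histogram uses the exact bin edges and conserves counts", {
  h <- data.frame(length = c(50L, 99L, 100L, 999L, 1000L))
  got <- size_histogram(h)
  expect_equal(unname(got), c(2L, 1L, 0L, 0L, 0L, 1L, 1L))
  expect_equal(names(got)[1], "50\u201399")
  expect_equal(names(got)[7], "\u22651000")
  expect_equal(unname(size_histogram(data.frame(length = 1000000L))),
               c(0L, 0L, 0L, 0L, 0L, 0L, 1L))
  expect_equal(sum(size_histogram(data.frame(length = integer()))), 0L)
  expect_error(size_histogram(data.frame(length = 49L)), "filter contract")
  # conservation property on random filtered hit sets
  for (seed in 1:5) {
    set.seed(seed)
    lens <- sample(50:5000, 40, replace = TRUE)
    expect_equal(sum(size_histogram(data.frame(length = lens))), 40L)
  }
})

test_that("reverse-complementing the nuclear genome flips strands only", {
  g <- gen_genome_with_implants(organelle_len = 8000, nuclear_len = 60000,
                                n_implants = 8, length_range = c(100, 600),
                                identity_range = c(92, 100), seed = 9)
  fwd <- detect_insertions(g$nuclear, g$organelle, word_size = 14)
  rc <- seq_set("nuc1", rc_str(g$nuclear$seq))
  rev <- detect_insertions(rc, g$organelle, word_size = 14)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(size_histogram(fwd), size_histogram(rev))
  expect_equal(coverage_profile(fwd, g$organelle)$exchange_rate_pct,
               coverage_profile(rev, g$organelle)$exchange_rate_pct)
  key <- function(h) h[order(h$o_start), c("o_start", "o_end", "length")]
  expect_equal(key(as.data.frame(fwd)), key(as.data.frame(rev)),
               ignore_attr = TRUE)
  m <- merge(as.data.frame(fwd), as.data.frame(rev), by = c("o_start", "o_end"))
  expect_true(all(m$strand.x != m$strand.y))
})

test_that("multi-contig nuclear input is searched contig by contig", {
  fx <- exact_implant_fixture(3)
  nuclear <- seq_set(c("c1", "c2"), c(fx$nuc, random_dna_str(300)))
  hits <- detect_insertions(nuclear, c(org1 = fx$org), word_size = 16,
                            min_length = 50)
  expect_equal(unique(hits$nuclear_id), "c1")
  expect_equal(hits$class, "NUPT")
})
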