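test_that("Smith-Waterman worked cases match hand-derived optima", {
  r <- smith_waterman("AAAA", "AAAA")
  expect_equal(r$score, 16L)            # 4 x BLOSUM62 A/A = 4
  expect_equal(r$identity_pct, 100)
  expect_equal(r$aln_len, 4L)
  expect_null(smith_waterman("AAAA", "PPPP"))  # all cells non-positive
  r2 <- smith_waterman("MKV", "MKV")
  expect_equal(c(r2$q_start, r2$q_end), c(0L, 3L))
  expect_equal(c(r2$s_start, r2$s_end), c(0L, 3L))
  expect_equal(r2$identity_pct, 100)
  expect_error(smith_waterman(seq_set("a", "MKV", kind = "protein"),
                              seq_set("b", "ACGT", kind = "nucleotide")),
               "mixed alphabets")
})

test_that("Smith-Waterman equals an exact affine-gap oracle on random pairs", {
  suppressMessages(requireNamespace("Biostrings"))
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B62 <- e$BLOSUM62
  set.seed(11)
  for (i in 1:60) {
    a <- random_protein_str(sample(5:40, 1))
    b <- random_protein_str(sample(5:40, 1))
    ours <- smith_waterman(a, b)
    oracle <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = B62, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    expect_equal(if (is.null(ours)) 0L else ours$score, max(0, oracle))
  }
})

test_that("E-value follows the Karlin-Altschul closed form", {
  expect_equal(blast_evalue(50, 100, 100, lambda = 0.267, K = 0.041),
               0.041 * 100 * 100 * exp(-0.267 * 50))
  expect_equal(blast_evalue(50, 100, 100, lambda = 0.267, K = 0.041),
               6.5e-4, tolerance = 0.02)
  s <- seq(10, 200, by = 10)
  e <- blast_evalue(s, 100, 100)
  expect_true(all(diff(e) < 0))                       # decreasing in score
  expect_equal(blast_evalue(50, 200, 100), 2 * blast_evalue(50, 100, 100))
  expect_error(blast_evalue(50, 0, 100), "m and n")
  expect_error(blast_evalue(50, 100, 100, lambda = -1), "positive")
})

make_proteome <- function(n, len, prefix, seed) {
  set.seed(seed)
  seq_set(sprintf("%s%02d", prefix, seq_len(n)),
          replicate(n, random_protein_str(len)), kind = "protein")
}

test_that("homology search keeps self-hits and honours both thresholds", {
  subjects <- make_proteome(5, 200, "s", 1)
  queries <- subjects[2, , drop = FALSE]
  queries$id <- "q1"
  class(queries) <- c("seq_set", "data.frame")
  tab <- search_homologs(queries, subjects)
  expect_true("s02" %in% tab$subject)
  self <- tab[tab$subject == "s02", ]
  expect_equal(self$identity_pct, 100)
  expect_true(self$evalue < 1e-10)
  # unrelated random proteins of this length never pass E <= 1e-10
  expect_false(any(tab$subject != "s02"))
  expect_error(search_homologs(queries, subjects[0, ]), "empty subject")
  expect_warning(out <- search_homologs(subjects[0, ], subjects),
                 "empty query")
  expect_equal(nrow(out), 0L)
})

test_that("tightening thresholds never adds rows (filter monotonicity)", {
  set.seed(3)
  base <- make_proteome(6, 150, "p", 3)
  # build queries as mutated copies so there are borderline hits
  qseq <- vapply(base$seq, function(s) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(150, 60)
    ch[idx] <- sample(c("A", "R", "N", "D", "C"), 60, TRUE)
    paste(ch, collapse = "")
  }, character(1))
  queries <- seq_set(paste0("q", 1:6), qseq, kind = "protein")
  loose <- search_homologs(queries, base, min_identity_pct = 10,
                           max_evalue = 1e-2)
  tight_id <- search_homologs(queries, base, min_identity_pct = 50,
                              max_evalue = 1e-2)
  tight_ev <- search_homologs(queries, base, min_identity_pct = 10,
                              max_evalue = 1e-20)
  keyify <- function(t) paste(t$query, t$subject)
  expect_true(all(keyify(tight_id) %in% keyify(loose)))
  expect_true(all(keyify(tight_ev) %in% keyify(loose)))
  expect_true(all(tight_id$identity_pct >= 50))
  expect_true(all(tight_ev$evalue <= 1e-20))
})

test_that("nuclear-vs-plastid search is symmetric up to coordinate swap", {
  a <- make_proteome(4, 180, "n", 5)
  b <- a
  b$id <- sub("n", "p", b$id)
  class(b) <- c("seq_set", "data.frame")
  fwd <- search_homologs(a, b, role = "nuclear_vs_plastid")
  rev <- search_homologs(b, a, role = "nuclear_vs_plastid")
  key_f <- paste(fwd$query, sub("p", "n", fwd$subject))
  key_r <- paste(sub("p", "n", rev$query), rev$subject)
  expect_setequal(key_f, key_r)
  m <- merge(fwd, rev, by.x = c("query"), by.y = c("subject"))
  expect_equal(m$score.x, m$score.y)
  expect_equal(m$q_start.x, m$s_start.y)
  expect_equal(m$s_start.x, m$q_start.y)
})

test_that("EST expression qualifier follows the seed-and-threshold contract", {
  set.seed(21)
  gene <- random_dna_str(1500)
  est_hit <- substr(gene, 301, 450)                 # exact 150 bp fragment
  ests <- seq_set(c("e1", "e2"), c(est_hit, random_dna_str(300)))
  expect_true(est_expressed(c(g = gene), ests))
  # antisense fragment also qualifies (EST orientation is arbitrary)
  ests_rc <- seq_set("e1", rc_str(est_hit))
  expect_true(est_expressed(c(g = gene), ests_rc))
  # no shared 28-mer: no seed, not expressed
  other <- seq_set("e3", random_dna_str(400))
  expect_false(est_expressed(c(g = gene), other))
  expect_error(est_expressed(c(g = gene), other[0, ]),
               "expression not assessable")
})
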