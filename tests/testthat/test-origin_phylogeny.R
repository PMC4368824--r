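test_that("Kimura protein correction matches its closed form", {
  expect_equal(kimura_protein_distance(0), 0)
  expect_equal(kimura_protein_distance(0.5), -log(1 - 0.5 - 0.25 / 5))
  expect_equal(kimura_protein_distance(0.5), 0.7985, tolerance = 1e-4)
  expect_equal(kimura_protein_distance(0.9), 5)
  expect_equal(kimura_protein_distance(0.85), 5)
})

test_that("distance matrix is symmetric, zero-diagonal, and caps saturation", {
  set.seed(2)
  base <- random_protein_str(120)
  mut <- function(s, n) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), n)
    for (i in idx) ch[i] <- sample(setdiff(c("A", "R", "N", "D", "C", "Q",
                                             "E", "G", "H", "I"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  fam <- seq_set(c("a", "b", "c"), c(base, mut(base, 5), mut(base, 10)),
                 kind = "protein")
  d <- protein_distance_matrix(fam)
  expect_equal(d, t(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_true(all(d[upper.tri(d)] > 0))
  # identical sequences at distance zero
  fam0 <- seq_set(c("a", "b", "c"), rep(base, 3), kind = "protein")
  expect_true(all(protein_distance_matrix(fam0) == 0))
  expect_error(protein_distance_matrix(fam[1:2, ]), "at least 3")
})

test_that("neighbor joining solves the additive four- and three-taxon cases", {
  d4 <- matrix(4, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                        c("A", "B", "C", "D")))
  d4["A", "B"] <- d4["B", "A"] <- 2
  d4["C", "D"] <- d4["D", "C"] <- 2
  diag(d4) <- 0
  tr <- nj_tree(d4)
  # the split AB|CD must be present
  want <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(ape::dist.topo(ape::unroot(want), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  # 3 taxa: unique star with solved edge lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  bl <- setNames(t3$edge.length[match(1:3, t3$edge[, 2])], t3$tip.label)
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "square and symmetric")
  m <- matrix(runif(9), 3, 3)
  expect_error(nj_tree(m), "symmetric|diagonal")
})

test_that("NJ recovers the generating topology from additive matrices", {
  set.seed(31)
  ok <- 0
  for (i in 1:30) {
    tr <- ape::rtree(6)
    d <- stats::cophenetic(tr)
    rec <- nj_tree(d)
    if (ape::dist.topo(ape::unroot(tr), ape::unroot(rec)) == 0) ok <- ok + 1
  }
  expect_equal(ok, 30L)
})

test_that("negative NJ branch lengths are clamped to zero", {
  # near-degenerate distances are a classical source of negative NJ branches
  set.seed(5)
  for (i in 1:20) {
    n <- 6
    pts <- matrix(runif(n * 2), n)
    d <- as.matrix(dist(pts))
    dimnames(d) <- list(letters[1:n], letters[1:n])
    tr <- nj_tree(d)
    expect_true(all(tr$edge.length >= 0))
  }
})

groups5 <- c(C1 = "cyanobacteria", C2 = "cyanobacteria",
             E1 = "reference_eukaryote", E2 = "reference_eukaryote",
             B1 = "other_bacteria", B2 = "other_bacteria",
             P1 = "query", P2 = "query")

test_that("origin calls follow the sister-clade composition rule", {
  r1 <- classify_origin(read_newick("((Q,(C1,C2)),(E1,B1));"), "Q", groups5)
  expect_equal(r1$call, "cyanobacterial")
  expect_equal(r1$sister_cyano_fraction, 1)
  expect_equal(r1$n_sister_leaves, 2L)
  r2 <- classify_origin(read_newick("((Q,(E1,E2)),(C1,B1));"), "Q", groups5)
  expect_equal(r2$call, "non_cyanobacterial")
  expect_equal(r2$sister_cyano_fraction, 0)
  r3 <- classify_origin(read_newick("((Q,(C1,E1)),(B1,B2));"), "Q", groups5)
  expect_equal(r3$call, "ambiguous")
  expect_equal(r3$sister_cyano_fraction, 0.5)
})

test_that("origin call contracts: missing query, paralogs, group coverage", {
  expect_error(classify_origin(read_newick("((A,(C1,C2)),(E1,B1));"), "Q",
                               groups5), "absent")
  expect_error(classify_origin(read_newick("((Q,(C1,C2)),(E1,ZZ));"), "Q",
                               groups5), "no taxon_group")
  # query-species paralogs are excluded from sister composition
  r <- classify_origin(read_newick("((Q,(P1,(C1,C2))),(E1,B1));"), "Q", groups5)
  expect_equal(r$call, "cyanobacterial")
  expect_equal(r$n_sister_leaves, 2L)
  # all other leaves paralogs: ambiguous with warning
  expect_warning(
    ra <- classify_origin(read_newick("(Q,P1,P2);"),
                          "Q", groups5),
    "paralog")
  expect_equal(ra$call, "ambiguous")
})

test_that("origin calls are invariant under re-rooting", {
  fam <- gen_families(n_families = 4,
                      donors = c("cyanobacterial", "eukaryotic",
                                 "bacterial_other", "mixed"),
                      seed = 13)
  for (i in seq_along(fam$families)) {
    f <- fam$families[[i]]
    base <- classify_origin(f$tree, f$query, fam$groups)$call
    for (node in sample(setdiff(f$tree$tip.label, f$query), 3)) {
      rerooted <- ape::root(f$tree, outgroup = node, resolve.root = TRUE)
      expect_equal(classify_origin(rerooted, f$query, fam$groups)$call, base)
    }
  }
})

test_that("classification matches the planted donor on synthetic families", {
  fam <- gen_families(n_families = 8,
                      donors = c("cyanobacterial", "eukaryotic",
                                 "bacterial_other", "mixed"),
                      seed = 17)
  for (i in seq_along(fam$families)) {
    f <- fam$families[[i]]
    tr <- nj_tree(protein_distance_matrix(f$seqs))
    got <- classify_origin(tr, f$query, fam$groups)$call
    expect_equal(got, fam$truth$expected_call[i],
                 label = sprintf("family %d (%s)", i, fam$truth$donor[i]))
  }
})

test_that("census algebra reproduces the worked example and its invariants", {
  calls <- data.frame(gene_id = c("n1", "n2"),
                      call = c("cyanobacterial", "cyanobacterial"))
  homol <- data.frame(query = c("n1", "n3"), subject = c("p1", "p2"))
  cs <- build_census(calls, homol, c("p1", "p2", "p3"))
  expect_equal(cs$n_cyano_recruits, 2L)
  expect_equal(cs$n_nuclear_with_plastid_homolog, 2L)
  expect_equal(cs$n_both, 1L)
  expect_equal(cs$n_plastid_proteins, 3L)
  expect_equal(cs$n_plastid_with_nuclear_homolog, 2L)
  expect_equal(cs$n_plastid_with_cyano_nuclear_homolog, 1L)
  # no recruits
  cs0 <- build_census(data.frame(gene_id = character(), call = character()),
                      homol, c("p1"))
  expect_equal(cs0$n_cyano_recruits, 0L)
  expect_equal(cs0$n_both, 0L)
  # expression fraction
  cs_e <- build_census(calls, homol, c("p1"),
                       expression = c(n1 = TRUE, n2 = FALSE))
  expect_equal(cs_e$pct_recruits_expressed, 50)
})

test_that("census inequalities hold on random relation triples", {
  set.seed(101)
  genes <- sprintf("n%02d", 1:20)
  prots <- sprintf("p%02d", 1:10)
  for (i in 1:200) {
    calls <- data.frame(
      gene_id = genes,
      call = sample(c("cyanobacterial", "non_cyanobacterial", "ambiguous"),
                    20, TRUE))
    k <- sample(0:15, 1)
    homol <- data.frame(query = sample(genes, k, TRUE),
                        subject = sample(prots, max(k, 1), TRUE)[seq_len(k)])
    cs <- build_census(calls, homol, prots)
    expect_lte(cs$n_both, min(cs$n_cyano_recruits,
                              cs$n_nuclear_with_plastid_homolog))
    expect_lte(cs$n_plastid_with_cyano_nuclear_homolog,
               cs$n_plastid_with_nuclear_homolog)
    expect_lte(cs$n_plastid_with_nuclear_homolog, cs$n_plastid_proteins)
  }
})
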