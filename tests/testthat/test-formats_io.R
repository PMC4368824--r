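test_that("FASTA round-trip preserves ids, sequences and descriptions", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1 first gene", "ACGT", ">g2", "acgtn"), f)
  s <- read_fasta(f, "nucleotide")
  expect_equal(s$id, c("g1", "g2"))
  expect_equal(s$seq, c("ACGT", "ACGTN"))  # case normalised
  expect_equal(s$desc, c("first gene", NA))
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(s, f2)
  s2 <- read_fasta(f2, "nucleotide")
  expect_equal(s2$id, s$id)
  expect_equal(s2$seq, s$seq)
})

test_that("FASTA reader enforces its contracts", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1", "AC", ">g1", "GT"), f)
  expect_error(read_fasta(f, "nucleotide"), "duplicate id g1")
  writeLines(c(">g1", "ACZT"), f)
  expect_error(read_fasta(f, "nucleotide"), "illegal character 'Z' at position 3")
  file.create(f2 <- withr::local_tempfile(fileext = ".fasta"))
  expect_error(read_fasta(f2, "nucleotide"), "empty")
  # protein alphabet accepts X but not B
  writeLines(c(">p1", "MKVX"), f)
  expect_equal(read_fasta(f, "protein")$seq, "MKVX")
  writeLines(c(">p1", "MKB"), f)
  expect_error(read_fasta(f, "protein"), "illegal character")
})

test_that("FASTA metadata ids must be a subset and attach per record", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1", "ACGT", ">g2", "ACGT"), f)
  meta <- data.frame(id = "g1", taxon_group = "cyanobacteria",
                     species = "Synechocystis")
  s <- read_fasta(f, "nucleotide", metadata = meta)
  expect_equal(s$taxon_group, c("cyanobacteria", NA))
  expect_error(read_fasta(f, "nucleotide",
                          metadata = data.frame(id = "g3", species = "x")),
               "absent from FASTA")
})

test_that("newick parse/serialise round-trips topology, labels and lengths", {
  t1 <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(sort(t1$tip.label), c("A", "B", "C"))
  expect_equal(length(t1$tip.label) + t1$Nnode, 5L)
  rt <- read_newick(write_newick(t1))
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(rt)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(rt$edge.length), sort(t1$edge.length))
  # multifurcation, no branch lengths
  t2 <- read_newick("(A,B,C);")
  expect_equal(t2$Nnode, 1L)
  expect_null(t2$edge.length)
})

test_that("newick parser rejects malformed input", {
  expect_error(read_newick("((A,B);"), "unbalanced")
  expect_error(read_newick("(A,B))C;"), "unbalanced ')' at character 6")
  expect_error(read_newick("(A,B)"), "must end with ';'")
  expect_error(read_newick("((A,B),(A,C));"), "duplicate leaf label A")
})

obo_fixture <- function(lines) {
  f <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  writeLines(c("format-version: 1.2", "", lines), f)
  f
}

gaf_fixture <- function(rows) {
  f <- withr::local_tempfile(fileext = ".gaf", .local_envir = parent.frame())
  writeLines(c("!gaf-version: 2.1", rows), f)
  f
}

gafrow <- function(gene, term, qualifier = "", evidence = "IEA")
  paste("DB", gene, gene, qualifier, term, "REF:1", evidence, "", "P",
        "", "", "gene", "taxon:1", "20150101", "DB", "", "", sep = "\t")

test_that("OBO/GAF reading applies the stated dropping rules", {
  obo <- obo_fixture(c(
    "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: T1", "namespace: biological_process",
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000009", "name: old", "namespace: biological_process",
    "is_obsolete: true", ""))
  expect_message(graph <- read_obo(obo), "1 obsolete")
  expect_setequal(graph$terms, c("GO:0000001", "GO:0000002"))
  expect_equal(graph$parents[["GO:0000002"]], "GO:0000001")
  gaf <- gaf_fixture(c(gafrow("g1", "GO:0000002"),
                       gafrow("g2", "GO:0000002", qualifier = "NOT"),
                       gafrow("g3", "GO:9999999")))
  expect_warning(ann <- read_gaf(gaf, graph), "absent from ontology")
  expect_equal(names(ann), "g1")          # NOT row and unknown term dropped
  expect_equal(ann$g1, "GO:0000002")
  # evidence filter is opt-in
  gaf2 <- gaf_fixture(c(gafrow("g1", "GO:0000002", evidence = "IEA"),
                        gafrow("g2", "GO:0000002", evidence = "EXP")))
  expect_setequal(names(read_gaf(gaf2, graph)), c("g1", "g2"))
  expect_equal(names(read_gaf(gaf2, graph, exclude_evidence = "IEA")), "g2")
})

test_that("cyclic ontologies are rejected; random DAGs always parse acyclic", {
  cyc <- obo_fixture(c(
    "[Term]", "id: GO:0000001", "namespace: biological_process",
    "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000002", "namespace: biological_process",
    "is_a: GO:0000001", ""))
  expect_error(read_obo(cyc), "cyclic")
  # property: serialise random DAGs to OBO, re-read, check edges survive
  for (seed in 1:5) {
    set.seed(seed)
    n <- 12L
    ids <- sprintf("GO:%07d", 1:n)
    parents <- lapply(seq_len(n), function(i)
      if (i == 1) character() else
        ids[sample.int(i - 1, min(i - 1, sample(2, 1)))])
    lines <- unlist(lapply(seq_len(n), function(i)
      c("[Term]", paste0("id: ", ids[i]), "namespace: biological_process",
        paste0("is_a: ", parents[[i]]), "")))
    f <- obo_fixture(lines)
    g <- read_obo(f)
    expect_setequal(g$terms, ids)
    for (i in seq_len(n))
      expect_setequal(g$parents[[ids[i]]], parents[[i]])
  }
})

test_that("slim flagging keeps only known ids and warns on unknown", {
  obo <- obo_fixture(c(
    "[Term]", "id: GO:0000001", "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "namespace: biological_process",
    "is_a: GO:0000001", ""))
  expect_warning(g <- read_obo(obo, slim_ids = c("GO:0000002", "GO:1111111")),
                 "absent from ontology")
  expect_equal(g$slim, "GO:0000002")
})
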