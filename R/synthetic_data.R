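# Ground-truth generators emulating every input the census consumes: nuclear
# genomes with implanted organelle fragments, protein families evolved on
# known trees, GO universes with planted enrichment, and EST libraries
# covering a known gene subset. All generators are deterministic under a
# fixed seed and return machine-readable truth tables.

DNA <- c("A", "C", "G", "T")
AA20 <- setdiff(AA_ALPHABET, "X")

random_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

other_base <- function(b) {
  pool <- setdiff(DNA, b)
  pool[sample.int(3L, 1L)]
}

#' Synthetic nuclear genome with implanted organelle fragments
#'
#' Generates an i.i.d.-uniform organelle genome and nuclear genome, then
#' copies random organelle intervals into non-overlapping nuclear locations
#' (optionally reverse-complemented, optionally in several copies), applying
#' uniform substitutions to hit each planted identity. Substitutions never
#' create indels, so the planted identity is exactly computable. The bases
#' flanking every implant are forced to mismatch the organelle continuation,
#' making the planted interval coincide with the maximal-alignment interval
#' so boundary accuracy is well defined.
#'
#' @param organelle_len,nuclear_len genome lengths in bp.
#' @param n_implants number of distinct implanted source intervals.
#' @param length_range two-element range of implant lengths (bp).
#' @param identity_range two-element range of planted identities (percent).
#' @param max_copies each implant is inserted in 1..max_copies nuclear
#'   locations (uniformly drawn).
#' @param min_separation minimum distance between implanted copies on the
#'   nuclear genome, so separate copies can never chain into one hit.
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `nuclear` and `organelle` ([seq_set()]s, ids `nuc1` /
#'   `org1`) and `truth`: one row per implanted copy with `nuclear_id`,
#'   `n_start`, `n_end`, `o_start`, `o_end`, `strand`,
#'   `planted_identity_pct`, `implant_index`, `copy_index`.
#' @export
gen_genome_with_implants <- function(organelle_len = 150000L,
                                     nuclear_len = 1000000L,
                                     n_implants = 100L,
                                     length_range = c(50L, 3000L),
                                     identity_range = c(60, 100),
                                     max_copies = 1L,
                                     min_separation = 200L,
                                     seed = 1L) {
  if (nuclear_len < n_implants * max(length_range))
    stop("infeasible packing: nuclear genome shorter than n_implants * max length")
  set.seed(seed)
  org <- sample(DNA, organelle_len, replace = TRUE)
  nuc <- sample(DNA, nuclear_len, replace = TRUE)
  truth <- list()
  occupied <- matrix(numeric(0), ncol = 2L) # [start, end) with separation pad
  place <- function(len) {
    for (try in seq_len(5000L)) {
      s <- sample.int(nuclear_len - len + 1L, 1L) - 1L
      e <- s + len
      if (!nrow(occupied) ||
          all(e + min_separation <= occupied[, 1L] |
              s >= occupied[, 2L] + min_separation)) {
        occupied <<- rbind(occupied, c(s, e))
        return(s)
      }
    }
    stop("infeasible packing: could not place implant without overlap")
  }
  if (n_implants > 0L) for (i in seq_len(n_implants)) {
    len <- length_range[1L] + sample.int(length_range[2L] - length_range[1L] + 1L, 1L) - 1L
    o_start <- sample.int(organelle_len - len + 1L, 1L) - 1L
    identity <- runif(1L, identity_range[1L], identity_range[2L])
    n_copies <- if (max_copies > 1L) sample.int(max_copies, 1L) else 1L
    n_sub <- round((1 - identity / 100) * len)
    planted_identity <- 100 * (1 - n_sub / len)
    for (cp in seq_len(n_copies)) {
      frag <- org[(o_start + 1L):(o_start + len)]
      if (n_sub > 0L) {
        pos <- sample.int(len, n_sub)
        for (p in pos) frag[p] <- other_base(frag[p])
      }
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-")
        frag <- rev(chartr("ACGT", "TGCA", frag))
      n_start <- place(len)
      nuc[(n_start + 1L):(n_start + len)] <- frag
      truth[[length(truth) + 1L]] <- data.frame(
        nuclear_id = "nuc1", n_start = n_start, n_end = n_start + len,
        o_start = o_start, o_end = o_start + len, strand = strand,
        planted_identity_pct = planted_identity,
        implant_index = i, copy_index = cp, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(nuclear_id = character(), n_start = integer(),
               n_end = integer(), o_start = integer(), o_end = integer(),
               strand = character(), planted_identity_pct = numeric(),
               implant_index = integer(), copy_index = integer())
  # Force a 12 bp mismatch barrier on both flanks of every copy, against the
  # organelle continuation in the copy's orientation: a maximal-scoring
  # extension then stops at the planted boundary, so the truth intervals are
  # exactly the maximal-alignment intervals.
  barrier <- 12L
  comp1 <- function(b) chartr("ACGT", "TGCA", b)
  if (nrow(truth)) for (r in seq_len(nrow(truth))) {
    ns <- truth$n_start[r]; ne <- truth$n_end[r]
    os <- truth$o_start[r]; oe <- truth$o_end[r]
    plus <- truth$strand[r] == "+"
    for (t in 0:(barrier - 1L)) {
      # left flank of the nuclear copy
      ni <- ns - t
      oi <- if (plus) os - t else oe + 1L + t
      if (ni >= 1L && oi >= 1L && oi <= organelle_len) {
        cont <- if (plus) org[oi] else comp1(org[oi])
        if (nuc[ni] == cont) nuc[ni] <- other_base(cont)
      }
      # right flank
      ni <- ne + 1L + t
      oi <- if (plus) oe + 1L + t else os - t
      if (ni <= nuclear_len && oi >= 1L && oi <= organelle_len) {
        cont <- if (plus) org[oi] else comp1(org[oi])
        if (nuc[ni] == cont) nuc[ni] <- other_base(cont)
      }
    }
  }
  list(nuclear = seq_set("nuc1", paste(nuc, collapse = ""),
                         compartment = "nuclear"),
       organelle = seq_set("org1", paste(org, collapse = ""),
                           compartment = "plastid"),
       truth = truth)
}

#' Exchange rate implied by an implant truth table
#'
#' Percentage of organelle positions covered by the union of the planted
#' source intervals, to 0.01 percent.
#'
#' @param truth truth table from [gen_genome_with_implants()].
#' @param organelle_len organelle genome length.
#' @export
truth_exchange_rate <- function(truth, organelle_len) {
  covered <- logical(organelle_len)
  for (r in seq_len(nrow(truth)))
    covered[(truth$o_start[r] + 1L):truth$o_end[r]] <- TRUE
  round(100 * mean(covered), 2L)
}

#' Per-position copy number implied by an implant truth table
#'
#' @inheritParams truth_exchange_rate
#' @return integer vector of planted per-position copy counts.
#' @export
truth_copy_number <- function(truth, organelle_len) {
  depth <- integer(organelle_len)
  for (r in seq_len(nrow(truth))) {
    idx <- (truth$o_start[r] + 1L):truth$o_end[r]
    depth[idx] <- depth[idx] + 1L
  }
  depth
}

# ---- protein families -----------------------------------------------------

evolve_protein <- function(tree, seq_len, root_seq = NULL) {
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  seqs[[root]] <- root_seq %||% sample(AA20, seq_len, replace = TRUE)
  # cladewise order: parents always precede children in the edge matrix
  tr <- stats::reorder(tree, "cladewise")
  ord <- tr$edge
  bl <- tr$edge.length
  for (e in seq_len(nrow(ord))) {
    parent <- ord[e, 1L]; child <- ord[e, 2L]
    s <- seqs[[parent]]
    n_sub <- min(rpois(1L, bl[e] * seq_len), seq_len)
    if (n_sub > 0L) {
      pos <- sample.int(seq_len, n_sub)
      for (p in pos) s[p] <- sample(setdiff(AA20, s[p]), 1L)
    }
    seqs[[child]] <- s
  }
  stats::setNames(lapply(seq_len(ntip), function(i)
    paste(seqs[[i]], collapse = "")), tree$tip.label)
}

#' Synthetic protein families with known donor lineage
#'
#' Each family evolves a random ancestral protein along a fixed-topology
#' tree (uniform amino-acid replacement, Poisson numbers of substitutions
#' per branch) in which cyanobacteria, other bacteria and reference
#' eukaryotes form clean clades. The query gene is attached as sister to a
#' leaf of the donor clade — or, for planted mixed-sister families, as
#' sister to a (cyanobacterium, eukaryote) cherry, which a correct
#' classifier must flag ambiguous.
#'
#' @param n_families number of families.
#' @param taxa_per_group leaves per taxon group.
#' @param seq_len ancestral protein length (aa).
#' @param subst_rate expected substitutions per site per branch (all
#'   branches share this length).
#' @param donors character vector recycled over families; values
#'   `"cyanobacterial"`, `"eukaryotic"`, `"bacterial_other"`, `"mixed"`.
#' @param seed integer seed.
#' @return list with `families` (per family: `seqs` [seq_set()], `tree`
#'   true `phylo`, `query` leaf id), `groups` (named vector leaf ->
#'   taxon_group over all families) and `truth` (`family_id`, `donor`,
#'   `query_gene_id`, `mixed_sister`, `expected_call`, `newick`).
#' @export
gen_families <- function(n_families = 9L, taxa_per_group = 3L, seq_len = 300L,
                         subst_rate = 0.03,
                         donors = c("cyanobacterial", "eukaryotic",
                                    "bacterial_other"),
                         seed = 1L) {
  set.seed(seed)
  r <- format(subst_rate, scientific = FALSE)
  leaf <- function(lab) paste0(lab, ":", r)
  comb <- function(a, b) paste0("(", a, ",", b, "):", r)
  nest <- function(tokens) Reduce(comb, tokens)
  families <- list(); truth <- list(); groups <- character()
  for (f in seq_len(n_families)) {
    donor <- donors[((f - 1L) %% length(donors)) + 1L]
    cy <- sprintf("F%02d_cyano_%d", f, seq_len(taxa_per_group))
    ba <- sprintf("F%02d_bact_%d", f, seq_len(taxa_per_group))
    eu <- sprintf("F%02d_euk_%d", f, seq_len(taxa_per_group))
    q <- sprintf("F%02d_query", f)
    cy_tok <- lapply(cy, leaf); ba_tok <- lapply(ba, leaf); eu_tok <- lapply(eu, leaf)
    if (donor == "cyanobacterial") {
      cy_tok[[1L]] <- comb(leaf(cy[1L]), leaf(q))
    } else if (donor == "bacterial_other") {
      ba_tok[[1L]] <- comb(leaf(ba[1L]), leaf(q))
    } else if (donor == "eukaryotic") {
      eu_tok[[1L]] <- comb(leaf(eu[1L]), leaf(q))
    } else if (donor == "mixed") {
      # query sister to a (cyano, eukaryote) cherry
      cherry <- comb(comb(leaf(cy[1L]), leaf(eu[1L])), leaf(q))
      cy_tok <- c(list(cherry), lapply(cy[-1L], leaf))
      eu_tok <- lapply(eu[-1L], leaf)
    } else stop(sprintf("unknown donor '%s'", donor))
    newick <- paste0("(", comb(nest(cy_tok), nest(ba_tok)), ",",
                     nest(eu_tok), ");")
    tree <- read_newick(newick)
    seqs <- evolve_protein(tree, seq_len)
    tg <- ifelse(grepl("_cyano_", names(seqs)), "cyanobacteria",
          ifelse(grepl("_bact_", names(seqs)), "other_bacteria",
          ifelse(grepl("_euk_", names(seqs)), "reference_eukaryote", "query")))
    fam_seqs <- seq_set(names(seqs), unlist(seqs), kind = "protein",
                        taxon_group = tg)
    groups <- c(groups, stats::setNames(tg, names(seqs)))
    families[[f]] <- list(seqs = fam_seqs, tree = tree, query = q)
    expected <- switch(donor,
                       cyanobacterial = "cyanobacterial",
                       eukaryotic = "non_cyanobacterial",
                       bacterial_other = "non_cyanobacterial",
                       mixed = "ambiguous")
    truth[[f]] <- data.frame(family_id = sprintf("F%02d", f), donor = donor,
                             query_gene_id = q,
                             mixed_sister = donor == "mixed",
                             expected_call = expected,
                             newick = newick, stringsAsFactors = FALSE)
  }
  list(families = families, groups = groups, truth = do.call(rbind, truth))
}

# ---- GO universes ---------------------------------------------------------

#' Synthetic GO universe with planted term enrichment
#'
#' Builds a small random DAG ontology (one BP root, a slim layer below it,
#' leaf terms below the slim layer), uniform background annotations, and a
#' study set in which the genes of each planted term are over-represented:
#' a planted gene enters the study independently with probability
#' `fold * study_frac` (so the expected study count of a planted term with
#' `K` genes is `fold * study_frac * K`), and the remaining study slots are
#' drawn uniformly from unplanted genes.
#'
#' @param n_genes population size.
#' @param n_terms total number of terms including the root.
#' @param planted `NULL` (null universe) or a data frame with columns `K`
#'   (annotated genes of the planted term) and `fold` (study
#'   over-representation factor, >= 1); each row gets its own leaf term.
#' @param study_frac study size as a fraction of the population.
#' @param seed integer seed.
#' @return list with `obo` / `gaf` (serialised text), `graph` (in-memory
#'   `ontology_graph`), `annotations` (gene -> terms list), `study`
#'   (character vector), `population`, and `truth` (planted term table with
#'   `expected_k`).
#' @export
gen_go_universe <- function(n_genes = 1000L, n_terms = 30L, planted = NULL,
                            study_frac = 0.1, seed = 1L) {
  set.seed(seed)
  if (!is.null(planted)) {
    stopifnot(all(c("K", "fold") %in% names(planted)))
    if (any(planted$fold < 1)) stop("study_fold must be >= 1")
    if (any(planted$fold * study_frac > 1))
      stop("infeasible fold: planted study membership probability exceeds 1")
  }
  n_planted <- if (is.null(planted)) 0L else nrow(planted)
  if (n_terms < 5L + n_planted) stop("n_terms too small")
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  root <- terms[1L]
  n_slim <- max(3L, round(0.2 * (n_terms - 1L)))
  slim <- terms[2L:(1L + n_slim)]
  leaves <- terms[(2L + n_slim):n_terms]
  parents <- stats::setNames(vector("list", n_terms), terms)
  parents[[root]] <- character()
  for (s in slim) parents[[s]] <- root
  for (l in leaves)
    parents[[l]] <- sample(slim, sample(1:2, 1L))
  genes <- sprintf("g%05d", seq_len(n_genes))
  planted_terms <- if (n_planted) leaves[seq_len(n_planted)] else character()
  free_leaves <- setdiff(leaves, planted_terms)
  annotations <- stats::setNames(
    lapply(seq_len(n_genes), function(i)
      sample(free_leaves, sample(1:3, 1L))), genes)
  planted_genes_all <- character()
  truth <- NULL
  if (n_planted) {
    truth <- planted
    truth$term <- planted_terms
    truth$expected_k <- planted$fold * study_frac * planted$K
    for (i in seq_len(n_planted)) {
      gs <- sample(genes, planted$K[i])
      for (g in gs) annotations[[g]] <- unique(c(annotations[[g]], planted_terms[i]))
      truth$genes[i] <- list(gs)
      planted_genes_all <- union(planted_genes_all, gs)
    }
  }
  n_study <- round(study_frac * n_genes)
  study <- character()
  if (n_planted) {
    for (i in seq_len(n_planted)) {
      gs <- truth$genes[[i]]
      keep <- runif(length(gs)) < planted$fold[i] * study_frac
      study <- union(study, gs[keep])
    }
  }
  pool <- setdiff(genes, union(study, planted_genes_all))
  if (length(study) < n_study)
    study <- c(study, sample(pool, n_study - length(study)))
  else
    study <- sample(study, n_study)
  graph <- structure(list(terms = terms,
                          name = stats::setNames(paste("term", seq_len(n_terms)), terms),
                          namespace = stats::setNames(rep("BP", n_terms), terms),
                          parents = parents, slim = slim,
                          n_obsolete_dropped = 0L),
                     class = "ontology_graph")
  # serialisations
  obo <- c("format-version: 1.2", "")
  for (t in terms) {
    obo <- c(obo, "[Term]", paste0("id: ", t),
             paste0("name: ", graph$name[[t]]),
             "namespace: biological_process",
             paste0("is_a: ", parents[[t]]), "")
  }
  gaf_rows <- unlist(lapply(genes, function(g)
    sprintf("SYN\t%s\t%s\t\t%s\tREF:0\tIEA\t\tP\t\t\tgene\ttaxon:0000\t20150101\tSYN\t\t",
            g, g, annotations[[g]])))
  gaf <- c("!gaf-version: 2.1", gaf_rows)
  list(obo = paste(obo, collapse = "\n"), gaf = paste(gaf, collapse = "\n"),
       graph = graph, annotations = annotations, study = sort(study),
       population = genes, truth = truth)
}

# ---- EST libraries --------------------------------------------------------

#' Synthetic EST library covering a known subset of genes
#'
#' Each expressed gene contributes 1-3 fragments (exact or lightly mutated,
#' random strand); unexpressed genes contribute nothing.
#'
#' @param genes [seq_set()] of nucleotide gene sequences.
#' @param expressed_frac fraction of genes expressed (exact count,
#'   `round(expressed_frac * n)`).
#' @param fragment_len_range fragment length range (bp), capped at the gene
#'   length.
#' @param mut_rate per-base substitution rate applied to fragments.
#' @param seed integer seed.
#' @return list with `ests` (a [seq_set()], possibly with zero rows) and
#'   `truth` (named logical: gene -> expressed).
#' @export
gen_ests <- function(genes, expressed_frac = 0.7,
                     fragment_len_range = c(150L, 400L), mut_rate = 0.01,
                     seed = 1L) {
  stopifnot(expressed_frac >= 0, expressed_frac <= 1)
  set.seed(seed)
  n <- nrow(genes)
  n_expr <- round(expressed_frac * n)
  expressed <- stats::setNames(rep(FALSE, n), genes$id)
  if (n_expr > 0L) expressed[sample(genes$id, n_expr)] <- TRUE
  ids <- character(); seqs <- character()
  for (g in genes$id[expressed[genes$id]]) {
    gs <- genes$seq[genes$id == g]
    glen <- nchar(gs)
    for (frag in seq_len(sample(1:3, 1L))) {
      len <- min(fragment_len_range[1L] + sample.int(fragment_len_range[2L] - fragment_len_range[1L] + 1L, 1L) - 1L, glen)
      start <- sample.int(glen - len + 1L, 1L)
      s <- strsplit(substr(gs, start, start + len - 1L), "")[[1L]]
      n_mut <- stats::rbinom(1L, len, mut_rate)
      if (n_mut > 0L) {
        pos <- sample.int(len, n_mut)
        for (p in pos) s[p] <- other_base(s[p])
      }
      seq <- paste(s, collapse = "")
      if (sample(c(TRUE, FALSE), 1L)) seq <- revcomp(seq)
      ids <- c(ids, sprintf("est_%04d", length(ids) + 1L))
      seqs <- c(seqs, seq)
    }
  }
  ests <- if (length(ids)) seq_set(ids, seqs) else {
    e <- data.frame(id = character(), seq = character(), kind = character(),
                    compartment = character(), species = character(),
                    taxon_group = character(), desc = character(),
                    stringsAsFactors = FALSE)
    class(e) <- c("seq_set", "data.frame")
    e
  }
  list(ests = ests, truth = expressed)
}
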