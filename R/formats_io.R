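# Readers and writers for the external formats the census touches: FASTA,
# newick, OBO 1.2 and GAF 2.x. All downstream modules work on the in-memory
# containers built here; interval coordinates everywhere in the package are
# 0-based, half-open, on the forward strand of the named sequence.

#' Build a set of sequence records
#'
#' The package's sequence container is a plain data frame (class `seq_set`)
#' with one row per sequence and columns `id`, `seq`, `kind`, `compartment`,
#' `species`, `taxon_group` and `desc`. Sequences are stored uppercase and
#' validated against the declared alphabet (A/C/G/T/N for nucleotide, the 20
#' amino acids plus X for protein).
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param seq character vector of sequences.
#' @param kind `"nucleotide"` or `"protein"`.
#' @param compartment one of `"nuclear"`, `"plastid"`, `"mitochondrial"`,
#'   `"unknown"` (recycled).
#' @param species species label (recycled).
#' @param taxon_group one of `"cyanobacteria"`, `"other_bacteria"`,
#'   `"reference_eukaryote"`, `"query"`, or `NA` (recycled).
#' @param desc free-text description (recycled).
#' @return a `seq_set` data frame.
#' @export
seq_set <- function(id, seq, kind = c("nucleotide", "protein"),
                    compartment = "unknown", species = NA_character_,
                    taxon_group = NA_character_, desc = NA_character_) {
  kind <- match.arg(kind)
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("'id' and 'seq' lengths differ")
  if (any(!nzchar(id))) stop("empty sequence id")
  if (any(!nzchar(seq))) stop(sprintf("empty sequence for id '%s'",
                                      id[!nzchar(seq)][1L]))
  dup <- id[duplicated(id)]
  if (length(dup)) stop(sprintf("duplicate id %s", dup[1L]))
  if (!all(is.na(compartment)) && !all(compartment %in% COMPARTMENTS))
    stop("unknown compartment")
  tg <- taxon_group
  if (!all(is.na(tg)) && !all(tg[!is.na(tg)] %in% TAXON_GROUPS))
    stop("unknown taxon_group")
  for (i in seq_along(id)) validate_alphabet(seq[i], kind, id[i])
  out <- data.frame(id = id, seq = seq, kind = kind,
                    compartment = compartment, species = species,
                    taxon_group = taxon_group, desc = desc,
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_set", "data.frame")
  out
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set of %d %s sequence(s)\n", nrow(x),
              paste(unique(x$kind), collapse = "/")))
  n <- min(nrow(x), 6L)
  for (i in seq_len(n))
    cat(sprintf("  %s  (%d %s)\n", x$id[i], nchar(x$seq[i]),
                if (x$kind[i] == "nucleotide") "bp" else "aa"))
  if (nrow(x) > n) cat(sprintf("  ... and %d more\n", nrow(x) - n))
  invisible(x)
}

#' Read a FASTA file into a seq_set
#'
#' Identifiers are the token before the first whitespace of the header; the
#' remainder of the header is kept in the `desc` column. Sequences are
#' uppercased and validated. Duplicate ids, illegal characters and empty
#' files are hard errors.
#'
#' @param path path to a FASTA file.
#' @param kind `"nucleotide"` or `"protein"`.
#' @param metadata optional data frame with an `id` column and any of
#'   `compartment`, `species`, `taxon_group`; its ids must be a subset of the
#'   FASTA ids.
#' @return a [seq_set()].
#' @export
read_fasta <- function(path, kind = c("nucleotide", "protein"), metadata = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (file.size(path) == 0L) stop(sprintf("empty FASTA file: %s", path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop(sprintf("empty FASTA file: %s", path))
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), NA_character_)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop(sprintf("duplicate id %s in %s", dup[1L], path))
  out <- seq_set(ids, as.character(ss), kind = kind, desc = desc)
  if (!is.null(metadata)) {
    if (!"id" %in% names(metadata)) stop("metadata must have an 'id' column")
    extra <- setdiff(metadata$id, ids)
    if (length(extra))
      stop(sprintf("metadata ids absent from FASTA: %s",
                   paste(utils::head(extra, 5L), collapse = ", ")))
    m <- match(out$id, metadata$id)
    for (col in intersect(c("compartment", "species", "taxon_group"), names(metadata))) {
      hit <- !is.na(m)
      out[[col]][hit] <- metadata[[col]][m[hit]]
    }
    # re-validate enum columns
    out <- seq_set(out$id, out$seq, kind = kind, compartment = out$compartment,
                   species = out$species, taxon_group = out$taxon_group,
                   desc = out$desc)
  }
  out
}

#' Write a seq_set to FASTA
#'
#' @param seqs a [seq_set()].
#' @param path output path.
#' @param width line width for wrapping sequences.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    header <- if (!is.na(seqs$desc[i])) paste(seqs$id[i], seqs$desc[i]) else seqs$id[i]
    writeLines(paste0(">", header), con)
    s <- seqs$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Parse a newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]. The text must be a
#' single newick statement terminated by `;`. Unbalanced parentheses are
#' reported with their character offset; duplicate leaf labels are a hard
#' error. Round-tripping through [write_newick()] preserves topology, labels
#' and branch lengths to 6 significant digits.
#'
#' @param text a newick string, or the path of a file holding one.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(text) {
  if (length(text) == 1L && !grepl("[(;]", text) && file.exists(text))
    text <- paste(readLines(text), collapse = "")
  text <- trimws(text)
  if (!grepl(";\\s*$", text)) stop("newick statement must end with ';'")
  depth <- 0L
  chars <- strsplit(text, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop(sprintf("unbalanced ')' at character %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("unbalanced '(': %d unclosed at end of statement", depth))
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("newick parse error")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) stop(sprintf("duplicate leaf label %s", dup[1L]))
  tree
}

#' Serialise a phylo tree to newick
#'
#' @param tree a `phylo` object.
#' @param digits significant digits for branch lengths.
#' @return a newick string terminated by `;`.
#' @export
write_newick <- function(tree, digits = 6L) {
  ape::write.tree(tree, digits = digits)
}

# ---- ontology -------------------------------------------------------------

#' Read an OBO 1.2 ontology
#'
#' Parses `[Term]` stanzas keeping `is_a` and `relationship: part_of` parent
#' links only. Obsolete terms are dropped (their count is reported in a
#' message). The parsed graph must be acyclic.
#'
#' @param path path to an OBO 1.2 file.
#' @param slim_ids optional character vector of term ids to flag as the
#'   GO-Slim subset (ids absent from the ontology are ignored with a warning).
#' @return an `ontology_graph`: a list with elements `terms`, `name`,
#'   `namespace` (named `BP`/`MF`/`CC` vector), `parents` (named list of
#'   parent term ids), and `slim`.
#' @export
read_obo <- function(path, slim_ids = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  ns_map <- c(biological_process = "BP", molecular_function = "MF",
              cellular_component = "CC")
  terms <- character(); names_ <- character(); ns <- character()
  parents <- list()
  cur <- NULL; n_obsolete <- 0L
  flush <- function() {
    if (is.null(cur) || is.null(cur$id)) return()
    if (isTRUE(cur$obsolete)) { n_obsolete <<- n_obsolete + 1L; return() }
    terms <<- c(terms, cur$id)
    names_ <<- c(names_, cur$name %||% cur$id)
    ns <<- c(ns, cur$ns %||% NA_character_)
    parents[[cur$id]] <<- unique(cur$parents)
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(parents = character()); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^namespace:", ln))
      cur$ns <- unname(ns_map[trimws(sub("^namespace:", "", ln))])
    else if (grepl("^is_obsolete:\\s*true", ln)) cur$obsolete <- TRUE
    else if (grepl("^is_a:", ln)) {
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$parents <- c(cur$parents, p)
    } else if (grepl("^relationship:\\s*part_of", ln)) {
      p <- trimws(sub("!.*$", "", sub("^relationship:\\s*part_of", "", ln)))
      cur$parents <- c(cur$parents, p)
    }
  }
  flush()
  if (n_obsolete > 0L) message(sprintf("dropped %d obsolete term(s)", n_obsolete))
  names(names_) <- terms
  names(ns) <- terms
  # drop parent links to unknown (e.g. obsolete) terms
  parents <- lapply(parents, function(p) p[p %in% terms])
  # acyclicity
  edges <- data.frame(
    from = rep(names(parents), lengths(parents)),
    to = unlist(parents, use.names = FALSE))
  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = data.frame(name = terms))
    if (!igraph::is_dag(g)) stop("cyclic ontology: parent links form a cycle")
  }
  slim <- character()
  if (!is.null(slim_ids)) {
    missing <- setdiff(slim_ids, terms)
    if (length(missing))
      warning(sprintf("%d slim id(s) absent from ontology, ignored", length(missing)))
    slim <- intersect(slim_ids, terms)
  }
  graph <- list(terms = terms, name = names_, namespace = ns,
                parents = parents, slim = slim,
                n_obsolete_dropped = n_obsolete)
  class(graph) <- "ontology_graph"
  graph
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph: %d terms (%s), %d slim\n", length(x$terms),
              paste(names(table(x$namespace)), table(x$namespace),
                    sep = ":", collapse = " "),
              length(x$slim)))
  invisible(x)
}

# All ancestors (excluding the term itself) for every term, by memoised DFS.
term_ancestors <- function(graph) {
  cache <- new.env(parent = emptyenv())
  anc <- function(t) {
    if (!is.null(cache[[t]])) return(cache[[t]])
    ps <- graph$parents[[t]]
    res <- unique(c(ps, unlist(lapply(ps, anc), use.names = FALSE)))
    cache[[t]] <- res %||% character()
    cache[[t]]
  }
  setNames(lapply(graph$terms, anc), graph$terms)
}

#' Read a GAF 2.x annotation file
#'
#' Comment lines start with `!`. Rows whose qualifier contains `NOT` are
#' dropped, as are rows annotating a term absent from the ontology (with a
#' warning). Evidence codes are not filtered by default; pass
#' `exclude_evidence = "IEA"` to drop electronically inferred annotations.
#'
#' @param path path to a GAF 2.x file.
#' @param graph an `ontology_graph` from [read_obo()].
#' @param exclude_evidence character vector of evidence codes to drop.
#' @return named list mapping gene id (GAF column 2) to its annotated GO term
#'   ids (GAF column 5).
#' @export
read_gaf <- function(path, graph, exclude_evidence = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  if (!length(lines)) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, length, integer(1)) >= 7L
  fields <- fields[keep]
  gene <- vapply(fields, `[[`, character(1), 2L)
  qualifier <- vapply(fields, `[[`, character(1), 4L)
  term <- vapply(fields, `[[`, character(1), 5L)
  evidence <- vapply(fields, `[[`, character(1), 7L)
  drop_not <- grepl("(^|\\|)NOT($|\\|)", qualifier)
  gene <- gene[!drop_not]; term <- term[!drop_not]; evidence <- evidence[!drop_not]
  if (!is.null(exclude_evidence)) {
    keep <- !(evidence %in% exclude_evidence)
    gene <- gene[keep]; term <- term[keep]
  }
  unknown <- !(term %in% graph$terms)
  if (any(unknown)) {
    warning(sprintf("dropped %d GAF row(s) referencing term(s) absent from ontology (e.g. %s)",
                    sum(unknown), term[unknown][1L]))
    gene <- gene[!unknown]; term <- term[!unknown]
  }
  if (!length(gene)) return(list())
  lapply(split(term, gene), unique)
}

#' Read ontology and annotations together
#'
#' @inheritParams read_obo
#' @inheritParams read_gaf
#' @param gaf_path path to a GAF 2.x file.
#' @return list with elements `graph` (an `ontology_graph`) and `annotations`
#'   (named list gene -> term ids).
#' @export
read_ontology <- function(path, gaf_path, slim_ids = NULL, exclude_evidence = NULL) {
  graph <- read_obo(path, slim_ids = slim_ids)
  annotations <- read_gaf(gaf_path, graph, exclude_evidence = exclude_evidence)
  list(graph = graph, annotations = annotations)
}
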