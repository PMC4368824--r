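# Gene-family trees and taxonomy-aware origin classification: pairwise
# Kimura-corrected protein distances, neighbor joining, sister-clade
# composition calls, and the census table algebra.

#' Pairwise Kimura-corrected protein distance matrix
#'
#' Each pair is aligned with [smith_waterman()]; the mismatch fraction `D`
#' (1 - identity) on that alignment is corrected with the Kimura protein
#' formula `d = -ln(1 - D - D^2/5)`, capped at 5.0 for `D >= 0.85` (or
#' whenever the argument of the logarithm is non-positive).
#'
#' @param family a [seq_set()] of at least 3 proteins.
#' @inheritParams smith_waterman
#' @return symmetric numeric matrix with zero diagonal, dimnames the family
#'   ids. A pair producing no local alignment is a hard error naming it.
#' @export
protein_distance_matrix <- function(family, matrix = blosum62(),
                                    gap_open = 11L, gap_extend = 1L) {
  n <- nrow(family)
  if (n < 3L) stop("need at least 3 proteins")
  d <- matrix(0, n, n, dimnames = list(family$id, family$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      aln <- smith_waterman(family[i, , drop = FALSE], family[j, , drop = FALSE],
                            matrix = matrix, gap_open = gap_open,
                            gap_extend = gap_extend)
      if (is.null(aln))
        stop(sprintf("no local alignment between %s and %s",
                     family$id[i], family$id[j]))
      D <- 1 - aln$identity_pct / 100
      arg <- 1 - D - D^2 / 5
      d[i, j] <- d[j, i] <- if (D >= 0.85 || arg <= 0) 5.0 else -log(arg)
    }
  }
  d
}

#' Kimura protein distance from a mismatch fraction
#'
#' @param D mismatch fraction in `[0, 1]`.
#' @return `-ln(1 - D - D^2/5)`, capped at 5.0 for `D >= 0.85`.
#' @export
kimura_protein_distance <- function(D) {
  stopifnot(all(D >= 0 & D <= 1))
  arg <- 1 - D - D^2 / 5
  ifelse(D >= 0.85 | arg <= 0, 5.0, -log(arg))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical neighbor joining (via [ape::nj()]); for an additive matrix the
#' unrooted topology equals the generating tree exactly. Negative branch
#' lengths are clamped to zero with the deficit shifted to a sibling edge so
#' path lengths are approximately preserved.
#'
#' @param dist square symmetric matrix with zero diagonal, >= 3 taxa.
#' @param ids optional taxon labels overriding the matrix dimnames.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(dist, ids = NULL) {
  dist <- as.matrix(dist)
  if (nrow(dist) != ncol(dist) || !isTRUE(all.equal(dist, t(dist), tolerance = 1e-8)))
    stop("distance matrix must be square and symmetric")
  if (any(abs(diag(dist)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (nrow(dist) < 3L) stop("need at least 3 taxa")
  if (!is.null(ids)) dimnames(dist) <- list(ids, ids)
  tree <- ape::nj(dist)
  # clamp negative branch lengths, shifting the deficit to a sibling edge
  if (!is.null(tree$edge.length)) {
    neg <- which(tree$edge.length < 0)
    for (e in neg) {
      deficit <- tree$edge.length[e]
      tree$edge.length[e] <- 0
      parent <- tree$edge[e, 1L]
      sibs <- setdiff(which(tree$edge[, 1L] == parent), e)
      if (length(sibs)) {
        s <- sibs[1L]
        tree$edge.length[s] <- max(0, tree$edge.length[s] + deficit)
      }
    }
  }
  tree
}

# Leaf sets of each subtree hanging off the query's attachment node,
# excluding the query tip itself. Works on the unrooted adjacency.
attachment_sides <- function(tree, query_leaf) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  q <- match(query_leaf, tree$tip.label)
  if (is.na(q)) stop(sprintf("query leaf '%s' absent from tree", query_leaf))
  edge <- tree$edge
  u <- edge[edge[, 2L] == q, 1L]
  if (!length(u)) u <- edge[edge[, 1L] == q, 2L] # degenerate rooting
  adj <- split(c(edge[, 2L], edge[, 1L]), c(edge[, 1L], edge[, 2L]))
  sides <- list()
  for (v in setdiff(adj[[as.character(u)]], q)) {
    # collect leaves reachable from v without passing through u
    seen <- c(u, v); stack <- v; leaves <- integer()
    while (length(stack)) {
      node <- stack[[1L]]; stack <- stack[-1L]
      if (node <= ntip) leaves <- c(leaves, node)
      nb <- setdiff(adj[[as.character(node)]], seen)
      seen <- c(seen, nb)
      stack <- c(stack, nb)
    }
    sides[[length(sides) + 1L]] <- sort(tree$tip.label[leaves])
  }
  sides
}

#' Classify a query gene's origin from its gene tree
#'
#' The tree is treated as unrooted. The query's sister set is the smallest
#' leaf set among the subtrees meeting the query's attachment node, counting
#' only leaves that are not query-species paralogs (paralogs carry no signal
#' about the donor lineage); size ties are broken deterministically by
#' comparing the sides' sorted label vectors. The call is
#' `cyanobacterial` when the cyanobacterial fraction of the sister set
#' exceeds 1/2, `non_cyanobacterial` when the sister set contains no
#' cyanobacterial leaf, and `ambiguous` otherwise — a strict majority rule
#' whose supporting fraction is reported so callers can re-threshold.
#'
#' @param tree a `phylo` gene tree.
#' @param query_leaf the query gene's leaf label.
#' @param groups named character vector mapping every other leaf label to a
#'   taxon group (`cyanobacteria`, `other_bacteria`, `reference_eukaryote`,
#'   `query`).
#' @param tree_id optional identifier recorded in the output.
#' @return an `origin_call`: one-row data frame with `gene_id`, `call`,
#'   `sister_cyano_fraction`, `n_sister_leaves`, `tree_id`.
#' @export
classify_origin <- function(tree, query_leaf, groups, tree_id = NA_character_) {
  if (!query_leaf %in% tree$tip.label)
    stop(sprintf("query leaf '%s' absent from tree", query_leaf))
  others <- setdiff(tree$tip.label, query_leaf)
  missing <- setdiff(others, names(groups))
  if (length(missing))
    stop(sprintf("no taxon_group for leaf '%s'", missing[1L]))
  bad <- setdiff(unique(groups[others]), TAXON_GROUPS)
  if (length(bad)) stop(sprintf("unknown taxon_group '%s'", bad[1L]))
  make_call <- function(call, frac, n_sister) {
    out <- data.frame(gene_id = query_leaf, call = call,
                      sister_cyano_fraction = frac,
                      n_sister_leaves = n_sister, tree_id = tree_id,
                      stringsAsFactors = FALSE)
    class(out) <- c("origin_call", "data.frame")
    out
  }
  informative <- others[groups[others] != "query"]
  if (!length(informative)) {
    warning("all non-query leaves are query-species paralogs; call ambiguous")
    return(make_call("ambiguous", NA_real_, 0L))
  }
  sides <- attachment_sides(tree, query_leaf)
  sides <- lapply(sides, function(s) s[s %in% informative])
  sizes <- lengths(sides)
  cand <- which(sizes > 0L)
  if (!length(cand)) {
    warning("query attaches among paralogs only; call ambiguous")
    return(make_call("ambiguous", NA_real_, 0L))
  }
  best <- cand[sizes[cand] == min(sizes[cand])]
  if (length(best) > 1L) {
    # deterministic, rooting-invariant tie-break on sorted label vectors
    keys <- vapply(sides[best], paste, character(1), collapse = "\r")
    best <- best[order(keys, decreasing = TRUE)]
  }
  sister <- sides[[best[1L]]]
  n_cyano <- sum(groups[sister] == "cyanobacteria")
  frac <- n_cyano / length(sister)
  call <- if (frac > 0.5) "cyanobacterial"
          else if (n_cyano == 0L) "non_cyanobacterial"
          else "ambiguous"
  make_call(call, frac, length(sister))
}

#' Assemble the gene-transfer census summary
#'
#' Set algebra over the three relations of the census: origin calls for
#' nuclear genes, the nuclear-versus-plastid homology table, and the plastid
#' proteome, plus the per-gene expression qualifier.
#'
#' @param origin_calls data frame with `gene_id` and `call` columns (one row
#'   per nuclear gene, e.g. rbind-ed [classify_origin()] results).
#' @param nuc_vs_plastid a `homology_table` with nuclear queries and plastid
#'   subjects.
#' @param plastid_proteins character vector of plastid protein ids.
#' @param expression optional named logical vector (gene -> expressed) for
#'   the recruits whose expression was assessed.
#' @return a one-row `census_summary` data frame with columns
#'   `n_cyano_recruits`, `n_nuclear_with_plastid_homolog`, `n_both`,
#'   `n_plastid_proteins`, `n_plastid_with_nuclear_homolog`,
#'   `n_plastid_with_cyano_nuclear_homolog`, `pct_recruits_expressed`.
#' @export
build_census <- function(origin_calls, nuc_vs_plastid, plastid_proteins,
                         expression = NULL) {
  recruits <- unique(origin_calls$gene_id[origin_calls$call == "cyanobacterial"])
  nuc_with <- unique(nuc_vs_plastid$query)
  pla_with <- unique(nuc_vs_plastid$subject)
  pla_cyano <- unique(nuc_vs_plastid$subject[nuc_vs_plastid$query %in% recruits])
  pct <- NA_real_
  if (!is.null(expression)) {
    assessed <- intersect(recruits, names(expression))
    if (length(assessed))
      pct <- 100 * mean(as.logical(expression[assessed]))
  }
  out <- data.frame(
    n_cyano_recruits = length(recruits),
    n_nuclear_with_plastid_homolog = length(nuc_with),
    n_both = length(intersect(recruits, nuc_with)),
    n_plastid_proteins = length(unique(plastid_proteins)),
    n_plastid_with_nuclear_homolog = length(pla_with),
    n_plastid_with_cyano_nuclear_homolog = length(pla_cyano),
    pct_recruits_expressed = pct)
  class(out) <- c("census_summary", "data.frame")
  out
}

#' @export
print.census_summary <- function(x, ...) {
  cat("gene-transfer census summary\n")
  print.data.frame(as.data.frame(x))
  invisible(x)
}
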