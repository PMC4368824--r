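# GO term-abundance analysis: true-path propagation, GO-Slim mapping,
# hypergeometric over-representation with per-namespace multiple-test
# adjustment.

#' Propagate annotations up the ontology (true-path rule)
#'
#' Closes each gene's term set under is_a/part_of ancestors within each
#' term's namespace. Idempotent; never removes a term.
#'
#' @param annotations named list mapping gene -> character vector of term ids.
#' @param graph an `ontology_graph`.
#' @return named list of propagated term sets.
#' @export
propagate_annotations <- function(annotations, graph) {
  anc <- term_ancestors(graph)
  # per-term closure restricted to the term's own namespace
  closure <- lapply(graph$terms, function(t) {
    a <- anc[[t]]
    c(t, a[graph$namespace[a] == graph$namespace[[t]]])
  })
  names(closure) <- graph$terms
  lapply(annotations, function(terms) {
    terms <- intersect(terms, graph$terms)
    unique(unlist(closure[terms], use.names = FALSE))
  })
}

#' Map terms to their most specific GO-Slim ancestors
#'
#' Returns the slim terms reachable upward (including the terms themselves)
#' from the input set, minus any slim term that is a strict ancestor of
#' another returned slim term. Terms with no slim ancestor contribute
#' nothing.
#'
#' @param terms character vector of term ids.
#' @param graph an `ontology_graph` with a non-empty `slim` set.
#' @return character vector of slim term ids.
#' @export
map_to_slim <- function(terms, graph) {
  if (!length(graph$slim)) stop("ontology has no slim subset")
  anc <- term_ancestors(graph)
  terms <- intersect(terms, graph$terms)
  hit <- unique(unlist(lapply(terms, function(t) {
    s <- intersect(c(t, anc[[t]]), graph$slim)
    s
  }), use.names = FALSE))
  if (!length(hit)) return(character())
  # drop slim terms that are strict ancestors of other selected slim terms
  masked <- unique(unlist(anc[hit], use.names = FALSE))
  setdiff(hit, masked)
}

#' Upper-tail hypergeometric probability
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: the probability of seeing
#' at least `k` annotated genes in a study set of size `n` drawn without
#' replacement from a population of `N` genes of which `K` are annotated.
#' Computed in log space from binomial coefficients.
#'
#' @param k observed annotated study genes.
#' @param K annotated population genes.
#' @param n study size.
#' @param N population size.
#' @return the upper tail probability.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || K > N || n > N || k > min(n, K))
    stop("inconsistent counts: need 0 <= k <= min(n, K), K <= N, n <= N")
  if (k == 0) return(1)
  j <- k:min(n, K)
  p <- sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
  min(p, 1)
}

#' Multiple-test adjustment
#'
#' Benjamini-Hochberg step-up adjusted p-values by default (the FDR-style
#' family historically used by term-abundance servers); Bonferroni and
#' Hochberg are available.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param method `"BH"`, `"bonferroni"` or `"hochberg"`.
#' @return adjusted p-values, input order preserved, clipped to 1.
#' @export
bh_adjust <- function(p, method = c("BH", "bonferroni", "hochberg")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}

#' GO term-abundance (enrichment) analysis
#'
#' Over-representation of each GO term in a study set against a population:
#' annotations are propagated by the true-path rule (and optionally
#' collapsed to GO-Slim), each term annotated in the study is tested with
#' the upper-tail hypergeometric probability, and p-values are adjusted
#' within each namespace separately.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population character vector of background gene ids.
#' @param annotations named list gene -> term ids (raw, unpropagated).
#' @param graph an `ontology_graph`.
#' @param alpha significance level; a term is significant when its adjusted
#'   p-value is strictly below `alpha`.
#' @param use_slim collapse propagated sets to most-specific slim terms.
#' @param method multiple-test adjustment method, see [bh_adjust()].
#' @return an `enrichment_result` data frame (`term`, `name`, `namespace`,
#'   `k`, `n`, `K`, `N`, `p_raw`, `p_adj`, `significant`), sorted by
#'   ascending adjusted p.
#' @export
go_enrich <- function(study, population, annotations, graph, alpha = 0.05,
                      use_slim = FALSE, method = "BH") {
  study <- unique(study); population <- unique(population)
  if (!length(study)) stop("empty study set")
  offenders <- setdiff(study, population)
  if (length(offenders))
    stop(sprintf("study genes absent from population: %s",
                 paste(utils::head(offenders, 5L), collapse = ", ")))
  ann <- annotations[intersect(names(annotations), population)]
  ann <- propagate_annotations(ann, graph)
  if (use_slim) ann <- lapply(ann, map_to_slim, graph = graph)
  gene <- rep(names(ann), lengths(ann))
  term <- unlist(ann, use.names = FALSE)
  n <- length(study); N <- length(population)
  in_study <- gene %in% study
  k_tab <- table(term[in_study])
  K_tab <- table(term)
  terms <- names(k_tab)
  if (!length(terms)) {
    out <- data.frame(term = character(), name = character(),
                      namespace = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_raw = numeric(),
                      p_adj = numeric(), significant = logical())
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  k <- as.integer(k_tab[terms])
  K <- as.integer(K_tab[terms])
  p_raw <- vapply(seq_along(terms),
                  function(i) hypergeom_upper(k[i], K[i], n, N), numeric(1))
  ns <- unname(graph$namespace[terms])
  p_adj <- numeric(length(p_raw))
  for (nsp in unique(ns)) {
    sel <- ns == nsp
    p_adj[sel] <- bh_adjust(p_raw[sel], method = method)
  }
  out <- data.frame(term = terms, name = unname(graph$name[terms]),
                    namespace = ns, k = k, n = n, K = K, N = N,
                    p_raw = p_raw, p_adj = p_adj,
                    significant = p_adj < alpha, stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "method") <- method
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Write enrichment results as TSV
#'
#' The header records the adjustment method and alpha as a comment line.
#' @param results an `enrichment_result`.
#' @param path output path.
#' @export
write_enrichment_tsv <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# adjustment=%s alpha=%s",
                     attr(results, "method") %||% "BH",
                     format(attr(results, "alpha") %||% 0.05)), con)
  df <- as.data.frame(results)
  df$p_raw <- signif(df$p_raw, 6L)
  df$p_adj <- signif(df$p_adj, 6L)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
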