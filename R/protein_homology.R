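# Local sequence search with the census filters: exact affine-gap
# Smith-Waterman behind a shared-k-mer prefilter, Karlin-Altschul E-values,
# and the EST-based expression qualifier.

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Exact Gotoh dynamic programming; the score is the true optimum under the
#' given substitution matrix and affine penalties (a gap of length L costs
#' `gap_open + L * gap_extend`). Returns `NULL` when the optimum is not
#' positive. Identity is identical columns over all alignment columns
#' including gaps, the convention the standard 25 percent identity filter
#' assumes.
#'
#' @param a,b one-row [seq_set()] rows or plain strings; both protein or both
#'   nucleotide.
#' @param matrix substitution matrix with single-letter dimnames
#'   ([blosum62()] by default; use [nucleotide_matrix()] for DNA).
#' @param gap_open,gap_extend positive affine gap penalties.
#' @return a `local_alignment` list (`query_id`, `subject_id`, `score`,
#'   `q_start`, `q_end`, `s_start`, `s_end` 0-based half-open,
#'   `identity_pct`, `aln_len`, `matches`) or `NULL`.
#' @export
smith_waterman <- function(a, b, matrix = blosum62(), gap_open = 11L,
                           gap_extend = 1L) {
  qa <- as_seq(a); qb <- as_seq(b)
  if (!is.na(qa$kind) && !is.na(qb$kind) && qa$kind != qb$kind)
    stop("mixed alphabets: query and subject must both be protein or both nucleotide")
  if (gap_open < 0L || gap_extend <= 0L) stop("affine penalties must be positive")
  res <- cpp_smith_waterman(qa$seq, qb$seq, matrix, rownames(matrix),
                            as.integer(gap_open), as.integer(gap_extend))
  if (is.null(res)) return(NULL)
  out <- list(query_id = qa$id, subject_id = qb$id, score = res$score,
              q_start = res$q_start, q_end = res$q_end,
              s_start = res$s_start, s_end = res$s_end,
              identity_pct = res$identity_pct, aln_len = res$aln_len,
              matches = res$matches)
  class(out) <- "local_alignment"
  out
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("%s x %s: score %d, identity %.1f%% over %d columns, q[%d,%d) s[%d,%d)\n",
              x$query_id, x$subject_id, x$score, x$identity_pct, x$aln_len,
              x$q_start, x$q_end, x$s_start, x$s_end))
  invisible(x)
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of local
#' alignments of score at least `S` between random sequences of lengths `m`
#' and `n`. The defaults are the gapped BLOSUM62 regime constants.
#'
#' @param score raw alignment score.
#' @param m,n query and subject (or search-space) lengths.
#' @param lambda,K positive Karlin-Altschul parameters.
#' @return the E-value.
#' @export
blast_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  if (any(m < 1L) || any(n < 1L)) stop("m and n must be >= 1")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  K * as.numeric(m) * as.numeric(n) * exp(-lambda * score)
}

#' Search queries against subjects with the census filters
#'
#' Candidate pairs sharing at least one exact `prefilter_k`-mer are aligned
#' by [smith_waterman()]; rows are retained only when the E-value is at most
#' `max_evalue` and identity at least `min_identity_pct` (the standard
#' recruit-screen filter is E <= 1e-10 and identity >= 25 percent). Within
#' each query, rows are sorted by ascending E-value, ties by descending score
#' then subject id.
#'
#' @param queries,subjects [seq_set()] collections (non-empty subjects).
#' @param role what the table is for: `"recruit_screen"`,
#'   `"nuclear_vs_plastid"` or `"est_expression"`.
#' @param min_identity_pct identity threshold (`>=`).
#' @param max_evalue E-value threshold (`<=`).
#' @param prefilter_k exact-word length of the candidate prefilter.
#' @inheritParams smith_waterman
#' @inheritParams blast_evalue
#' @return a `homology_table` data frame (`query`, `subject`, `score`,
#'   `evalue`, `identity_pct`, `aln_len`, `q_start`, `q_end`, `s_start`,
#'   `s_end`) with attribute `role`.
#' @export
search_homologs <- function(queries, subjects,
                            role = c("recruit_screen", "nuclear_vs_plastid",
                                     "est_expression"),
                            min_identity_pct = 25, max_evalue = 1e-10,
                            prefilter_k = 4L, matrix = blosum62(),
                            gap_open = 11L, gap_extend = 1L,
                            lambda = 0.267, K = 0.041) {
  role <- match.arg(role)
  if (nrow(subjects) == 0L) stop("empty subject set")
  empty <- data.frame(query = character(), subject = character(),
                      score = integer(), evalue = numeric(),
                      identity_pct = numeric(), aln_len = integer(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(queries) == 0L) {
    warning("empty query set")
    attr(empty, "role") <- role
    class(empty) <- c("homology_table", "data.frame")
    return(empty)
  }
  kmers <- function(s) {
    n <- nchar(s)
    if (n < prefilter_k) return(character())
    unique(substring(s, 1:(n - prefilter_k + 1L), prefilter_k:n))
  }
  sub_index <- new.env(parent = emptyenv())
  for (j in seq_len(nrow(subjects)))
    for (km in kmers(subjects$seq[j]))
      sub_index[[km]] <- c(sub_index[[km]], j)
  rows <- list()
  for (i in seq_len(nrow(queries))) {
    cand <- unique(unlist(lapply(kmers(queries$seq[i]),
                                 function(km) sub_index[[km]]),
                          use.names = FALSE))
    if (!length(cand)) next
    for (j in sort(cand)) {
      aln <- smith_waterman(queries[i, , drop = FALSE],
                            subjects[j, , drop = FALSE],
                            matrix = matrix, gap_open = gap_open,
                            gap_extend = gap_extend)
      if (is.null(aln)) next
      ev <- blast_evalue(aln$score, nchar(queries$seq[i]),
                         nchar(subjects$seq[j]), lambda, K)
      if (ev > max_evalue || aln$identity_pct < min_identity_pct) next
      rows[[length(rows) + 1L]] <- data.frame(
        query = aln$query_id, subject = aln$subject_id, score = aln$score,
        evalue = ev, identity_pct = aln$identity_pct, aln_len = aln$aln_len,
        q_start = aln$q_start, q_end = aln$q_end,
        s_start = aln$s_start, s_end = aln$s_end, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(out)) {
    out <- out[order(match(out$query, queries$id), out$evalue, -out$score,
                     out$subject), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "role") <- role
  class(out) <- c("homology_table", "data.frame")
  out
}

#' Is a gene expressed according to an EST library?
#'
#' Megablast-style qualifier: the gene is considered expressed when at least
#' one local alignment against the library, seeded by an exact
#' `word_size`-mer on either strand, reaches an E-value at most `max_evalue`.
#' Alignment scoring is the megablast reward/penalty (+1/-2, gaps -2 per
#' column) and the E-value uses the ungapped nucleotide constants over the
#' whole library as search space.
#'
#' @param gene one-row [seq_set()] or nucleotide string.
#' @param ests a non-empty [seq_set()] of EST sequences.
#' @param word_size exact seed length (default 28, the megablast default).
#' @param max_evalue qualifying E-value threshold.
#' @param lambda,K nucleotide Karlin-Altschul constants.
#' @return `TRUE` or `FALSE`, deterministically.
#' @export
est_expressed <- function(gene, ests, word_size = 28L, max_evalue = 1e-10,
                          lambda = 1.28, K = 0.46) {
  g <- as_seq(gene)
  if (!is.data.frame(ests) || nrow(ests) == 0L)
    stop("expression not assessable: empty EST library")
  m <- nchar(g$seq)
  n_space <- sum(nchar(ests$seq))
  for (j in seq_len(nrow(ests))) {
    est <- ests$seq[j]
    if (word_size > min(m, nchar(est))) next
    anchors <- cpp_find_anchors(g$seq, est, as.integer(word_size))
    if (nrow(anchors) == 0L) next
    hits <- cpp_chain_align(anchors$n_pos, anchors$o_pos, anchors$strand,
                            as.integer(word_size), g$seq, est, 100L, 0.2,
                            12L, TRUE)
    if (nrow(hits) == 0L) next
    score <- hits$matches - 2L * (hits$columns - hits$matches)
    ev <- blast_evalue(score, m, n_space, lambda, K)
    if (any(ev <= max_evalue)) return(TRUE)
  }
  FALSE
}

#' Write a homology table as TSV
#' @param table a `homology_table`.
#' @param path output path.
#' @export
write_homology_tsv <- function(table, path) {
  df <- as.data.frame(table)
  df$identity_pct <- round(df$identity_pct, 2L)
  df$evalue <- signif(df$evalue, 4L)
  write_tsv(df, path)
}
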