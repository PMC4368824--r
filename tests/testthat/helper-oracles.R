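# Independent oracles and small fixture builders used across the suite.

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                    collapse = "")

random_protein_str <- function(n) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, n, TRUE), collapse = "")
}

rc_str <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Brute-force all-pairs word comparison: every shared word between the
# nuclear forward strand and the organelle forward/reverse-complement.
oracle_anchors <- function(nuc, org, w) {
  words <- function(s) {
    n <- nchar(s)
    if (n < w) return(character())
    substring(s, 1:(n - w + 1), w:n)
  }
  nw <- words(nuc)
  ow <- words(org)
  rows <- list()
  for (i in seq_along(nw)) {
    if (grepl("N", nw[i], fixed = TRUE)) next
    fwd <- which(ow == nw[i] & !grepl("N", ow, fixed = TRUE))
    for (j in fwd)
      rows[[length(rows) + 1]] <- data.frame(n_pos = i - 1L, o_pos = j - 1L,
                                             strand = "+")
    rcw <- rc_str(nw[i])
    rev <- which(ow == rcw & !grepl("N", ow, fixed = TRUE))
    for (j in rev)
      rows[[length(rows) + 1]] <- data.frame(n_pos = i - 1L, o_pos = j - 1L,
                                             strand = "-")
  }
  if (!length(rows))
    return(data.frame(n_pos = integer(), o_pos = integer(),
                      strand = character()))
  do.call(rbind, rows)
}

sort_anchors <- function(a) {
  a <- a[order(a$n_pos, a$o_pos, a$strand), , drop = FALSE]
  rownames(a) <- NULL
  a
}

# Exhaustive enumeration of the hypergeometric upper tail: all C(N, n)
# draws from an urn with K marked balls.
oracle_hypergeom_upper <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  marked <- colSums(draws <= K)
  mean(marked >= k)
}

# Monte-Carlo membership oracle for (power) Voronoi cell areas.
mc_voronoi_areas <- function(sites, weights, n_samples = 3e5) {
  x <- runif(n_samples); y <- runif(n_samples)
  pow <- sapply(seq_len(nrow(sites)), function(i)
    (x - sites[i, 1])^2 + (y - sites[i, 2])^2 - weights[i])
  owner <- max.col(-pow)
  tabulate(owner, nbins = nrow(sites)) / n_samples
}

poly_area_test <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3) return(0)
  i <- seq_len(n); j <- c(2:n, 1)
  abs(sum(p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2])) / 2
}

# Overlap bookkeeping for implant-recovery checks.
hits_overlapping <- function(hits, n_start, n_end) {
  which(hits$n_start < n_end & hits$n_end > n_start)
}
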