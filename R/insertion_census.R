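# Detection of organelle-derived segments (NUPTs/NUMTs) in nuclear genomes:
# exact-word seeding, colinear chaining, X-drop extension, banded global
# alignment, identity/length filtering, and the derived summaries (exchange
# rate, size-class histogram, per-position copy number).

SIZE_BIN_EDGES <- c(50, 100, 200, 300, 400, 500, 1000, Inf)
SIZE_BIN_LABELS <- c("50\u201399", "-199", "-299", "-399", "-499", "-999",
                     "\u22651000")

#' Find exact shared words between a nuclear and an organelle sequence
#'
#' Reports every exact `word_size`-mer shared between the nuclear forward
#' strand and the organelle forward strand (strand `+`) or its reverse
#' complement (strand `-`). Words containing `N` never match. Coordinates are
#' 0-based starts of the word on each sequence; a `-` anchor at `(n, o)` means
#' the nuclear word equals the reverse complement of the organelle word at
#' `o`. The default word size of 50 is the field-standard setting for
#' genome-against-plastome screens of recent transfers; smaller words trade
#' specificity for sensitivity to diverged insertions.
#'
#' @param nuclear,organelle one-row [seq_set()] or plain nucleotide string.
#' @param word_size exact word length, at least 8.
#' @return data frame with columns `n_pos`, `o_pos` (0-based), `strand`.
#' @export
find_seed_matches <- function(nuclear, organelle, word_size = 50L) {
  nuc <- as_seq(nuclear); org <- as_seq(organelle)
  if (!is.na(nuc$kind) && nuc$kind != "nucleotide")
    stop("'nuclear' must be a nucleotide sequence")
  if (!is.na(org$kind) && org$kind != "nucleotide")
    stop("'organelle' must be a nucleotide sequence")
  if (word_size < 8L) stop("word_size must be >= 8")
  if (word_size > min(nchar(nuc$seq), nchar(org$seq))) {
    warning("word_size exceeds a sequence length; no anchors")
    return(data.frame(n_pos = integer(), o_pos = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  a <- cpp_find_anchors(nuc$seq, org$seq, as.integer(word_size))
  data.frame(n_pos = a$n_pos, o_pos = a$o_pos,
             strand = ifelse(a$strand > 0L, "+", "-"),
             stringsAsFactors = FALSE)
}

#' Chain anchors and align the chained spans
#'
#' Colinear same-strand anchors whose gaps on both coordinates are at most
#' `max_join_gap` are chained; chains are merged to maximality, extended
#' outwards by ungapped X-drop extension, and each final span is globally
#' aligned within a band (match +1, mismatch -1, gap -2; band width
#' `max(16, band_frac * span)`). Identity is matched columns over all
#' alignment columns.
#'
#' @param anchors output of [find_seed_matches()].
#' @param nuclear,organelle the sequences the anchors came from.
#' @param word_size the word size used for the anchors.
#' @param max_join_gap largest per-coordinate gap (bp) joined into one chain.
#' @param band_frac band width as a fraction of the aligned span.
#' @param xdrop score drop-off terminating the ungapped extension.
#' @param extend set `FALSE` to skip the X-drop extension.
#' @return an `insertion_hits` data frame with columns `nuclear_id`,
#'   `n_start`, `n_end`, `organelle_id`, `o_start`, `o_end`, `strand`,
#'   `length` (organelle span), `identity_pct`, `n_anchors` columns
#'   `matches`, `columns`.
#' @export
chain_and_align <- function(anchors, nuclear, organelle, word_size = 50L,
                            max_join_gap = 100L, band_frac = 0.2,
                            xdrop = 12L, extend = TRUE) {
  nuc <- as_seq(nuclear); org <- as_seq(organelle)
  if (nrow(anchors) == 0L) return(empty_hits())
  strand_int <- ifelse(anchors$strand == "+", 1L, -1L)
  h <- cpp_chain_align(anchors$n_pos, anchors$o_pos, strand_int,
                       as.integer(word_size), nuc$seq, org$seq,
                       as.integer(max_join_gap), band_frac,
                       as.integer(xdrop), extend)
  out <- data.frame(nuclear_id = rep(nuc$id, nrow(h)),
                    n_start = h$n_start, n_end = h$n_end,
                    organelle_id = rep(org$id, nrow(h)),
                    o_start = h$o_start, o_end = h$o_end,
                    strand = h$strand,
                    length = h$o_end - h$o_start,
                    identity_pct = h$identity_pct,
                    matches = h$matches, columns = h$columns,
                    stringsAsFactors = FALSE)
  out <- out[order(out$n_start, out$o_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("insertion_hits", "data.frame")
  out
}

empty_hits <- function() {
  out <- data.frame(nuclear_id = character(), n_start = integer(),
                    n_end = integer(), organelle_id = character(),
                    o_start = integer(), o_end = integer(),
                    strand = character(), length = integer(),
                    identity_pct = numeric(), matches = integer(),
                    columns = integer(), stringsAsFactors = FALSE)
  class(out) <- c("insertion_hits", "data.frame")
  out
}

#' Filter insertion hits on identity and length
#'
#' Retains hits with `identity_pct` strictly above `min_identity_pct` and
#' `length` at least `min_length`; order is preserved. The defaults are the
#' standard screen settings: identity strictly greater than 80 percent and a
#' minimum span of 50 bp.
#'
#' @param hits an `insertion_hits` data frame.
#' @param min_identity_pct identity threshold (strict `>`).
#' @param min_length minimum organelle span (`>=`).
#' @return the retained hits.
#' @export
filter_hits <- function(hits, min_identity_pct = 80, min_length = 50L) {
  keep <- hits$identity_pct > min_identity_pct & hits$length >= min_length
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("insertion_hits", "data.frame")
  out
}

#' Detect organelle-derived insertions in a nuclear genome
#'
#' End-to-end detector: seeds, chains, aligns and filters, over every nuclear
#' contig. The hit class is `NUPT` for plastid and `NUMT` for mitochondrial
#' sources.
#'
#' @param nuclear a [seq_set()] of nuclear contigs.
#' @param organelle a one-row [seq_set()] (or string) for the organelle
#'   genome.
#' @param class `"NUPT"` or `"NUMT"`.
#' @param circular treat the organelle genome as circular by adding a
#'   `word_size - 1` wrap-around pad, so hits crossing the origin are found;
#'   their `o_end` may then exceed the organelle length and is interpreted
#'   modulo the length by [coverage_profile()].
#' @inheritParams chain_and_align
#' @inheritParams filter_hits
#' @inheritParams find_seed_matches
#' @return filtered `insertion_hits` with a `class` column and an
#'   `organelle_len` attribute.
#' @export
detect_insertions <- function(nuclear, organelle, class = c("NUPT", "NUMT"),
                              word_size = 50L, max_join_gap = 100L,
                              band_frac = 0.2, min_identity_pct = 80,
                              min_length = 50L, circular = FALSE,
                              xdrop = 12L) {
  class <- match.arg(class)
  org <- as_seq(organelle)
  org_len <- nchar(org$seq)
  org_search <- org
  if (circular && org_len > word_size)
    org_search$seq <- paste0(org$seq, substr(org$seq, 1L, word_size - 1L))
  if (is.character(nuclear)) nuclear <- seq_set(names(nuclear) %||% "nuclear",
                                                nuclear)
  pieces <- lapply(seq_len(nrow(nuclear)), function(i) {
    contig <- nuclear[i, , drop = FALSE]
    anchors <- suppressWarnings(
      find_seed_matches(contig, org_search$seq, word_size = word_size))
    chain_and_align(anchors, contig, org_search, word_size = word_size,
                    max_join_gap = max_join_gap, band_frac = band_frac,
                    xdrop = xdrop)
  })
  hits <- do.call(rbind, c(pieces, list(empty_hits())))
  hits <- filter_hits(hits, min_identity_pct, min_length)
  hits$organelle_id <- if (nrow(hits)) org$id else character(0)
  hits$class <- rep(class, nrow(hits))
  attr(hits, "organelle_len") <- org_len
  attr(hits, "circular") <- circular
  class(hits) <- c("insertion_hits", "data.frame")
  hits
}

#' @export
print.insertion_hits <- function(x, ...) {
  cat(sprintf("%d insertion hit(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Per-position coverage and exchange rate of an organelle genome
#'
#' `depth[i]` is the number of hits whose organelle interval contains
#' position `i` (the copy number of that position); the exchange rate is the
#' percentage of organelle positions covered by at least one hit, reported to
#' 0.01 percent.
#'
#' @param hits `insertion_hits`, all referencing `organelle`.
#' @param organelle the organelle sequence (or its length as a single
#'   integer).
#' @return a `coverage_profile`: list with `organelle_id`, `depth` (integer
#'   vector, one entry per organelle position), `exchange_rate_pct`, `length`.
#' @export
coverage_profile <- function(hits, organelle) {
  if (is.numeric(organelle) && length(organelle) == 1L) {
    org_len <- as.integer(organelle); org_id <- "organelle"
  } else {
    org <- as_seq(organelle); org_len <- nchar(org$seq); org_id <- org$id
  }
  circular <- isTRUE(attr(hits, "circular"))
  delta <- integer(org_len + 1L)
  if (nrow(hits)) {
    if (any(hits$o_start < 0L) ||
        (!circular && any(hits$o_end > org_len)) ||
        (circular && any(hits$o_end > 2L * org_len)))
      stop("hit interval outside organelle length")
    for (i in seq_len(nrow(hits))) {
      s <- hits$o_start[i]; e <- hits$o_end[i]
      if (e <= org_len) {
        delta[s + 1L] <- delta[s + 1L] + 1L
        delta[e + 1L] <- delta[e + 1L] - 1L
      } else { # wrap-around hit on a circular genome
        delta[s + 1L] <- delta[s + 1L] + 1L
        delta[1L] <- delta[1L] + 1L
        wrap_end <- e - org_len
        delta[wrap_end + 1L] <- delta[wrap_end + 1L] - 1L
      }
    }
  }
  depth <- cumsum(delta[seq_len(org_len)])
  out <- list(organelle_id = org_id, depth = as.integer(depth),
              exchange_rate_pct = round(100 * mean(depth >= 1L), 2L),
              length = org_len)
  class(out) <- "coverage_profile"
  out
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage of %s (%d bp): exchange %.2f%%, max depth %d\n",
              x$organelle_id, x$length, x$exchange_rate_pct, max(x$depth)))
  invisible(x)
}

#' Size-class histogram of insertion hits
#'
#' Bins hit lengths into the standard size classes 50-99, 100-199, 200-299,
#' 300-399, 400-499, 500-999 and >= 1000 bp. Hits must already be filtered to
#' length at least 50.
#'
#' @param hits filtered `insertion_hits`.
#' @return named integer vector over the seven size-class labels.
#' @export
size_histogram <- function(hits) {
  if (nrow(hits) && any(hits$length < 50L))
    stop("hit with length < 50: filter contract violated")
  counts <- table(cut(hits$length, breaks = SIZE_BIN_EDGES,
                      labels = SIZE_BIN_LABELS, right = FALSE))
  out <- as.integer(counts)
  names(out) <- SIZE_BIN_LABELS
  out
}

# ---- report writers -------------------------------------------------------

#' Write insertion hits as TSV
#'
#' Columns: nuclear_id, n_start, n_end, organelle_id, o_start, o_end, strand,
#' length, identity_pct, class.
#' @param hits `insertion_hits`.
#' @param path output path.
#' @export
write_hits_tsv <- function(hits, path) {
  cols <- c("nuclear_id", "n_start", "n_end", "organelle_id", "o_start",
            "o_end", "strand", "length", "identity_pct", "class")
  df <- as.data.frame(hits)[, intersect(cols, names(hits)), drop = FALSE]
  df$identity_pct <- round(df$identity_pct, 2L)
  write_tsv(df, path)
}

#' Write insertion hits as 6-column BED on the nuclear genome
#'
#' Score is the identity percentage rounded to an integer (capped at 1000 by
#' the format, not reached here).
#' @param hits `insertion_hits`.
#' @param path output path.
#' @export
write_hits_bed <- function(hits, path) {
  name <- sprintf("%s_%d", if (nrow(hits)) hits$class else character(0),
                  seq_len(nrow(hits)))
  bed <- data.frame(chrom = hits$nuclear_id, start = hits$n_start,
                    end = hits$n_end, name = name,
                    score = round(hits$identity_pct),
                    strand = hits$strand, stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a coverage profile as 2-column TSV (position, depth)
#' @param profile a `coverage_profile`.
#' @param path output path.
#' @export
write_coverage_tsv <- function(profile, path) {
  write_tsv(data.frame(position = seq_along(profile$depth) - 1L,
                       depth = profile$depth), path)
}

#' Write a size histogram as TSV with the standard bin labels
#' @param histogram output of [size_histogram()].
#' @param path output path.
#' @export
write_histogram_tsv <- function(histogram, path) {
  write_tsv(data.frame(size_class = names(histogram),
                       count = as.integer(histogram)), path)
}
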