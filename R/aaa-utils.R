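# Internal helpers shared across modules.

NUC_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")
TAXON_GROUPS <- c("cyanobacteria", "other_bacteria", "reference_eukaryote", "query")
COMPARTMENTS <- c("nuclear", "plastid", "mitochondrial", "unknown")

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Reverse complement of a nucleotide string
#'
#' Vectorised over its input; `N` maps to `N`.
#'
#' @param seqs character vector of nucleotide sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(seqs) {
  vapply(seqs, revcomp, character(1), USE.NAMES = FALSE)
}

# Extract a single sequence string from a seq_set row, a named character, or a
# plain string. Returns list(id=, seq=).
as_seq <- function(x, arg = deparse(substitute(x))) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L)
      stop(sprintf("'%s' must be a single sequence record, got %d rows", arg, nrow(x)))
    return(list(id = x$id[[1L]], seq = x$seq[[1L]],
                kind = if ("kind" %in% names(x)) x$kind[[1L]] else NA_character_))
  }
  if (is.character(x) && length(x) == 1L) {
    id <- if (!is.null(names(x))) names(x) else arg
    return(list(id = id, seq = unname(x), kind = NA_character_))
  }
  if (is.list(x) && !is.null(x$seq) && !is.null(x$id))
    return(list(id = x$id, seq = x$seq, kind = x$kind %||% NA_character_))
  stop(sprintf("'%s' must be a one-row seq_set or a character string", arg))
}

validate_alphabet <- function(seq, kind, id) {
  alphabet <- if (kind == "nucleotide") NUC_ALPHABET else AA_ALPHABET
  chars <- strsplit(seq, "")[[1L]]
  bad <- which(!(chars %in% alphabet))
  if (length(bad))
    stop(sprintf("illegal character '%s' at position %d in sequence '%s' (%s alphabet)",
                 chars[bad[1L]], bad[1L], id, kind))
  invisible(TRUE)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
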