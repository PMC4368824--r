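# Group-level means and relative standard deviations of genome measures
# (genome length, protein and RNA gene counts, coding fraction) across
# phylogenetic groups and compartments.

GENOME_GROUPS <- c("Chlorophyta", "Nonvascular", "Ferns", "Gymnosperms",
                   "Angiosperms")
GENOME_MEASURES <- c("length_bp", "n_proteins", "n_rnas", "coding_fraction")

#' Relative standard deviation (percent)
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation. A constant
#' list gives 0; a single value gives 0 with a warning (sd undefined); a
#' zero mean is a hard error.
#'
#' @param values numeric vector with at least one element.
#' @return the RSD in percent.
#' @export
rsd <- function(values) {
  if (!length(values)) stop("rsd of an empty vector")
  m <- mean(values)
  if (m == 0) stop("rsd undefined for zero mean")
  if (length(values) == 1L) {
    warning("rsd of a single value reported as 0")
    return(0)
  }
  100 * sd(values) / m
}

#' Group-level genome statistics table
#'
#' Mean and relative standard deviation of each genome measure per
#' (phylogenetic group, compartment) cell. Cells without data are simply
#' absent, never imputed.
#'
#' @param measures data frame with columns `species`, `group` (one of
#'   Chlorophyta, Nonvascular, Ferns, Gymnosperms, Angiosperms),
#'   `compartment` (nuclear/plastid/mitochondrial) and the numeric measures
#'   `length_bp`, `n_proteins`, `n_rnas`, `coding_fraction`.
#' @return a `genome_group_table` data frame: one row per populated cell
#'   with `n_species` and `<measure>_mean` / `<measure>_rsd` columns.
#' @export
group_table <- function(measures) {
  needed <- c("species", "group", "compartment")
  if (!all(needed %in% names(measures)))
    stop("measures must have species, group and compartment columns")
  bad <- setdiff(unique(measures$group), GENOME_GROUPS)
  if (length(bad)) stop(sprintf("unknown group label '%s'", bad[1L]))
  present <- intersect(GENOME_MEASURES, names(measures))
  cells <- unique(measures[, c("group", "compartment")])
  cells <- cells[order(match(cells$group, GENOME_GROUPS), cells$compartment), ,
                 drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- measures$group == cells$group[i] &
      measures$compartment == cells$compartment[i]
    row <- data.frame(group = cells$group[i],
                      compartment = cells$compartment[i],
                      n_species = sum(sel), stringsAsFactors = FALSE)
    for (msr in present) {
      v <- measures[[msr]][sel]
      v <- v[!is.na(v)]
      if (!length(v)) {
        row[[paste0(msr, "_mean")]] <- NA_real_
        row[[paste0(msr, "_rsd")]] <- NA_real_
      } else {
        row[[paste0(msr, "_mean")]] <- mean(v)
        row[[paste0(msr, "_rsd")]] <-
          if (length(v) == 1L) suppressWarnings(rsd(v)) else rsd(v)
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("genome_group_table", "data.frame")
  out
}

#' Write the group statistics table as TSV
#'
#' The header records that the sample (n-1) standard deviation was used.
#' @param table a `genome_group_table`.
#' @param path output path.
#' @export
write_group_table_tsv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# rsd = 100 * sample sd (n-1) / mean", con)
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, 4L))
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
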