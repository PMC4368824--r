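# End-to-end orchestration: a plain-text (YAML) config with explicit input
# paths and thresholds drives every census stage and emits the paper-shaped
# outputs (hit tables, coverage, histograms, homology tables, origin calls,
# census summary, enrichment tables, treemap SVG, group statistics).

#' Validate a pipeline configuration
#'
#' @param config a list (or path of a YAML file) with input paths and
#'   thresholds. Required keys: `nuclear_fasta`, `plastid_fasta`,
#'   `proteome_fasta`, `reference_fasta`, `groups_tsv`, `out_dir`, `seed`.
#'   Optional: `mito_fasta`, `genes_fasta`, `ests_fasta`, `obo`, `gaf`,
#'   `slim_tsv`, `metadata_tsv`, and the thresholds `word_size`,
#'   `min_identity`, `min_length`, `max_join_gap`, `max_evalue`,
#'   `min_protein_identity`, `alpha`.
#' @return the validated config list with defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    base <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    # resolve relative paths against the config file location
    for (key in grep("_fasta$|_tsv$|^obo$|^gaf$", names(config), value = TRUE))
      if (!is.null(config[[key]]) && !grepl("^/", config[[key]]))
        config[[key]] <- file.path(base, config[[key]])
  }
  required <- c("nuclear_fasta", "plastid_fasta", "proteome_fasta",
                "reference_fasta", "groups_tsv", "out_dir", "seed")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop(sprintf("config is missing key(s): %s", paste(missing, collapse = ", ")))
  defaults <- list(word_size = 50L, min_identity = 80, min_length = 50L,
                   max_join_gap = 100L, max_evalue = 1e-10,
                   min_protein_identity = 25, alpha = 0.05,
                   max_family_size = 12L)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (config$word_size < 8L) stop("word_size must be >= 8")
  if (config$min_identity < 0 || config$min_identity > 100)
    stop("min_identity out of range")
  if (config$alpha <= 0 || config$alpha >= 1) stop("alpha out of range")
  paths <- grep("_fasta$|_tsv$|^obo$|^gaf$", names(config), value = TRUE)
  for (key in paths) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("config path '%s' does not exist: %s", key, p))
  }
  config
}

#' Run the full gene-transfer census
#'
#' Executes, in order: NUPT detection (nuclear vs plastid), NUMT detection
#' (nuclear vs chondriome, if given), the recruit screen of the query
#' proteome against the grouped reference proteomes, per-query gene-family
#' trees and origin classification, nuclear-versus-plastid homology, EST
#' expression qualification, the census summary, GO-Slim and full-GO
#' enrichment of the recruits, the Voronoi treemap, and group-level genome
#' statistics. One structured message per stage reports input/output row
#' counts. Re-running with an identical config reproduces identical outputs.
#'
#' @param config a config list or YAML path, see [pipeline_config()].
#' @return invisibly, the manifest data frame (file, bytes) also written to
#'   `manifest.tsv` in the output directory.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  emit <- function(file) outputs <<- c(outputs, file)
  set.seed(config$seed)

  # --- insertion census ----------------------------------------------------
  nuclear <- stage("read_inputs", read_fasta(config$nuclear_fasta, "nucleotide"))
  run_census <- function(organelle_path, class, prefix) {
    organelle <- read_fasta(organelle_path, "nucleotide")
    hits <- detect_insertions(nuclear, organelle[1L, ], class = class,
                              word_size = config$word_size,
                              max_join_gap = config$max_join_gap,
                              min_identity_pct = config$min_identity,
                              min_length = config$min_length)
    prof <- coverage_profile(hits, organelle[1L, ])
    message(sprintf("stage %s_census: %d contigs in, %d hits, exchange %.2f%%",
                    prefix, nrow(nuclear), nrow(hits), prof$exchange_rate_pct))
    emit(write_hits_tsv(hits, file.path(out_dir, paste0(prefix, "_hits.tsv"))))
    emit(write_hits_bed(hits, file.path(out_dir, paste0(prefix, "_hits.bed"))))
    emit(write_coverage_tsv(prof, file.path(out_dir, paste0(prefix, "_coverage.tsv"))))
    emit(write_histogram_tsv(size_histogram(hits),
                             file.path(out_dir, paste0(prefix, "_histogram.tsv"))))
    hits
  }
  stage("nupt_census", run_census(config$plastid_fasta, "NUPT", "nupt"))
  if (!is.null(config$mito_fasta))
    stage("numt_census", run_census(config$mito_fasta, "NUMT", "numt"))

  # --- recruit screen and origin classification ----------------------------
  proteome <- stage("read_inputs", read_fasta(config$proteome_fasta, "protein"))
  refs <- stage("read_inputs", read_fasta(config$reference_fasta, "protein"))
  groups_df <- read.delim(config$groups_tsv, stringsAsFactors = FALSE)
  groups <- stats::setNames(groups_df$taxon_group, groups_df$leaf_id)
  screen <- stage("recruit_screen",
                  search_homologs(proteome, refs, role = "recruit_screen",
                                  min_identity_pct = config$min_protein_identity,
                                  max_evalue = config$max_evalue))
  message(sprintf("stage recruit_screen: %d queries, %d filtered hits",
                  nrow(proteome), nrow(screen)))
  emit(write_homology_tsv(screen, file.path(out_dir, "recruit_screen.tsv")))

  calls <- stage("origin_classification", {
    per_query <- split(screen, screen$query)
    rows <- lapply(names(per_query), function(q) {
      subj <- utils::head(per_query[[q]]$subject, config$max_family_size)
      fam <- rbind(proteome[proteome$id == q, , drop = FALSE],
                   refs[refs$id %in% subj, , drop = FALSE])
      if (nrow(fam) < 3L)
        return(data.frame(gene_id = q, call = "ambiguous",
                          sister_cyano_fraction = NA_real_,
                          n_sister_leaves = 0L, tree_id = NA_character_,
                          stringsAsFactors = FALSE))
      tree <- nj_tree(protein_distance_matrix(fam))
      classify_origin(tree, q, groups, tree_id = q)
    })
    do.call(rbind, rows)
  })
  if (is.null(calls)) calls <- data.frame(gene_id = character(),
                                          call = character(),
                                          sister_cyano_fraction = numeric(),
                                          n_sister_leaves = integer(),
                                          tree_id = character())
  message(sprintf("stage origin_classification: %d genes classified, %d cyanobacterial",
                  nrow(calls), sum(calls$call == "cyanobacterial")))
  emit(write_tsv(calls, file.path(out_dir, "origin_calls.tsv")))

  # --- nuclear vs plastid proteins -----------------------------------------
  nvp <- NULL
  plastid_ids <- character()
  if (!is.null(config$plastid_proteome_fasta)) {
    plastid_prot <- read_fasta(config$plastid_proteome_fasta, "protein")
    plastid_ids <- plastid_prot$id
    nvp <- stage("nuclear_vs_plastid",
                 search_homologs(proteome, plastid_prot,
                                 role = "nuclear_vs_plastid",
                                 min_identity_pct = config$min_protein_identity,
                                 max_evalue = config$max_evalue))
    message(sprintf("stage nuclear_vs_plastid: %d pairs", nrow(nvp)))
    emit(write_homology_tsv(nvp, file.path(out_dir, "nuclear_vs_plastid.tsv")))
  }

  # --- expression ----------------------------------------------------------
  expression <- NULL
  if (!is.null(config$genes_fasta) && !is.null(config$ests_fasta)) {
    genes <- read_fasta(config$genes_fasta, "nucleotide")
    ests <- read_fasta(config$ests_fasta, "nucleotide")
    recruits <- calls$gene_id[calls$call == "cyanobacterial"]
    assess <- genes[genes$id %in% recruits, , drop = FALSE]
    expression <- stage("expression", stats::setNames(
      vapply(seq_len(nrow(assess)), function(i)
        est_expressed(assess[i, , drop = FALSE], ests,
                      max_evalue = config$max_evalue), logical(1)),
      assess$id))
    message(sprintf("stage expression: %d recruits assessed, %d expressed",
                    length(expression), sum(expression)))
    emit(write_tsv(data.frame(gene_id = names(expression),
                              expressed = unname(expression)),
                   file.path(out_dir, "expression.tsv")))
  }

  # --- census summary ------------------------------------------------------
  census <- stage("census_summary", build_census(
    calls,
    nvp %||% data.frame(query = character(), subject = character()),
    plastid_ids, expression))
  message(sprintf("stage census_summary: %d recruits, %d nuclear genes with plastid homolog",
                  census$n_cyano_recruits, census$n_nuclear_with_plastid_homolog))
  emit(write_tsv(as.data.frame(census), file.path(out_dir, "census_summary.tsv")))

  # --- GO enrichment and treemap -------------------------------------------
  if (!is.null(config$obo) && !is.null(config$gaf)) {
    slim_ids <- if (!is.null(config$slim_tsv))
      readLines(config$slim_tsv) else NULL
    onto <- stage("read_inputs",
                  suppressWarnings(read_ontology(config$obo, config$gaf,
                                                 slim_ids = slim_ids)))
    study <- intersect(calls$gene_id[calls$call == "cyanobacterial"],
                       names(onto$annotations))
    population <- names(onto$annotations)
    if (length(study)) {
      enr_full <- stage("enrichment",
                        go_enrich(study, population, onto$annotations,
                                  onto$graph, alpha = config$alpha))
      emit(write_enrichment_tsv(enr_full, file.path(out_dir, "enrichment_full.tsv")))
      use_slim <- length(onto$graph$slim) > 0L
      enr <- if (use_slim)
        stage("enrichment", go_enrich(study, population, onto$annotations,
                                      onto$graph, alpha = config$alpha,
                                      use_slim = TRUE)) else enr_full
      emit(write_enrichment_tsv(enr, file.path(out_dir, "enrichment_slim.tsv")))
      message(sprintf("stage enrichment: %d study genes, %d terms tested, %d significant",
                      length(study), nrow(enr), sum(enr$significant)))
      if (nrow(enr)) {
        cells <- stage("treemap", {
          terms <- data.frame(term = enr$term, parent = NA_character_,
                              weight = enr$k, stringsAsFactors = FALSE)
          lay <- layout_hierarchy(terms,
                                  layout_config(seed = config$seed))
          color_by_significance(lay, enr, alpha = config$alpha)
        })
        emit(treemap_svg(cells, file.path(out_dir, "treemap.svg")))
        emit(write_cells_tsv(cells, file.path(out_dir, "treemap_cells.tsv")))
        message(sprintf("stage treemap: %d cells", nrow(cells)))
      }
    }
  }

  # --- group statistics ----------------------------------------------------
  if (!is.null(config$metadata_tsv)) {
    meta <- read.delim(config$metadata_tsv, stringsAsFactors = FALSE)
    gt <- stage("group_stats", group_table(meta))
    message(sprintf("stage group_stats: %d cells", nrow(gt)))
    emit(write_group_table_tsv(gt, file.path(out_dir, "group_stats.tsv")))
  }

  manifest <- data.frame(file = basename(outputs),
                         bytes = file.size(outputs),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}
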