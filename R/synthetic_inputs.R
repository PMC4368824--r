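# Bundled synthetic study: writes a complete, self-consistent set of census
# inputs (genomes with implants, proteomes, gene trees' sequence families,
# ESTs, GO annotations, genome metadata) plus a ready-to-run YAML config.

#' Write a complete synthetic input bundle and pipeline config
#'
#' Generates every input [run_pipeline()] consumes, at desk scale, with
#' known ground truth, and writes `config.yaml` referencing them by
#' relative path. The detector word size in the emitted config is 12 (the
#' sensitivity setting, since the bundle plants diverged implants); all
#' other thresholds are the standard census defaults.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed controlling every generator.
#' @param n_families number of synthetic protein families.
#' @param n_implants implants per organelle genome.
#' @return the path of the written config file.
#' @export
make_synthetic_inputs <- function(dir, seed = 42L, n_families = 9L,
                                  n_implants = 20L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # genomes with implants (plastid and mitochondrial sources)
  gp <- gen_genome_with_implants(organelle_len = 20000L, nuclear_len = 200000L,
                                 n_implants = n_implants,
                                 length_range = c(60L, 1500L),
                                 identity_range = c(85, 100), seed = seed)
  gm <- gen_genome_with_implants(organelle_len = 15000L, nuclear_len = 200000L,
                                 n_implants = max(1L, n_implants %/% 2L),
                                 length_range = c(60L, 1000L),
                                 identity_range = c(85, 100), seed = seed + 1L)
  # one nuclear genome carrying both implant sets: NUPTs in the first half,
  # NUMTs in the second
  nuclear <- seq_set("nuc1", paste0(gp$nuclear$seq, gm$nuclear$seq),
                     compartment = "nuclear")
  write_fasta(nuclear, file.path(dir, "nuclear.fasta"))
  write_fasta(gp$organelle, file.path(dir, "plastid.fasta"))
  org_m <- gm$organelle; org_m$compartment <- "mitochondrial"
  write_fasta(org_m, file.path(dir, "chondriome.fasta"))
  write_tsv(gp$truth, file.path(dir, "nupt_truth.tsv"))
  write_tsv(gm$truth, file.path(dir, "numt_truth.tsv"))

  # protein families with known donors
  fams <- gen_families(n_families = n_families, seed = seed + 2L)
  queries <- do.call(rbind, lapply(fams$families, function(f)
    f$seqs[f$seqs$id == f$query, , drop = FALSE]))
  refs <- do.call(rbind, lapply(fams$families, function(f)
    f$seqs[f$seqs$id != f$query, , drop = FALSE]))
  class(queries) <- class(refs) <- c("seq_set", "data.frame")
  write_fasta(queries, file.path(dir, "proteome.fasta"))
  write_fasta(refs, file.path(dir, "references.fasta"))
  write_tsv(data.frame(leaf_id = names(fams$groups),
                       taxon_group = unname(fams$groups)),
            file.path(dir, "groups.tsv"))
  write_tsv(fams$truth[, c("family_id", "donor", "query_gene_id",
                           "expected_call")],
            file.path(dir, "family_truth.tsv"))
  # synthetic plastid-encoded proteome: cyanobacterial family members stand
  # in for plastid-encoded proteins
  cyano_first <- do.call(rbind, lapply(fams$families, function(f) {
    r <- f$seqs[f$seqs$taxon_group == "cyanobacteria", , drop = FALSE][1L, , drop = FALSE]
    r$id <- paste0("pp_", sub("_.*$", "", r$id))
    r
  }))
  class(cyano_first) <- c("seq_set", "data.frame")
  write_fasta(cyano_first, file.path(dir, "plastid_proteome.fasta"))

  # nucleotide gene models for the queries + EST library
  set.seed(seed + 3L)
  genes <- seq_set(queries$id,
                   vapply(seq_len(nrow(queries)), function(i) random_dna(1000L),
                          character(1)))
  write_fasta(genes, file.path(dir, "genes.fasta"))
  ests <- gen_ests(genes, expressed_frac = 0.8, seed = seed + 4L)
  write_fasta(ests$ests, file.path(dir, "ests.fasta"))
  write_tsv(data.frame(gene_id = names(ests$truth),
                       expressed = unname(ests$truth)),
            file.path(dir, "est_truth.tsv"))

  # GO annotations over the query genes plus background genes
  uni <- gen_go_universe(n_genes = 60L, n_terms = 25L, seed = seed + 5L)
  set.seed(seed + 6L)
  leaves <- setdiff(uni$graph$terms,
                    c(uni$graph$terms[1L], uni$graph$slim))
  all_genes <- c(queries$id, sprintf("bg%03d", seq_len(40L)))
  gaf_rows <- unlist(lapply(all_genes, function(g)
    sprintf("SYN\t%s\t%s\t\t%s\tREF:0\tIEA\t\tP\t\t\tgene\ttaxon:0000\t20150101\tSYN\t\t",
            g, g, sample(leaves, sample(1:3, 1L)))))
  writeLines(uni$obo, file.path(dir, "anno.obo"))
  writeLines(c("!gaf-version: 2.1", gaf_rows), file.path(dir, "anno.gaf"))
  writeLines(uni$graph$slim, file.path(dir, "slim.tsv"))

  # genome metadata for the group statistics stage
  set.seed(seed + 7L)
  groups <- rep(c("Chlorophyta", "Nonvascular", "Angiosperms"), each = 4L)
  meta <- data.frame(
    species = sprintf("species_%02d", seq_along(groups)),
    group = groups,
    compartment = "plastid",
    length_bp = round(runif(length(groups), 120000, 180000)),
    n_proteins = round(runif(length(groups), 70, 90)),
    n_rnas = round(runif(length(groups), 35, 50)),
    coding_fraction = round(runif(length(groups), 0.45, 0.65), 3L))
  write_tsv(meta, file.path(dir, "metadata.tsv"))

  config <- list(nuclear_fasta = "nuclear.fasta",
                 plastid_fasta = "plastid.fasta",
                 mito_fasta = "chondriome.fasta",
                 proteome_fasta = "proteome.fasta",
                 reference_fasta = "references.fasta",
                 plastid_proteome_fasta = "plastid_proteome.fasta",
                 groups_tsv = "groups.tsv",
                 genes_fasta = "genes.fasta",
                 ests_fasta = "ests.fasta",
                 obo = "anno.obo",
                 gaf = "anno.gaf",
                 slim_tsv = "slim.tsv",
                 metadata_tsv = "metadata.tsv",
                 word_size = 12L,
                 min_identity = 80,
                 min_length = 50L,
                 max_evalue = 1e-10,
                 min_protein_identity = 25,
                 alpha = 0.05,
                 seed = seed,
                 out_dir = file.path(dir, "results"))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  cfg_path
}
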