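# Pipeline orchestration: serialize a study to disk, load it back, run every
# stage in order (compare -> identify -> classify -> correlate -> tsi ->
# conserve), and write deterministic TSV/GTF outputs with a manifest.

#' Write a synthetic study to a directory
#'
#' Serialises every component as plain text: per-species reference and
#' assembled GTFs, expression TSVs, protein-homology and cross-species hit
#' tables (BLAST tabular), chromosome sizes, ortholog groups, and the truth
#' ledger.
#'
#' @param study A study from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "lnc_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in study$species) {
    write_gtf(study$reference[[sp]], file.path(dir, paste0("reference_", sp, ".gtf")))
    write_gtf(study$assembled[[sp]], file.path(dir, paste0("assembled_", sp, ".gtf")))
    write_expression(study$expression[[sp]],
                     file.path(dir, paste0("expression_", sp, ".tsv")))
    write_blast_tab(study$homology_hits[[sp]],
                    file.path(dir, paste0("homology_", sp, ".tsv")))
    cs <- study$chrom_sizes[[sp]]
    utils::write.table(data.frame(chrom = names(cs), length = unname(cs)),
                       file.path(dir, paste0("chrom_sizes_", sp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (key in names(study$cross_hits))
    write_blast_tab(study$cross_hits[[key]],
                    file.path(dir, paste0("cross_", key, ".tsv")))
  write_ortholog_groups(study$ortholog_groups, file.path(dir, "ortholog_groups.tsv"))
  utils::write.table(study$truth, file.path(dir, "truth_ledger.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(paste0("seed\t", study$config$seed),
               paste0("species\t", paste(study$species, collapse = ",")),
               paste0("tissues\t", paste(study$config$tissues, collapse = ",")),
               paste0("replicates\t", paste(study$config$replicates, collapse = ","))),
             file.path(dir, "study_config.tsv"))
  invisible(dir)
}

#' Read a serialized study directory
#'
#' @param dir Directory written by [write_study()].
#' @return A list with the same annotation/expression/hit components as a
#'   generated study (the truth ledger is read back when present).
#' @export
read_study <- function(dir) {
  cfg_lines <- strsplit(readLines(file.path(dir, "study_config.tsv")), "\t")
  cfg <- stats::setNames(lapply(cfg_lines, `[`, 2L),
                         vapply(cfg_lines, `[`, character(1), 1L))
  species <- strsplit(cfg$species, ",")[[1]]
  out <- list(species = species,
              reference = list(), assembled = list(), expression = list(),
              homology_hits = list(), cross_hits = list(), chrom_sizes = list())
  for (sp in species) {
    out$reference[[sp]] <- read_gtf(file.path(dir, paste0("reference_", sp, ".gtf")))
    out$assembled[[sp]] <- read_gtf(file.path(dir, paste0("assembled_", sp, ".gtf")))
    out$expression[[sp]] <- read_expression(file.path(dir, paste0("expression_", sp, ".tsv")))
    out$homology_hits[[sp]] <- read_blast_tab(file.path(dir, paste0("homology_", sp, ".tsv")))
    cs <- utils::read.table(file.path(dir, paste0("chrom_sizes_", sp, ".tsv")),
                            sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    out$chrom_sizes[[sp]] <- stats::setNames(cs$length, cs$chrom)
  }
  for (f in list.files(dir, pattern = "^cross_.*\\.tsv$")) {
    key <- sub("^cross_(.*)\\.tsv$", "\\1", f)
    out$cross_hits[[key]] <- read_blast_tab(file.path(dir, f))
  }
  out$ortholog_groups <- read_ortholog_groups(file.path(dir, "ortholog_groups.tsv"))
  truth_path <- file.path(dir, "truth_ledger.tsv")
  if (file.exists(truth_path))
    out$truth <- utils::read.table(truth_path, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
  out
}

#' Run the full lncRNA pipeline on a study
#'
#' Executes every stage in order for each species — class-code comparison,
#' the identification cascade, novelty categorization, positional
#' classification, expression correlation, tissue-specificity calling — and
#' the cross-species conservation stage, writing deterministic TSV/GTF
#' outputs and a manifest.
#'
#' @param study A study from [generate_study()] or [read_study()].
#' @param out_dir Output directory; created if needed.
#' @param window Pairing window in bases (default 50000).
#' @param min_length,evalue_homology Identification-cascade thresholds
#'   (defaults 200 bases, 0.001).
#' @param evalue_rbh Reciprocal-best-hit e-value cutoff (default 1e-5).
#' @param tsi_threshold Tissue-specificity threshold on tau (default 0.9).
#' @return A list with per-species results (`class_codes`, `filter_report`,
#'   `lncrnas`, `novelty`, `pairs`, `category_table`, `distal_fraction`,
#'   `correlation`, `tsi`), conservation results (`conservation`,
#'   `conserved_groups`, `rbh`), and a `manifest` data.frame (file, rows,
#'   md5) for every written output.
#' @export
run_pipeline <- function(study, out_dir, window = 50000, min_length = 200,
                         evalue_homology = 0.001, evalue_rbh = 1e-5,
                         tsi_threshold = 0.9) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  species <- study$species
  for (sp in species) {
    for (comp in c("reference", "assembled", "expression"))
      if (is.null(study[[comp]][[sp]]))
        stop("stage input missing: ", comp, " for species ", sp)
  }
  res <- list(species = list())
  pairs_by_species <- list()
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
  }

  for (sp in species) {
    ref <- study$reference[[sp]]
    coding_ids <- ref$transcripts$transcript_id[ref$transcripts$biotype == "protein_coding"]
    coding_ref <- subset_transcripts(ref, coding_ids)
    asm <- study$assembled[[sp]]
    expr <- study$expression[[sp]]

    codes <- assign_class_codes(asm, coding_ref)
    emit(codes, paste0("class_codes_", sp, ".tsv"))

    fl <- run_filter_cascade(asm, coding_ref, study$homology_hits[[sp]],
                             min_length = min_length,
                             evalue_cutoff = evalue_homology,
                             class_codes = codes)
    if (is.null(fl$lncrnas))
      stop("identification stage removed every transcript for ", sp)
    rep_df <- data.frame(stage = c("input", names(fl$report$removed_by_stage),
                                   "surviving"),
                         count = c(fl$report$input_count,
                                   unname(fl$report$removed_by_stage),
                                   length(fl$report$surviving_ids)))
    emit(rep_df, paste0("filter_report_", sp, ".tsv"))
    gtf_path <- file.path(out_dir, paste0("lncrnas_", sp, ".gtf"))
    write_gtf(fl$lncrnas, gtf_path)
    written <- c(written, gtf_path)

    novelty <- categorize_novelty(fl$lncrnas, ref)
    emit(novelty, paste0("novelty_", sp, ".tsv"))

    pairs <- pair_nearest_genes(fl$lncrnas, coding_ref, window = window)
    pairs <- classify_positions(pairs, fl$lncrnas, coding_ref)
    emit(pairs, paste0("pairs_", sp, ".tsv"))
    cat_tab <- tabulate_categories(pairs)
    emit(cat_tab, paste0("position_categories_", sp, ".tsv"))
    distal_frac <- if (!is.null(study$chrom_sizes[[sp]]))
      distal_genome_fraction(coding_ref, study$chrom_sizes[[sp]], window = window)
    else NA_real_

    corr <- correlation_by_group(pairs, expr, coding_ref)
    emit(corr$by_group, paste0("correlation_groups_", sp, ".tsv"))
    corr_dist <- correlation_by_distance(corr$pair_rho)
    emit(corr_dist, paste0("correlation_distance_", sp, ".tsv"))

    tsi <- call_tissue_specific(expr, threshold = tsi_threshold,
                                transcripts = fl$report$surviving_ids)
    emit(tsi, paste0("tsi_", sp, ".tsv"))
    curve <- expression_cutoff_curve(tsi, expr)
    emit(curve, paste0("tsi_cutoff_curve_", sp, ".tsv"))
    gene_frac <- specific_gene_fraction(tsi, pairs, expr, coding_ref,
                                        threshold = tsi_threshold)
    emit(gene_frac, paste0("tsi_gene_fraction_", sp, ".tsv"))

    pairs_by_species[[sp]] <- pairs
    res$species[[sp]] <- list(
      class_codes = codes, filter_report = fl$report, lncrnas = fl$lncrnas,
      novelty = novelty, pairs = pairs, category_table = cat_tab,
      distal_fraction = distal_frac, correlation = corr,
      correlation_by_distance = corr_dist, tsi = tsi,
      cutoff_curve = curve, specific_gene_fraction = gene_frac)
  }

  cons <- positional_conservation(pairs_by_species, study$ortholog_groups,
                                  species = species)
  cons_df <- data.frame(species = rownames(cons$counts), cons$counts,
                        check.names = FALSE)
  emit(cons_df, "conservation_counts.tsv")
  groups_all <- conserved_groups_all_species(pairs_by_species,
                                             study$ortholog_groups,
                                             species = species)
  emit(groups_all, "conserved_groups.tsv")

  rbh <- list()
  for (key in names(study$cross_hits)) {
    ab <- strsplit(key, "__", fixed = TRUE)[[1]]
    back_key <- paste(ab[2L], ab[1L], sep = "__")
    if (ab[1L] < ab[2L] && !is.null(study$cross_hits[[back_key]])) {
      rbh[[key]] <- reciprocal_best_hits(study$cross_hits[[key]],
                                         study$cross_hits[[back_key]],
                                         evalue_cutoff = evalue_rbh)
      emit(rbh[[key]], paste0("rbh_", key, ".tsv"))
    }
  }

  res$conservation <- cons
  res$conserved_groups <- groups_all
  res$rbh <- rbh
  manifest <- data.frame(
    file = basename(written),
    rows = vapply(written, function(f) length(readLines(f)) - 1L, integer(1)),
    md5 = unname(tools::md5sum(written)),
    stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res$manifest <- manifest
  res
}

#' Generate a packaged fixture study on disk
#'
#' Wraps [generate_study()] + [write_study()] with two presets: `"small"`
#' (reduced planted counts; completes in seconds) and `"default"`.
#'
#' @param seed Master seed.
#' @param scale `"small"` or `"default"`.
#' @param dir Output directory.
#' @return The generated study, invisibly; files are written under `dir`.
#' @export
make_fixtures <- function(seed, scale = c("small", "default"), dir) {
  scale <- match.arg(scale)
  config <- if (scale == "small")
    simulation_config(seed = seed, n_coding_genes = 40,
                      planted = list(conserved_groups = 3,
                                     intergenic_per_category = 3,
                                     genic_per_category = 2,
                                     distal = 3, eq = 3, mono = 3, short = 2,
                                     strong_homology = 2, weak_homology = 2,
                                     annotated_lnc = 3, novel_isoform = 2,
                                     specific_per_tissue = 1))
  else simulation_config(seed = seed)
  study <- generate_study(config)
  write_study(study, dir)
  invisible(study)
}
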