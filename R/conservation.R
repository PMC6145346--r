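# Cross-species lncRNA conservation.
#
# Sequence route: reciprocal best hits (RBH) between two species' lncRNA
# sets — a pair is orthologous when each member is the other's best-scoring
# cross-species hit (minimal e-value; ties by maximal bitscore, then
# lexicographic subject id) and both e-values pass the cutoff.
#
# Positional (synteny) route: a lncRNA of species A, paired to gene g, is
# conserved in species B when g's ortholog group contains a gene of B that
# is itself paired to some lncRNA of B.

# best hit per query id from one hit table
.best_hits <- function(hits, evalue_cutoff) {
  h <- hits[hits$evalue < evalue_cutoff, , drop = FALSE]
  if (nrow(h) == 0L)
    return(stats::setNames(character(0), character(0)))
  h <- h[order(h$qseqid, h$evalue, -h$bitscore, h$sseqid), , drop = FALSE]
  best <- h[!duplicated(h$qseqid), , drop = FALSE]
  stats::setNames(best$sseqid, best$qseqid)
}

#' Reciprocal best hits between two species
#'
#' @param hits_ab BLAST tabular hits of species A queries vs species B
#'   subjects (see [read_blast_tab()]).
#' @param hits_ba Hits in the opposite direction.
#' @param evalue_cutoff Both best hits must have `evalue <` this value;
#'   default 1e-5.
#' @return data.frame `id_a`, `id_b`: the reciprocal-best-hit pairs, sorted
#'   by `id_a`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, evalue_cutoff = 1e-5) {
  ab <- .best_hits(hits_ab, evalue_cutoff)
  ba <- .best_hits(hits_ba, evalue_cutoff)
  keep <- names(ab)[!is.na(ba[ab]) & ba[ab] == names(ab)]
  out <- data.frame(id_a = keep, id_b = unname(ab[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$id_a), , drop = FALSE]
}

# index: per species, gene_id -> group_id(s); and group -> species -> genes
.group_index <- function(groups) {
  key <- paste(groups$species, groups$gene_id, sep = "\r")
  gene2group <- split(groups$group_id, key)
  by_group <- split(groups, groups$group_id)
  list(gene2group = gene2group, by_group = by_group)
}

#' Positional conservation matrix across species
#'
#' Builds the species-by-species conservation matrix: off-diagonal cell
#' (A, B) counts A's lncRNAs conserved in B (paired gene's ortholog group
#' holds a B gene that is itself paired to a B lncRNA); the diagonal (A, A)
#' counts A's lncRNAs whose paired gene's group is complete (has a gene in
#' every other species) — the lncRNAs entering the conservation analysis.
#'
#' @param pairs_by_species Named list (species -> classified pairs data.frame
#'   with `lncrna_id`, `gene_id`); distal-excluded rows (`NA` gene) are
#'   dropped internally.
#' @param groups Ortholog-group table (`group_id`, `species`, `gene_id`).
#' @param species Character vector of the species analysed; default the
#'   names of `pairs_by_species`.
#' @return list with `counts` (species x species matrix), `percent`
#'   (off-diagonal cells as a percentage of the row diagonal), and
#'   `n_unevaluable` (per species, lncRNAs whose paired gene is in no
#'   group).
#' @export
positional_conservation <- function(pairs_by_species, groups,
                                    species = names(pairs_by_species)) {
  # mirror the study design: only groups with >= 1 gene in every species
  # enter the analysis
  sp_per_group <- lapply(split(groups$species, groups$group_id), unique)
  complete_ids <- names(sp_per_group)[vapply(sp_per_group, function(s)
    all(species %in% s), logical(1))]
  groups <- groups[groups$group_id %in% complete_ids, , drop = FALSE]
  idx <- .group_index(groups)
  # per species: paired (lncrna, gene); genes with >= 1 paired lncRNA
  paired <- lapply(pairs_by_species, function(p)
    p[!is.na(p$gene_id), c("lncrna_id", "gene_id"), drop = FALSE])
  genes_with_lnc <- lapply(paired, function(p) unique(p$gene_id))

  n <- length(species)
  counts <- matrix(0L, n, n, dimnames = list(species, species))
  unevaluable <- stats::setNames(integer(n), species)
  for (a in species) {
    pa <- paired[[a]]
    for (i in seq_len(nrow(pa))) {
      grp_ids <- idx$gene2group[[paste(a, pa$gene_id[i], sep = "\r")]]
      if (is.null(grp_ids)) {
        unevaluable[[a]] <- unevaluable[[a]] + 1L
        next
      }
      members <- do.call(rbind, idx$by_group[grp_ids])
      # diagonal: group complete across all declared species
      if (all(species %in% members$species))
        counts[a, a] <- counts[a, a] + 1L
      for (b in setdiff(species, a)) {
        genes_b <- members$gene_id[members$species == b]
        if (any(genes_b %in% genes_with_lnc[[b]]))
          counts[a, b] <- counts[a, b] + 1L
      }
    }
  }
  percent <- matrix(NA_real_, n, n, dimnames = list(species, species))
  for (a in species) {
    denom <- counts[a, a]
    for (b in species)
      percent[a, b] <- if (denom > 0) 100 * counts[a, b] / denom else NA_real_
  }
  diag(percent) <- 100
  list(counts = counts, percent = percent, n_unevaluable = unevaluable)
}

#' Ortholog groups with a paired lncRNA in every species
#'
#' @inheritParams positional_conservation
#' @return data.frame `group_id`, `species`, `gene_id`, `lncrna_id`: one row
#'   per (group, species, lncRNA) for every group in which all species
#'   contribute at least one paired lncRNA; empty when none qualify.
#' @export
conserved_groups_all_species <- function(pairs_by_species, groups,
                                         species = names(pairs_by_species)) {
  paired <- lapply(pairs_by_species, function(p)
    p[!is.na(p$gene_id), c("lncrna_id", "gene_id"), drop = FALSE])
  out <- list()
  for (gid in sort(unique(groups$group_id))) {
    members <- groups[groups$group_id == gid, , drop = FALSE]
    rows <- list()
    complete <- TRUE
    for (sp in species) {
      genes_sp <- members$gene_id[members$species == sp]
      psp <- paired[[sp]]
      hit <- psp[psp$gene_id %in% genes_sp, , drop = FALSE]
      if (nrow(hit) == 0L) { complete <- FALSE; break }
      rows[[sp]] <- data.frame(group_id = gid, species = sp,
                               gene_id = hit$gene_id,
                               lncrna_id = hit$lncrna_id,
                               stringsAsFactors = FALSE)
    }
    if (complete) out[[gid]] <- do.call(rbind, rows)
  }
  if (length(out) == 0L)
    return(data.frame(group_id = character(0), species = character(0),
                      gene_id = character(0), lncrna_id = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
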