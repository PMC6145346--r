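# Positional classification of lncRNAs relative to their nearest
# protein-coding gene within a 50 kb window. Distances are gaps between
# transcribed regions (gene span = union span over the gene's transcripts);
# overlapping spans have distance 0 and are "genic".
#
# Category universe (16 named categories + the excluded and unclassified rows):
#   {Sense, Antisense} x {Intergenic Upstream, Intergenic Downstream,
#                         Containing Exonic, Overlapping Exonic, Nested Exonic,
#                         Containing Intronic, Overlapping Intronic,
#                         Nested Intronic}
#   plus "Intergenic, No Gene Within Window" (distal-excluded)
#   plus "Unclassified Strand" (unstranded lncRNAs).

POSITION_CATEGORIES <- c(
  as.vector(outer(c("Sense", "Antisense"),
                  c("Intergenic Upstream", "Intergenic Downstream",
                    "Containing Exonic", "Overlapping Exonic", "Nested Exonic",
                    "Containing Intronic", "Overlapping Intronic",
                    "Nested Intronic"),
                  paste)),
  "Intergenic, No Gene Within Window",
  "Unclassified Strand")

# gene-level table: one row per gene with union span; exon table retained
.gene_spans <- function(genes) {
  tx <- genes$transcripts
  sp <- split(seq_len(nrow(tx)), tx$gene_id)
  data.frame(
    gene_id = names(sp),
    chrom = vapply(sp, function(i) tx$chrom[i][1L], character(1)),
    strand = vapply(sp, function(i) tx$strand[i][1L], character(1)),
    start = vapply(sp, function(i) min(tx$start[i]), numeric(1)),
    end = vapply(sp, function(i) max(tx$end[i]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Pair lncRNAs with their nearest protein-coding gene
#'
#' For each lncRNA, finds the protein-coding gene with the smallest gap
#' between transcribed regions (the union span of the gene's transcripts and
#' the lncRNA's span; gap 0 when they overlap). LncRNAs with no gene within
#' `window` bases are marked distal-excluded. Ties are broken by smaller
#' distance, then lexicographically smaller `gene_id`.
#'
#' @param lncrnas An [annotation_set()] of lncRNAs.
#' @param genes An [annotation_set()] of protein-coding transcripts.
#' @param window Maximum gap in bases; default 50000.
#' @return data.frame with one row per lncRNA: `lncrna_id`, `gene_id` (`NA`
#'   when excluded), `distance` (`NA` when excluded).
#' @export
pair_nearest_genes <- function(lncrnas, genes, window = 50000) {
  ltx <- lncrnas$transcripts
  g <- .gene_spans(genes)
  lnc_gr <- GenomicRanges::GRanges(
    ltx$chrom, IRanges::IRanges(ltx$start + 1L, ltx$end))
  # expand gene spans by window + 1 so a single overlap query finds every
  # candidate with gap <= window (a gap of exactly `window` leaves the
  # expanded range merely adjacent, which findOverlaps would miss)
  gene_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(pmax(g$start - window - 1, 0) + 1L,
                              g$end + window + 1))
  hits <- GenomicRanges::findOverlaps(lnc_gr, gene_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  gap <- .span_gap(ltx$start[qh], ltx$end[qh], g$start[sh], g$end[sh])
  keep <- gap <= window
  qh <- qh[keep]; sh <- sh[keep]; gap <- gap[keep]
  ord <- order(qh, gap, g$gene_id[sh])
  qh <- qh[ord]; sh <- sh[ord]; gap <- gap[ord]
  first <- !duplicated(qh)
  best_gene <- rep(NA_character_, nrow(ltx))
  best_gap <- rep(NA_real_, nrow(ltx))
  best_gene[qh[first]] <- g$gene_id[sh[first]]
  best_gap[qh[first]] <- gap[first]
  data.frame(lncrna_id = ltx$transcript_id, gene_id = best_gene,
             distance = best_gap, stringsAsFactors = FALSE)
}

# classify one (lncRNA, gene) pair; both as rows/structures
.classify_one <- function(lnc_row, lnc_exons, gene_row, gene_exons) {
  if (lnc_row$strand == ".")
    return(list(category = "Unclassified Strand", orientation = "unclassified",
                location = "unclassified", subtype = "none"))
  orientation <- if (lnc_row$strand == gene_row$strand) "Sense" else "Antisense"
  span_overlap <- lnc_row$start < gene_row$end && gene_row$start < lnc_row$end
  if (span_overlap) {
    exonic <- any(vapply(seq_len(nrow(lnc_exons)), function(i) {
      any(lnc_exons$start[i] < gene_exons$end &
            gene_exons$start < lnc_exons$end[i])
    }, logical(1)))
    loc <- if (exonic) "Exonic" else "Intronic"
    subtype <- if (lnc_row$start >= gene_row$start && lnc_row$end <= gene_row$end)
      "Nested"
    else if (gene_row$start >= lnc_row$start && gene_row$end <= lnc_row$end)
      "Containing"
    else "Overlapping"
    list(category = paste(orientation, subtype, loc),
         orientation = tolower(orientation),
         location = paste0("genic_", tolower(loc)),
         subtype = tolower(subtype))
  } else {
    # upstream/downstream relative to the gene's transcriptional direction
    lnc_is_left <- lnc_row$end <= gene_row$start
    upstream <- if (gene_row$strand == "-") !lnc_is_left else lnc_is_left
    side <- if (upstream) "Upstream" else "Downstream"
    list(category = paste(orientation, "Intergenic", side),
         orientation = tolower(orientation),
         location = paste0("intergenic_", tolower(side)),
         subtype = "none")
  }
}

#' Classify lncRNA-gene pairs into positional categories
#'
#' Completes the pairs from [pair_nearest_genes()] with orientation (sense /
#' antisense by strand), genic vs intergenic location, exonic vs intronic
#' overlap (exonic requires >= 1 bp of lncRNA-exon / gene-exon overlap), the
#' containment subtype (nested = lncRNA inside the gene span, containing =
#' gene inside the lncRNA span, overlapping = partial), and upstream /
#' downstream for intergenic pairs judged from the gene's transcriptional
#' direction.
#'
#' @param pairs data.frame from [pair_nearest_genes()].
#' @param lncrnas,genes The annotation sets the pairs were built from.
#' @return `pairs` with added columns `orientation`, `location`, `subtype`,
#'   `category` (one of `POSITION_CATEGORIES`).
#' @export
classify_positions <- function(pairs, lncrnas, genes) {
  ltx <- lncrnas$transcripts
  g <- .gene_spans(genes)
  gene_ex <- genes$exons
  out <- pairs
  out$orientation <- NA_character_
  out$location <- NA_character_
  out$subtype <- NA_character_
  out$category <- NA_character_
  for (i in seq_len(nrow(pairs))) {
    if (is.na(pairs$gene_id[i])) {
      out$category[i] <- "Intergenic, No Gene Within Window"
      out$orientation[i] <- "none"
      out$location[i] <- "distal_excluded"
      out$subtype[i] <- "none"
      next
    }
    li <- match(pairs$lncrna_id[i], ltx$transcript_id)
    gi <- match(pairs$gene_id[i], g$gene_id)
    cls <- .classify_one(
      ltx[li, , drop = FALSE],
      lncrnas$exons[lncrnas$exons$transcript_id == pairs$lncrna_id[i], ,
                    drop = FALSE],
      g[gi, , drop = FALSE],
      gene_ex[gene_ex$gene_id == pairs$gene_id[i], , drop = FALSE])
    out$orientation[i] <- cls$orientation
    out$location[i] <- cls$location
    out$subtype[i] <- cls$subtype
    out$category[i] <- cls$category
  }
  out
}

#' Tabulate positional categories
#' @param pairs Classified pairs from [classify_positions()].
#' @return data.frame `category`, `count` over the full category universe
#'   (16 named categories, the distal-excluded row and the
#'   unclassified-strand row); counts sum to the number of lncRNAs.
#' @export
tabulate_categories <- function(pairs) {
  tab <- table(factor(pairs$category, levels = POSITION_CATEGORIES))
  data.frame(category = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Fraction of the genome farther than a window from every gene
#'
#' Computes, by merged-interval arithmetic, the fraction of genome positions
#' whose distance to every protein-coding gene span exceeds the window —
#' the part of the genome where a lncRNA would be distal-excluded.
#'
#' @param genes An [annotation_set()] of protein-coding transcripts.
#' @param chrom_sizes Named numeric vector: chromosome name -> length in
#'   bases; must cover every chromosome with a gene.
#' @param window Window in bases; default 50000.
#' @return Fraction in `[0, 1]`.
#' @export
distal_genome_fraction <- function(genes, chrom_sizes, window = 50000) {
  total <- sum(chrom_sizes)
  if (is.null(genes) || nrow(genes$transcripts) == 0L) return(1.0)
  g <- .gene_spans(genes)
  missing_chr <- setdiff(g$chrom, names(chrom_sizes))
  if (length(missing_chr) > 0L)
    stop("chrom_sizes lacks chromosome(s): ", paste(missing_chr, collapse = ", "))
  if (any(g$end > chrom_sizes[g$chrom]))
    stop("gene span beyond chromosome end")
  covered <- 0
  for (chr in unique(g$chrom)) {
    gi <- g[g$chrom == chr, , drop = FALSE]
    s <- pmax(gi$start - window, 0)
    e <- pmin(gi$end + window, chrom_sizes[[chr]])
    ir <- IRanges::reduce(IRanges::IRanges(start = s + 1L, end = e))
    covered <- covered + sum(IRanges::width(ir))
  }
  (total - covered) / total
}
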