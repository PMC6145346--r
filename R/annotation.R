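#' @importFrom stats cor rlnorm rnorm runif setNames aggregate
#' @importFrom utils read.table write.table head tail
NULL

# Internal coordinates are 0-based half-open throughout; GTF I/O converts at
# the boundary. Strand is one of "+", "-", "." (unstranded).

VALID_STRANDS <- c("+", "-", ".")

#' Construct an annotation set from an exon table
#'
#' An `AnnotationSet` is the package's container for a transcriptome: a table
#' of exons (0-based half-open coordinates) plus a derived per-transcript
#' summary table. It underlies every pipeline stage, from class-code
#' assignment to positional classification.
#'
#' @param exons data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `transcript_id` and optionally `biotype` (per transcript;
#'   one of `"protein_coding"`, `"lncRNA"`, `"other"`). Coordinates are
#'   0-based half-open; `start < end` is required for every exon.
#' @return An object of class `AnnotationSet` with components `exons`
#'   (normalised exon table, sorted by chrom, transcript, start) and
#'   `transcripts` (one row per transcript: span, exon count, spliced
#'   length, biotype).
#' @details Transcripts whose exons span several chromosomes or strands, or
#'   whose exons overlap each other, are rejected: the pipeline assumes
#'   well-formed assemblies and refuses to guess.
#' @export
annotation_set <- function(exons) {
  need <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id")
  miss <- setdiff(need, names(exons))
  if (length(miss) > 0L)
    stop("exon table lacks column(s): ", paste(miss, collapse = ", "))
  exons$chrom <- as.character(exons$chrom)
  exons$strand <- as.character(exons$strand)
  exons$gene_id <- as.character(exons$gene_id)
  exons$transcript_id <- as.character(exons$transcript_id)
  exons$start <- as.numeric(exons$start)
  exons$end <- as.numeric(exons$end)
  if (!"biotype" %in% names(exons)) exons$biotype <- "other"
  if (any(!exons$strand %in% VALID_STRANDS))
    stop("invalid strand value; must be one of +, -, .")
  if (any(exons$end <= exons$start))
    stop("empty or inverted exon interval (end <= start)")
  if (nrow(exons) == 0L)
    stop("empty exon table")

  ord <- order(exons$transcript_id, exons$start)
  exons <- exons[ord, , drop = FALSE]
  rownames(exons) <- NULL

  idx <- split(seq_len(nrow(exons)), exons$transcript_id)
  first <- vapply(idx, `[`, integer(1), 1L)
  # per-transcript consistency
  for (nm in c("chrom", "strand", "gene_id", "biotype")) {
    n_distinct <- vapply(idx, function(i) length(unique(exons[[nm]][i])), integer(1))
    if (any(n_distinct > 1L))
      stop("transcript(s) with inconsistent ", nm, ": ",
           paste(names(idx)[n_distinct > 1L], collapse = ", "))
  }
  overlapping <- vapply(idx, function(i) {
    if (length(i) < 2L) return(FALSE)
    any(exons$start[i][-1L] < exons$end[i][-length(i)])
  }, logical(1))
  if (any(overlapping))
    stop("transcript(s) with overlapping exons: ",
         paste(names(idx)[overlapping], collapse = ", "))

  tx <- data.frame(
    transcript_id = names(idx),
    gene_id = exons$gene_id[first],
    chrom = exons$chrom[first],
    strand = exons$strand[first],
    start = vapply(idx, function(i) min(exons$start[i]), numeric(1)),
    end = vapply(idx, function(i) max(exons$end[i]), numeric(1)),
    n_exons = lengths(idx),
    spliced_length = vapply(idx, function(i) sum(exons$end[i] - exons$start[i]),
                            numeric(1)),
    biotype = exons$biotype[first],
    stringsAsFactors = FALSE
  )
  tx <- tx[order(tx$chrom, tx$start, tx$transcript_id), , drop = FALSE]
  rownames(tx) <- NULL
  structure(list(exons = exons, transcripts = tx), class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  tx <- x$transcripts
  cat(sprintf("AnnotationSet: %d transcripts / %d genes / %d exons on %d chromosome(s)\n",
              nrow(tx), length(unique(tx$gene_id)), nrow(x$exons),
              length(unique(tx$chrom))))
  bt <- table(tx$biotype)
  cat("  biotypes:", paste(sprintf("%s=%d", names(bt), bt), collapse = ", "), "\n")
  invisible(x)
}

#' Per-transcript summary table of an annotation set
#' @param annotation An `AnnotationSet`.
#' @return data.frame with one row per transcript.
#' @export
transcript_table <- function(annotation) {
  stopifnot(inherits(annotation, "AnnotationSet"))
  annotation$transcripts
}

#' Exons of one transcript
#' @param annotation An `AnnotationSet`.
#' @param transcript_id Transcript identifier.
#' @return data.frame of exon intervals sorted by start.
#' @export
transcript_exons <- function(annotation, transcript_id) {
  ex <- annotation$exons
  out <- ex[ex$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(out) == 0L) stop("unknown transcript: ", transcript_id)
  out
}

#' Keep a subset of transcripts
#' @param annotation An `AnnotationSet`.
#' @param transcript_ids Character vector of transcript identifiers to keep.
#' @return A new `AnnotationSet` restricted to the given transcripts.
#' @export
subset_transcripts <- function(annotation, transcript_ids) {
  ex <- annotation$exons
  keep <- ex$transcript_id %in% transcript_ids
  if (!any(keep)) stop("no transcripts left after subsetting")
  annotation_set(ex[keep, , drop = FALSE])
}

#' Intron chain of a transcript
#'
#' Returns the ordered gaps between consecutive exons. Intron-chain identity
#' is the criterion for a complete match ("=" class code); mono-exonic
#' transcripts have an empty chain.
#'
#' @param annotation An `AnnotationSet`.
#' @param transcript_id Transcript identifier.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`, one row
#'   per intron (0-based half-open), empty for mono-exonic transcripts.
#' @export
intron_chain <- function(annotation, transcript_id) {
  ex <- transcript_exons(annotation, transcript_id)
  n <- nrow(ex)
  if (n < 2L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0)))
  data.frame(chrom = ex$chrom[1L],
             start = ex$end[-n],
             end = ex$start[-1L],
             strand = ex$strand[1L],
             stringsAsFactors = FALSE)
}

# ---- internal indexes -------------------------------------------------------

# junction key: one string per intron; chain key: the full ordered chain.
# Strand is deliberately excluded from the key; strand comparisons are done
# explicitly by the callers so that unstranded features can be handled.
.junction_keys <- function(exons_tx) {
  n <- nrow(exons_tx)
  if (n < 2L) return(character(0))
  paste0(exons_tx$chrom[1L], ":", exons_tx$end[-n], "-", exons_tx$start[-1L])
}

.chain_key <- function(exons_tx) {
  jk <- .junction_keys(exons_tx)
  if (length(jk) == 0L) return(NA_character_)
  paste(jk, collapse = "|")
}

# per-transcript cached structural index used by the classifier modules
.tx_index <- function(annotation) {
  ex <- annotation$exons
  tx <- annotation$transcripts
  idx <- split(seq_len(nrow(ex)), ex$transcript_id)
  idx <- idx[tx$transcript_id]
  junctions <- lapply(idx, function(i) .junction_keys(ex[i, , drop = FALSE]))
  chains <- vapply(idx, function(i) .chain_key(ex[i, , drop = FALSE]),
                   character(1))
  list(tx = tx, exon_rows = idx, exons = ex,
       junctions = junctions, chains = chains)
}

# GRanges over transcript spans (1-based inclusive for IRanges)
.span_granges <- function(tx) {
  GenomicRanges::GRanges(
    seqnames = tx$chrom,
    ranges = IRanges::IRanges(start = tx$start + 1L, end = tx$end),
    strand = ifelse(tx$strand == ".", "*", tx$strand)
  )
}

# GRanges over exons
.exon_granges <- function(ex) {
  GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ifelse(ex$strand == ".", "*", ex$strand)
  )
}

# gap in bases between two 0-based half-open intervals on one chromosome;
# 0 when they overlap or touch
.span_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s2 - e1, s1 - e2))
}
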