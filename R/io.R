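# GTF, expression-table, BLAST-tabular and ortholog-group I/O.
#
# GTF is 9 tab-separated columns with 1-based inclusive coordinates. Two
# attribute dialects are accepted in column 9: the Cufflinks/Ensembl
# `key "value"; key "value";` form and the NCBI-style `key=value;` form
# (with or without spaces around `=`).

.parse_gtf_attributes <- function(attr) {
  # returns a named character vector per attribute string
  lapply(attr, function(a) {
    a <- sub("\\s*;\\s*$", "", a)
    parts <- strsplit(a, ";", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    keys <- character(length(parts))
    vals <- character(length(parts))
    for (i in seq_along(parts)) {
      p <- parts[i]
      if (grepl("^\\S+\\s+\"", p)) {           # key "value"
        keys[i] <- sub("^(\\S+)\\s+.*$", "\\1", p)
        vals[i] <- sub("^\\S+\\s+\"(.*)\"$", "\\1", p)
      } else if (grepl("=", p, fixed = TRUE)) {  # key=value / key = value
        keys[i] <- trimws(sub("=.*$", "", p))
        vals[i] <- gsub("^\"|\"$", "", trimws(sub("^[^=]*=", "", p)))
      } else {                                   # bare key value
        keys[i] <- sub("^(\\S+)\\s.*$", "\\1", p)
        vals[i] <- sub("^\\S+\\s+", "", p)
      }
    }
    stats::setNames(vals, keys)
  })
}

#' Read a GTF annotation
#'
#' Assembles transcripts from the `exon` feature rows of a GTF file. GTF
#' coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention at this boundary.
#'
#' @param path Path to a tab-delimited GTF file.
#' @param biotype_filter Optional predicate taking the named attribute vector
#'   of an exon row and returning `TRUE` to keep the transcript, e.g.
#'   `function(a) identical(a[["gene_biotype"]], "protein_coding")`. All exon
#'   rows of a transcript must pass.
#' @return An [annotation_set()]. The `biotype` column is taken from the
#'   `gene_biotype` (or `transcript_biotype`) attribute when present and is
#'   mapped to `protein_coding` / `lncRNA` / `other`.
#' @export
read_gtf <- function(path, biotype_filter = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("GTF file has no feature rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed GTF row (expected 9 tab-separated columns) at line ",
         line_no[which(nf != 9L)[1L]])
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  feat <- m[, 3L]
  is_exon <- feat == "exon"
  if (!any(is_exon)) stop("GTF file has no exon rows: ", path)
  m <- m[is_exon, , drop = FALSE]
  line_no <- line_no[is_exon]
  start1 <- suppressWarnings(as.numeric(m[, 4L]))
  end1 <- suppressWarnings(as.numeric(m[, 5L]))
  bad <- is.na(start1) | is.na(end1) | end1 < start1
  if (any(bad))
    stop("malformed GTF coordinates (non-numeric or end < start) at line ",
         line_no[which(bad)[1L]])
  attrs <- .parse_gtf_attributes(m[, 9L])
  gene_id <- vapply(attrs, function(a) unname(a["gene_id"]), character(1))
  tx_id <- vapply(attrs, function(a) unname(a["transcript_id"]), character(1))
  bad_attr <- is.na(gene_id) | is.na(tx_id)
  if (any(bad_attr))
    stop("exon row lacking gene_id/transcript_id attribute at line ",
         line_no[which(bad_attr)[1L]])
  biotype <- vapply(attrs, function(a) {
    b <- unname(a["gene_biotype"]) %||% unname(a["transcript_biotype"]) %||% ""
    if (b == "protein_coding") "protein_coding"
    else if (b %in% c("lncRNA", "lnc_RNA", "lincRNA")) "lncRNA"
    else "other"
  }, character(1))
  if (!is.null(biotype_filter)) {
    pass <- vapply(attrs, function(a) isTRUE(biotype_filter(a)), logical(1))
    drop_tx <- unique(tx_id[!pass])
    sel <- !tx_id %in% drop_tx
    if (!any(sel)) stop("biotype_filter removed every transcript")
    m <- m[sel, , drop = FALSE]; line_no <- line_no[sel]
    start1 <- start1[sel]; end1 <- end1[sel]
    gene_id <- gene_id[sel]; tx_id <- tx_id[sel]; biotype <- biotype[sel]
  }
  strand <- m[, 7L]
  bad_strand <- !strand %in% VALID_STRANDS
  if (any(bad_strand))
    stop("invalid strand at line ", line_no[which(bad_strand)[1L]])
  # conflicting strand within one transcript -> consistency error with line
  sp <- split(strand, tx_id)
  conflict <- names(sp)[vapply(sp, function(s) length(unique(s)) > 1L, logical(1))]
  if (length(conflict) > 0L)
    stop("conflicting exon strands within transcript(s): ",
         paste(conflict, collapse = ", "))
  annotation_set(data.frame(
    chrom = m[, 1L], start = start1 - 1, end = end1, strand = strand,
    gene_id = gene_id, transcript_id = tx_id, biotype = biotype,
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b)
  if (is.null(a) || length(a) == 0L || (length(a) == 1L && is.na(a))) b else a

#' Write an annotation set as GTF
#'
#' Emits one `exon` feature row per exon, converting internal 0-based
#' half-open coordinates back to GTF 1-based inclusive. Rows are ordered by
#' (chrom, start, transcript_id, exon start) so output is deterministic.
#'
#' @param annotation An [annotation_set()]; must be non-empty.
#' @param path Output file path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path, source = "lncscout") {
  stopifnot(inherits(annotation, "AnnotationSet"))
  ex <- annotation$exons
  if (nrow(ex) == 0L) stop("refusing to write an empty annotation")
  tx <- annotation$transcripts
  tx_rank <- stats::setNames(seq_len(nrow(tx)), tx$transcript_id)
  ord <- order(tx_rank[ex$transcript_id], ex$start)
  ex <- ex[ord, , drop = FALSE]
  bt <- stats::setNames(tx$biotype, tx$transcript_id)
  lines <- sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
    ex$chrom, source, as.integer(ex$start + 1), as.integer(ex$end),
    ex$strand, ex$gene_id, ex$transcript_id, bt[ex$transcript_id])
  writeLines(lines, path)
  invisible(path)
}

# ---- expression matrices ----------------------------------------------------

#' Construct an expression matrix
#'
#' Transcript-by-library expression values (FPKM-like, non-negative) with a
#' design describing which (tissue, replicate) each library measures.
#'
#' @param values Numeric matrix, rows = transcripts (rownames required),
#'   columns = libraries (colnames required), all values >= 0.
#' @param design data.frame with columns `library`, `tissue`, `replicate`;
#'   one row per column of `values`, each (tissue, replicate) pair unique.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, design) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (any(values < 0)) stop("expression values must be non-negative")
  need <- c("library", "tissue", "replicate")
  if (!all(need %in% names(design))) stop("design needs columns library, tissue, replicate")
  design <- design[match(colnames(values), design$library), , drop = FALSE]
  if (any(is.na(design$library))) stop("design does not cover every library column")
  key <- paste(design$tissue, design$replicate)
  if (anyDuplicated(key)) stop("duplicated (tissue, replicate) pair in design")
  rownames(design) <- NULL
  structure(list(values = values, design = design), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  d <- x$design
  cat(sprintf("ExpressionMatrix: %d transcripts x %d libraries (%d tissues x %d replicates)\n",
              nrow(x$values), ncol(x$values), length(unique(d$tissue)),
              length(unique(d$replicate))))
  invisible(x)
}

#' Write an expression matrix as TSV
#'
#' First column `transcript_id`, then one column per library; a second header
#' block is not used — the (tissue, replicate) design is encoded in library
#' names as `tissue.replicate`.
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  df <- data.frame(transcript_id = rownames(expr$values),
                   expr$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' @param path TSV written by [write_expression()]: first column
#'   `transcript_id`, remaining columns named `tissue.replicate`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- df[[1L]]
  libs <- colnames(values)
  parts <- strsplit(libs, ".", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("library columns must be named tissue.replicate")
  design <- data.frame(library = libs,
                       tissue = vapply(parts, `[`, character(1), 1L),
                       replicate = vapply(parts, `[`, character(1), 2L),
                       stringsAsFactors = FALSE)
  expression_matrix(values, design)
}

# ---- BLAST tabular ----------------------------------------------------------

BLAST12 <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
             "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' @param path Path to a 12-column BLAST tabular file; an optional 13th
#'   column is read as `qcovs` (query coverage percentage).
#' @return data.frame with standard outfmt-6 column names (plus `qcovs` when
#'   present).
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 12L) stop("BLAST tabular file must have >= 12 columns: ", path)
  names(df)[1:12] <- BLAST12
  if (ncol(df) >= 13L) names(df)[13L] <- "qcovs"
  df
}

#' Write a BLAST tabular hit table
#' @param hits data.frame with the outfmt-6 columns (optional `qcovs`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  cols <- c(BLAST12, if ("qcovs" %in% names(hits)) "qcovs")
  utils::write.table(hits[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- ortholog groups --------------------------------------------------------

#' Read an ortholog-group table
#' @param path TSV with header `group_id`, `species`, `gene_id`: one row per
#'   (group, species, gene) membership.
#' @return data.frame with those three character columns.
#' @export
read_ortholog_groups <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("group_id", "species", "gene_id")
  if (!all(need %in% names(df)))
    stop("ortholog-group table needs columns group_id, species, gene_id")
  df[need]
}

#' Write an ortholog-group table
#' @param groups data.frame with columns `group_id`, `species`, `gene_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_groups <- function(groups, path) {
  utils::write.table(groups[c("group_id", "species", "gene_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
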