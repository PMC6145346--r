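# The lncRNA identification cascade. Stages, in order:
#   1. annotation_match : drop transcripts whose class code against the
#      protein-coding reference is "=" (they are known genes);
#   2. mono_exonic      : drop single-exon transcripts (likely noise);
#   3. short            : drop transcripts with spliced length <= min_length
#      (a lncRNA is defined as longer than 200 bases);
#   4. protein_homology : drop transcripts with any protein-database hit at
#      evalue below the cutoff.
# Survivors are the lncRNA set.

#' Run the lncRNA identification cascade
#'
#' @param assembled An [annotation_set()] of assembled transcripts.
#' @param coding_reference An [annotation_set()] containing only
#'   protein-coding transcripts; used for the class-code "=" removal. (The
#'   full annotation, with noncoding biotypes, is deliberately NOT used here:
#'   identification is de novo.)
#' @param hits data.frame of protein-homology hits (outfmt-6 columns,
#'   see [read_blast_tab()]); may be empty. Hits whose `qseqid` is not an
#'   assembled transcript are ignored and counted in the report.
#' @param min_length Spliced-length threshold in bases; survivors must be
#'   strictly longer. Default 200.
#' @param evalue_cutoff Transcripts with any hit at `evalue <` this value are
#'   removed. Default 0.001.
#' @param class_codes Optional precomputed result of
#'   [assign_class_codes()] for `assembled` vs `coding_reference`; computed
#'   when missing.
#' @return list with `lncrnas` (an [annotation_set()] of survivors) and
#'   `report` (a `FilterReport`: input count, per-stage removal counts,
#'   surviving ids).
#' @export
run_filter_cascade <- function(assembled, coding_reference, hits = NULL,
                               min_length = 200, evalue_cutoff = 0.001,
                               class_codes = NULL) {
  stopifnot(inherits(assembled, "AnnotationSet"))
  if (min_length < 0 || evalue_cutoff < 0)
    stop("min_length and evalue_cutoff must be non-negative")
  tx <- assembled$transcripts
  if (nrow(tx) == 0L) stop("empty assembled set")
  if (is.null(class_codes))
    class_codes <- assign_class_codes(assembled, coding_reference)

  alive <- tx$transcript_id
  removed <- integer(0)
  report_stage <- function(nm, drop_ids) {
    n <- length(drop_ids)
    removed[[nm]] <<- n
    alive <<- setdiff(alive, drop_ids)
  }

  eq_ids <- class_codes$transcript_id[class_codes$class_code == "="]
  report_stage("annotation_match", intersect(alive, eq_ids))

  mono <- tx$transcript_id[tx$n_exons == 1L]
  report_stage("mono_exonic", intersect(alive, mono))

  short <- tx$transcript_id[tx$spliced_length <= min_length]
  report_stage("short", intersect(alive, short))

  unknown_hits <- 0L
  if (!is.null(hits) && nrow(hits) > 0L) {
    unknown_hits <- sum(!hits$qseqid %in% tx$transcript_id)
    if (unknown_hits > 0L)
      warning(unknown_hits, " homology hit(s) with unknown query id ignored")
    hom <- unique(hits$qseqid[hits$evalue < evalue_cutoff])
    report_stage("protein_homology", intersect(alive, hom))
  } else {
    report_stage("protein_homology", character(0))
  }

  report <- structure(list(
    input_count = nrow(tx),
    removed_by_stage = unlist(removed),
    surviving_ids = alive,
    unknown_hit_queries = unknown_hits,
    params = list(min_length = min_length, evalue_cutoff = evalue_cutoff)
  ), class = "FilterReport")

  if (length(alive) == 0L)
    return(list(lncrnas = NULL, report = report))
  lnc <- subset_transcripts(assembled, alive)
  lnc$exons$biotype <- "lncRNA"
  lnc <- annotation_set(lnc$exons)
  list(lncrnas = lnc, report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("lncRNA identification cascade\n")
  cat(sprintf("  input transcripts : %d\n", x$input_count))
  for (nm in names(x$removed_by_stage))
    cat(sprintf("  removed %-17s: %d\n", nm, x$removed_by_stage[[nm]]))
  cat(sprintf("  surviving lncRNAs : %d\n", length(x$surviving_ids)))
  if (x$unknown_hit_queries > 0L)
    cat(sprintf("  (ignored hits with unknown query ids: %d)\n",
                x$unknown_hit_queries))
  invisible(x)
}

#' Known-noncoding database overlap of identified lncRNAs
#'
#' Flags lncRNAs with sequence similarity to a noncoding-RNA database
#' (NONCODE-style blastn hits): a lncRNA overlaps the database when some hit
#' passes `evalue < evalue_cutoff`, `pident > min_identity` and
#' `qcovs > min_coverage` (all strict). Among passing hits the one with the
#' highest bit score is reported.
#'
#' @param lncrnas An [annotation_set()] of identified lncRNAs.
#' @param hits data.frame of blastn hits with `qcovs` (see
#'   [read_blast_tab()]).
#' @param evalue_cutoff,min_identity,min_coverage Thresholds; defaults
#'   `1e-5`, `50`, `50`.
#' @return list with `matches` (data.frame `transcript_id`, `subject_id`,
#'   `bitscore`; one row per lncRNA with a passing hit) and
#'   `overlap_fraction` (matched lncRNAs / all lncRNAs).
#' @export
noncode_overlap <- function(lncrnas, hits, evalue_cutoff = 1e-5,
                            min_identity = 50, min_coverage = 50) {
  ids <- lncrnas$transcripts$transcript_id
  if (is.null(hits) || nrow(hits) == 0L) {
    return(list(matches = data.frame(transcript_id = character(0),
                                     subject_id = character(0),
                                     bitscore = numeric(0)),
                overlap_fraction = 0))
  }
  if (!"qcovs" %in% names(hits))
    stop("noncode_overlap requires hits carrying query coverage (qcovs)")
  pass <- hits$evalue < evalue_cutoff & hits$pident > min_identity &
    hits$qcovs > min_coverage & hits$qseqid %in% ids
  h <- hits[pass, , drop = FALSE]
  if (nrow(h) == 0L)
    return(list(matches = data.frame(transcript_id = character(0),
                                     subject_id = character(0),
                                     bitscore = numeric(0)),
                overlap_fraction = 0))
  h <- h[order(h$qseqid, -h$bitscore, h$sseqid), , drop = FALSE]
  best <- h[!duplicated(h$qseqid), , drop = FALSE]
  matches <- data.frame(transcript_id = best$qseqid,
                        subject_id = best$sseqid,
                        bitscore = best$bitscore,
                        stringsAsFactors = FALSE)
  rownames(matches) <- NULL
  list(matches = matches,
       overlap_fraction = nrow(matches) / length(ids))
}

#' Structural summaries of lncRNAs versus mRNAs
#'
#' Distribution tables of spliced transcript length, exon count and isoforms
#' per locus for two transcript groups, as fractions per group.
#'
#' @param lncrnas,mrnas [annotation_set()] objects; both non-empty.
#' @param length_breaks Lower edges of the length bins (bases); default
#'   `c(200, 1000, 10000)` giving bins 200-999, 1000-9999, >= 10000.
#' @param exon_breaks Exon-count bin edges; counts at or above the last edge
#'   are pooled. Default `1:10`.
#' @param isoform_breaks Isoforms-per-locus bin edges, same pooling rule.
#' @return list of three data.frames (`length`, `exons`, `isoforms`), each
#'   with columns `bin`, `lncRNA`, `mRNA` holding per-group fractions that
#'   sum to one.
#' @export
summarize_structure <- function(lncrnas, mrnas,
                                length_breaks = c(200, 1000, 10000),
                                exon_breaks = 1:10,
                                isoform_breaks = 1:10) {
  groups <- list(lncRNA = lncrnas$transcripts, mRNA = mrnas$transcripts)
  if (any(vapply(groups, nrow, integer(1)) == 0L))
    stop("both transcript sets must be non-empty")

  bin_frac <- function(x, breaks, labels) {
    b <- findInterval(x, breaks)
    b[b < 1L] <- 1L
    f <- tabulate(b, nbins = length(breaks)) / length(x)
    data.frame(bin = labels, frac = f, stringsAsFactors = FALSE)
  }
  len_labels <- c(paste0(length_breaks[-length(length_breaks)], "-",
                         length_breaks[-1L] - 1L),
                  paste0(">=", length_breaks[length(length_breaks)]))
  count_labels <- function(breaks)
    c(as.character(breaks[-length(breaks)]),
      paste0(">=", breaks[length(breaks)]))

  assemble <- function(getter, breaks, labels) {
    cols <- lapply(groups, function(g) bin_frac(getter(g), breaks, labels)$frac)
    data.frame(bin = labels, lncRNA = cols$lncRNA, mRNA = cols$mRNA,
               stringsAsFactors = FALSE)
  }
  list(
    length = assemble(function(g) g$spliced_length, length_breaks, len_labels),
    exons = assemble(function(g) g$n_exons, exon_breaks,
                     count_labels(exon_breaks)),
    isoforms = assemble(function(g) as.integer(table(g$gene_id)),
                        isoform_breaks, count_labels(isoform_breaks))
  )
}
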