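# Cufflinks-style class codes: the relationship of each assembled transcript
# to a reference annotation, over the six-code universe {=, j, u, x, o, s}.
#
# Precedence when several relationships hold: = > j > o > x > s > u.
#   "="  identical intron chain with some reference transcript (terminal exon
#        boundaries are free to differ); multi-exon only.
#   "j"  shares >= 1 splice junction with a same-strand reference transcript
#        AND carries >= 1 junction absent from every same-strand overlapping
#        reference transcript (a novel isoform); multi-exon only.
#   "o"  same-strand exon overlap (>= 1 bp) that is neither "=" nor "j".
#        This includes the textbook case (overlap with no shared splice
#        sites) and the contained-isoform corner whose junctions are all
#        annotated but whose chain matches no single reference transcript.
#   "x"  opposite-strand exon overlap (>= 1 bp), no same-strand exon overlap.
#   "s"  the query lies entirely within an intron of an opposite-strand
#        reference transcript, with no exon overlap on either strand.
#   "u"  none of the above: an unknown, intergenic transcript.
#
# Unstranded ('.') queries take no part in sense/antisense decisions: they
# can only be "o" (exon overlap with any reference feature) or "u".

CLASS_CODES <- c("=", "j", "o", "x", "s", "u")

#' Assign class codes to assembled transcripts
#'
#' Compares every transcript of `assembled` to `reference` and assigns one
#' class code each, with precedence `=` > `j` > `o` > `x` > `s` > `u`.
#'
#' @param assembled An [annotation_set()] of assembled (query) transcripts.
#' @param reference An [annotation_set()] used as the reference annotation.
#' @return data.frame with columns `transcript_id`, `class_code`,
#'   `matched_reference_id` (`NA` for code `"u"`; otherwise a reference
#'   transcript witnessing the assigned relationship).
#' @export
assign_class_codes <- function(assembled, reference) {
  q <- .tx_index(assembled)
  r <- .tx_index(reference)

  # chain -> reference transcript lookup (first witness by table order)
  chain_map <- split(r$tx$transcript_id, r$chains)[unique(r$chains[!is.na(r$chains)])]
  # junction key -> reference transcript ids (per strand)
  jx_tab <- data.frame(
    key = unlist(r$junctions, use.names = FALSE),
    ref_id = rep(r$tx$transcript_id, lengths(r$junctions)),
    strand = rep(r$tx$strand, lengths(r$junctions)),
    stringsAsFactors = FALSE)

  ref_span_gr <- .span_granges(r$tx)
  ref_exon_gr <- .exon_granges(r$exons)
  q_span_gr <- .span_granges(q$tx)
  q_exon_gr <- .exon_granges(q$exons)

  # overlaps of query spans with reference spans (strand-blind; strand logic
  # handled explicitly below)
  span_hits <- GenomicRanges::findOverlaps(q_span_gr, ref_span_gr,
                                           ignore.strand = TRUE)
  span_by_q <- split(S4Vectors::subjectHits(span_hits),
                     S4Vectors::queryHits(span_hits))

  # exon-level overlaps, mapped back to transcript pairs
  ex_hits <- GenomicRanges::findOverlaps(q_exon_gr, ref_exon_gr,
                                         ignore.strand = TRUE)
  ex_pairs <- unique(data.frame(
    q = match(q$exons$transcript_id[S4Vectors::queryHits(ex_hits)],
              q$tx$transcript_id),
    r = match(r$exons$transcript_id[S4Vectors::subjectHits(ex_hits)],
              r$tx$transcript_id)))
  ex_by_q <- split(ex_pairs$r, ex_pairs$q)

  n <- nrow(q$tx)
  code <- character(n)
  match_id <- rep(NA_character_, n)
  r_strand <- r$tx$strand
  r_id <- r$tx$transcript_id

  for (i in seq_len(n)) {
    qs <- q$tx$strand[i]
    qj <- q$junctions[[i]]
    span_refs <- span_by_q[[as.character(i)]] %||% integer(0)
    exon_refs <- ex_by_q[[as.character(i)]] %||% integer(0)

    # "=": identical intron chain on the same strand
    if (qs != "." && length(qj) > 0L) {
      ck <- paste(qj, collapse = "|")
      cand <- chain_map[[ck]]
      if (!is.null(cand)) {
        ok <- cand[r_strand[match(cand, r_id)] == qs]
        if (length(ok) > 0L) {
          code[i] <- "="
          match_id[i] <- sort(ok)[1L]
          next
        }
      }
    }

    same_exon <- exon_refs[r_strand[exon_refs] == qs]
    opp_exon <- exon_refs[r_strand[exon_refs] %in% setdiff(c("+", "-"), qs) &
                            r_strand[exon_refs] != "."]
    if (qs == ".") { same_exon <- exon_refs; opp_exon <- integer(0) }

    # "j": junction share + novel junction (stranded, multi-exon)
    if (qs != "." && length(qj) > 0L) {
      shared_refs <- unique(jx_tab$ref_id[jx_tab$key %in% qj &
                                            jx_tab$strand == qs])
      if (length(shared_refs) > 0L) {
        same_span <- span_refs[r_strand[span_refs] == qs]
        ref_j_pool <- unique(unlist(r$junctions[same_span], use.names = FALSE))
        if (any(!qj %in% ref_j_pool)) {
          # witness: shared-junction reference with most junctions in common
          n_shared <- vapply(shared_refs, function(rid) {
            ri <- match(rid, r_id)
            sum(qj %in% r$junctions[[ri]])
          }, numeric(1))
          best <- shared_refs[order(-n_shared, shared_refs)][1L]
          code[i] <- "j"
          match_id[i] <- best
          next
        }
      }
    }

    # "o": same-strand exon overlap not resolved above
    if (length(same_exon) > 0L) {
      code[i] <- "o"
      match_id[i] <- sort(r_id[same_exon])[1L]
      next
    }

    # "x": opposite-strand exon overlap
    if (length(opp_exon) > 0L) {
      code[i] <- "x"
      match_id[i] <- sort(r_id[opp_exon])[1L]
      next
    }

    # "s": contained in an intron of an opposite-strand reference transcript
    if (qs != ".") {
      opp_span <- span_refs[r_strand[span_refs] != qs & r_strand[span_refs] != "."]
      s_hit <- NA_character_
      for (ri in opp_span) {
        rex <- r$exons[r$exon_rows[[ri]], , drop = FALSE]
        if (nrow(rex) < 2L) next
        istart <- rex$end[-nrow(rex)]
        iend <- rex$start[-1L]
        if (any(q$tx$start[i] >= istart & q$tx$end[i] <= iend)) {
          s_hit <- r_id[ri]
          break
        }
      }
      if (!is.na(s_hit)) {
        code[i] <- "s"
        match_id[i] <- s_hit
        next
      }
    }

    code[i] <- "u"
  }

  data.frame(transcript_id = q$tx$transcript_id, class_code = code,
             matched_reference_id = match_id, stringsAsFactors = FALSE)
}

#' Tabulate class codes
#' @param codes data.frame from [assign_class_codes()].
#' @return Named integer vector over the six codes, in the order
#'   `=`, `j`, `u`, `x`, `o`, `s`.
#' @export
tabulate_class_codes <- function(codes) {
  tab <- table(factor(codes$class_code, levels = c("=", "j", "u", "x", "o", "s")))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Categorize lncRNA novelty against the full annotation
#'
#' After identification, each lncRNA is compared to the full reference
#' annotation (all biotypes, including annotated noncoding transcripts) and
#' placed in exactly one of three categories: `previously_annotated` when its
#' intron chain matches an annotated transcript, `novel_locus` when its span
#' overlaps no annotated transcript at all, and `novel_isoform` otherwise
#' (it touches annotated structure — shared junctions or exon overlap — but
#' is not a complete match).
#'
#' @param lncrnas An [annotation_set()] of identified lncRNAs.
#' @param full_reference An [annotation_set()] carrying all annotated
#'   transcripts of every biotype.
#' @return data.frame with columns `transcript_id`, `category`.
#' @export
categorize_novelty <- function(lncrnas, full_reference) {
  q <- .tx_index(lncrnas)
  r <- .tx_index(full_reference)
  ref_chains <- r$chains[!is.na(r$chains)]

  span_hits <- GenomicRanges::findOverlaps(.span_granges(q$tx),
                                           .span_granges(r$tx),
                                           ignore.strand = TRUE)
  has_overlap <- seq_len(nrow(q$tx)) %in% S4Vectors::queryHits(span_hits)

  category <- vapply(seq_len(nrow(q$tx)), function(i) {
    qj <- q$junctions[[i]]
    if (length(qj) > 0L && paste(qj, collapse = "|") %in% ref_chains)
      return("previously_annotated")
    if (!has_overlap[i]) return("novel_locus")
    "novel_isoform"
  }, character(1))

  data.frame(transcript_id = q$tx$transcript_id, category = category,
             stringsAsFactors = FALSE)
}
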