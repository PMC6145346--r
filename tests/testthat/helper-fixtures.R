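# Shared builders and independent oracles.

# quick transcript builder: exon starts/ends as vectors
tx_rows <- function(id, starts, ends, strand = "+", chrom = "chr1",
                    gene = paste0(id, ".g"), biotype = "other") {
  data.frame(chrom = chrom, start = starts, end = ends, strand = strand,
             gene_id = gene, transcript_id = id, biotype = biotype,
             stringsAsFactors = FALSE)
}

ann <- function(...) annotation_set(do.call(rbind, list(...)))

# ---- independent class-code oracle ------------------------------------------
# Exhaustive pairwise evaluation of the class-code definitions, written as a
# direct double loop with set operations; shares no code path with
# assign_class_codes beyond the AnnotationSet container.

.o_junctions <- function(ex) {
  n <- nrow(ex)
  if (n < 2L) return(character(0))
  paste0(ex$chrom[1L], ":", ex$end[-n], "-", ex$start[-1L])
}

.o_exon_overlap <- function(ex1, ex2) {
  for (i in seq_len(nrow(ex1)))
    if (any(ex1$start[i] < ex2$end & ex2$start < ex1$end[i])) return(TRUE)
  FALSE
}

oracle_class_codes <- function(asm, ref) {
  rtx <- ref$transcripts
  r_ex <- lapply(rtx$transcript_id, function(id) transcript_exons(ref, id))
  r_j <- lapply(r_ex, .o_junctions)
  q_ex <- lapply(asm$transcripts$transcript_id,
                 function(id) transcript_exons(asm, id))
  out <- character(nrow(asm$transcripts))
  for (qi in seq_len(nrow(asm$transcripts))) {
    q <- asm$transcripts[qi, ]
    qex <- q_ex[[qi]]
    qj <- .o_junctions(qex)
    stranded <- q$strand != "."
    is_eq <- FALSE; same_ex <- FALSE; opp_ex <- FALSE
    shares_j <- FALSE; intron_contained <- FALSE
    same_overlap_junctions <- character(0)
    for (ri in seq_len(nrow(rtx))) {
      r <- rtx[ri, ]
      if (r$chrom != q$chrom) next
      same_strand <- stranded && r$strand == q$strand
      opp_strand <- stranded && r$strand != "." && r$strand != q$strand
      span_olap <- q$start < r$end && r$start < q$end
      ex_olap <- .o_exon_overlap(qex, r_ex[[ri]])
      if (same_strand && length(qj) > 0L && length(r_j[[ri]]) == length(qj) &&
          all(qj == r_j[[ri]])) is_eq <- TRUE
      if (same_strand && any(qj %in% r_j[[ri]])) shares_j <- TRUE
      if (same_strand && span_olap)
        same_overlap_junctions <- union(same_overlap_junctions, r_j[[ri]])
      if (ex_olap) {
        if (!stranded || same_strand) same_ex <- TRUE
        if (opp_strand) opp_ex <- TRUE
      }
      if (opp_strand && span_olap && !ex_olap && nrow(r_ex[[ri]]) > 1L) {
        rex <- r_ex[[ri]]
        for (ii in seq_len(nrow(rex) - 1L))
          if (q$start >= rex$end[ii] && q$end <= rex$start[ii + 1L])
            intron_contained <- TRUE
      }
    }
    out[qi] <- if (is_eq) "="
    else if (stranded && shares_j && any(!qj %in% same_overlap_junctions)) "j"
    else if (same_ex) "o"
    else if (opp_ex) "x"
    else if (stranded && intron_contained) "s"
    else "u"
  }
  data.frame(transcript_id = asm$transcripts$transcript_id,
             class_code = out, stringsAsFactors = FALSE)
}

# ---- randomized annotation pairs exercising every code ----------------------

random_tx <- function(id, chrom = "chr1", lo = 0, hi = 20000,
                      strand = sample(c("+", "-"), 1L)) {
  n_ex <- sample(1:4, 1L)
  ex_len <- sample(60:300, n_ex, replace = TRUE)
  introns <- if (n_ex > 1L) sample(80:600, n_ex - 1L, replace = TRUE) else integer(0)
  span <- sum(ex_len) + sum(introns)
  start <- sample(lo:max(lo, hi - span), 1L)
  starts <- start + cumsum(c(0L, ex_len[-n_ex] + introns))
  tx_rows(id, starts, starts + ex_len, strand = strand, chrom = chrom)
}

random_case <- function(seed, n_ref = NULL, n_query = NULL) {
  set.seed(seed)
  if (is.null(n_ref)) n_ref <- sample(5:50, 1L)
  if (is.null(n_query)) n_query <- sample(5:50, 1L)
  ref_rows <- do.call(rbind, lapply(seq_len(n_ref), function(i)
    random_tx(sprintf("R%03d", i))))
  ref <- annotation_set(ref_rows)
  q_rows <- list()
  for (i in seq_len(n_query)) {
    id <- sprintf("Q%03d", i)
    mode <- sample(c("copy", "mutate", "random"), 1L,
                   prob = c(0.25, 0.25, 0.5))
    if (mode == "random") {
      q_rows[[i]] <- random_tx(id)
      next
    }
    src <- transcript_exons(ref, sample(ref$transcripts$transcript_id, 1L))
    starts <- src$start; ends <- src$end
    if (mode == "copy") {             # "=" candidate: jitter terminal exons
      starts[1L] <- max(0L, starts[1L] - sample(0:50, 1L))
      ends[length(ends)] <- ends[length(ends)] + sample(0:50, 1L)
    } else if (nrow(src) >= 2L) {     # "j" candidate: shift one junction
      gap <- starts[2L] - ends[1L]
      ends[1L] <- ends[1L] + sample(seq_len(max(1L, gap - 1L)), 1L)
    }
    q_rows[[i]] <- tx_rows(id, starts, ends, strand = src$strand[1L],
                           chrom = src$chrom[1L])
  }
  list(ref = ref, asm = annotation_set(do.call(rbind, q_rows)))
}

# ---- rank-then-Pearson oracle for Spearman ----------------------------------
# average ranks computed by sorting, Pearson by the explicit product-moment
# formula

oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# ---- linear-scan nearest-gene oracle ----------------------------------------

oracle_nearest <- function(lnc_row, gene_spans, window = 50000) {
  best_gene <- NA_character_; best_d <- Inf
  for (i in seq_len(nrow(gene_spans))) {
    g <- gene_spans[i, ]
    if (g$chrom != lnc_row$chrom) next
    d <- max(0, g$start - lnc_row$end, lnc_row$start - g$end)
    if (d < best_d || (d == best_d && !is.na(best_gene) && g$gene_id < best_gene)) {
      best_d <- d; best_gene <- g$gene_id
    }
  }
  if (!is.finite(best_d) || best_d > window)
    list(gene_id = NA_character_, distance = NA_real_)
  else list(gene_id = best_gene, distance = best_d)
}

# ---- brute-force positional-category oracle ---------------------------------
# linear scan over all genes with plain pairwise interval tests

oracle_classify <- function(lnc, genes, window = 50000) {
  gtx <- genes$transcripts
  gene_ids <- sort(unique(gtx$gene_id))
  spans <- do.call(rbind, lapply(gene_ids, function(g) {
    rows <- gtx[gtx$gene_id == g, ]
    data.frame(gene_id = g, chrom = rows$chrom[1], strand = rows$strand[1],
               start = min(rows$start), end = max(rows$end))
  }))
  out <- character(nrow(lnc$transcripts))
  for (i in seq_len(nrow(lnc$transcripts))) {
    l <- lnc$transcripts[i, ]
    lex <- transcript_exons(lnc, l$transcript_id)
    near <- oracle_nearest(l, spans, window)
    if (is.na(near$gene_id)) { out[i] <- "Intergenic, No Gene Within Window"; next }
    if (l$strand == ".") { out[i] <- "Unclassified Strand"; next }
    g <- spans[spans$gene_id == near$gene_id, ]
    orient <- if (l$strand == g$strand) "Sense" else "Antisense"
    if (near$distance == 0) {
      gex <- genes$exons[genes$exons$gene_id == g$gene_id, ]
      exonic <- FALSE
      for (a in seq_len(nrow(lex)))
        for (b in seq_len(nrow(gex)))
          if (lex$start[a] < gex$end[b] && gex$start[b] < lex$end[a])
            exonic <- TRUE
      sub <- if (l$start >= g$start && l$end <= g$end) "Nested"
      else if (g$start >= l$start && g$end <= l$end) "Containing"
      else "Overlapping"
      out[i] <- paste(orient, sub, if (exonic) "Exonic" else "Intronic")
    } else {
      left <- l$end <= g$start
      up <- if (g$strand == "-") !left else left
      out[i] <- paste(orient, "Intergenic", if (up) "Upstream" else "Downstream")
    }
  }
  data.frame(lncrna_id = lnc$transcripts$transcript_id, category = out,
             stringsAsFactors = FALSE)
}

# small default study cached for the whole test run (generation is seeded)
small_study <- local({
  cache <- NULL
  function(seed = 7L) {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = seed, n_coding_genes = 40,
        planted = list(conserved_groups = 3, intergenic_per_category = 3,
                       genic_per_category = 2, distal = 3, eq = 3, mono = 3,
                       short = 2, strong_homology = 2, weak_homology = 2,
                       annotated_lnc = 3, novel_isoform = 2,
                       specific_per_tissue = 1))
      cache <<- generate_study(cfg)
    }
    cache
  }
})
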