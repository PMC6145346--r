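# Tissue specificity index (tau):
#   tau = sum_{i=1..N} (1 - x_i) / (N - 1)
# with x_i the expression in tissue i normalized by the maximum across
# tissues. tau = 1 when a transcript is expressed in a single tissue,
# tau = 0 when expression is uniform across all tissues. Replicate tau
# values are combined with an F1 score, 2AB/(A+B); a transcript is called
# tissue specific when tau exceeds the threshold (default 0.9, strict) in
# every replicate and the maximally expressing tissue agrees across
# replicates.

#' Tissue specificity index (tau)
#'
#' @param levels Named or unnamed numeric vector of non-negative expression
#'   levels, one per tissue.
#' @return tau in `[0, 1]`; `NA` when all levels are zero (undefined).
#' @export
compute_tau <- function(levels) {
  if (length(levels) < 2L) stop("tau needs at least two tissues")
  if (any(levels < 0)) stop("expression levels must be non-negative")
  m <- max(levels)
  if (m == 0) return(NA_real_)
  x <- levels / m
  sum(1 - x) / (length(levels) - 1L)
}

#' Combine two replicate tau values with an F1 score
#'
#' `F1(a, b) = 2ab / (a + b)`, with `F1(0, 0) = 0` by continuity.
#'
#' @param tau_a,tau_b Values in `[0, 1]`.
#' @return Combined score in `[0, 1]`.
#' @export
combine_replicates <- function(tau_a, tau_b) {
  stopifnot(all(tau_a >= 0 & tau_a <= 1), all(tau_b >= 0 & tau_b <= 1))
  s <- tau_a + tau_b
  out <- ifelse(s == 0, 0, 2 * tau_a * tau_b / s)
  out
}

#' Call tissue-specific transcripts
#'
#' Computes tau per replicate (each replicate contributes one library per
#' tissue), the F1-combined score, and the specificity call: tau strictly
#' above `threshold` in every replicate with the same maximally expressing
#' tissue in all replicates. All-zero replicates give undefined tau and the
#' transcript is never called specific.
#'
#' @param expr An [expression_matrix()] whose design has >= 2 replicates,
#'   each covering every tissue exactly once.
#' @param threshold Specificity threshold on tau; strict. Default 0.9.
#' @param transcripts Optional character vector restricting the rows scored.
#' @return data.frame with one row per transcript: `transcript_id`, one
#'   `tau_<replicate>` column per replicate, `tau_combined` (F1 of the first
#'   two replicates), `max_tissue` (`NA` when replicates disagree),
#'   `is_specific`.
#' @export
call_tissue_specific <- function(expr, threshold = 0.9, transcripts = NULL) {
  design <- expr$design
  reps <- sort(unique(design$replicate))
  if (length(reps) < 2L) stop("need at least two replicates")
  tissues <- sort(unique(design$tissue))
  for (r in reps) {
    d <- design[design$replicate == r, ]
    if (!setequal(d$tissue, tissues) || anyDuplicated(d$tissue))
      stop("replicate ", r, " does not cover every tissue exactly once")
  }
  vals <- expr$values
  if (!is.null(transcripts)) {
    missing <- setdiff(transcripts, rownames(vals))
    if (length(missing) > 0L)
      stop("unknown transcript(s): ", paste(utils::head(missing, 3L),
                                            collapse = ", "))
    vals <- vals[transcripts, , drop = FALSE]
  }
  n_tx <- nrow(vals)
  tau_mat <- matrix(NA_real_, n_tx, length(reps),
                    dimnames = list(rownames(vals), reps))
  argmax_mat <- matrix(NA_character_, n_tx, length(reps))
  for (k in seq_along(reps)) {
    d <- design[design$replicate == reps[k], ]
    libs <- d$library[match(tissues, d$tissue)]
    sub <- vals[, libs, drop = FALSE]
    m <- apply(sub, 1L, max)
    nonzero <- m > 0
    tau_mat[nonzero, k] <- rowSums(1 - sub[nonzero, , drop = FALSE] /
                                     m[nonzero]) / (length(tissues) - 1L)
    argmax_mat[nonzero, k] <- tissues[apply(sub[nonzero, , drop = FALSE],
                                            1L, which.max)]
  }
  defined <- rowSums(is.na(tau_mat)) == 0L
  agree <- defined & apply(argmax_mat, 1L, function(a)
    !anyNA(a) && length(unique(a)) == 1L)
  pass <- defined & apply(tau_mat > threshold, 1L, all)
  is_specific <- as.vector(pass & agree)
  combined <- rep(NA_real_, n_tx)
  combined[defined] <- combine_replicates(tau_mat[defined, 1L],
                                          tau_mat[defined, 2L])
  out <- data.frame(transcript_id = rownames(vals),
                    stringsAsFactors = FALSE)
  for (k in seq_along(reps)) out[[paste0("tau_", reps[k])]] <- tau_mat[, k]
  out$tau_combined <- combined
  out$max_tissue <- ifelse(agree, argmax_mat[, 1L], NA_character_)
  out$is_specific <- is_specific
  rownames(out) <- NULL
  out
}

#' Expression-cutoff curves of tissue-specific lncRNAs
#'
#' For each tissue, the fraction of its specific transcripts whose
#' expression in that tissue (mean over the tissue's libraries) is at or
#' above each cutoff. Curves are monotone non-increasing in the cutoff and
#' equal 1 at cutoff 0 (specific transcripts are expressed at a non-zero
#' level in their tissue by construction of tau).
#'
#' @param tsi data.frame from [call_tissue_specific()].
#' @param expr The [expression_matrix()] used for the calls.
#' @param cutoffs Increasing grid of expression levels; default
#'   `c(0, 0.5, 1, 2, 5, 10, 20, 50)`.
#' @return data.frame `tissue`, `cutoff`, `fraction`, `n` (specific
#'   transcripts in the tissue).
#' @export
expression_cutoff_curve <- function(tsi, expr,
                                    cutoffs = c(0, 0.5, 1, 2, 5, 10, 20, 50)) {
  spec <- tsi[tsi$is_specific, , drop = FALSE]
  if (nrow(spec) == 0L)
    return(data.frame(tissue = character(0), cutoff = numeric(0),
                      fraction = numeric(0), n = integer(0)))
  design <- expr$design
  out <- list()
  for (t in sort(unique(spec$max_tissue))) {
    ids <- spec$transcript_id[spec$max_tissue == t]
    libs <- design$library[design$tissue == t]
    levels <- rowMeans(expr$values[ids, libs, drop = FALSE])
    for (c in cutoffs) {
      out[[length(out) + 1L]] <- data.frame(
        tissue = t, cutoff = c, fraction = mean(levels >= c),
        n = length(ids), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Tissue-specific fraction of genes paired to specific lncRNAs
#'
#' For each tissue, takes the protein-coding genes paired with that tissue's
#' specific lncRNAs, applies the same tau calling rule to gene-level
#' expression (sum of the gene's transcripts), and reports the fraction of
#' those genes that are themselves tissue specific.
#'
#' @param tsi data.frame from [call_tissue_specific()] on the lncRNAs.
#' @param pairs Pairs from [pair_nearest_genes()] /
#'   [classify_positions()] linking lncRNAs to genes.
#' @param expr The [expression_matrix()] (must cover the genes'
#'   transcripts).
#' @param genes Protein-coding [annotation_set()].
#' @param threshold Tau threshold for the gene calls; default 0.9.
#' @return data.frame `tissue`, `n_genes`, `n_specific`, `fraction`.
#' @export
specific_gene_fraction <- function(tsi, pairs, expr, genes, threshold = 0.9) {
  spec <- tsi[tsi$is_specific, , drop = FALSE]
  spec <- merge(spec, pairs[, c("lncrna_id", "gene_id")],
                by.x = "transcript_id", by.y = "lncrna_id")
  spec <- spec[!is.na(spec$gene_id), , drop = FALSE]
  if (nrow(spec) == 0L)
    return(data.frame(tissue = character(0), n_genes = integer(0),
                      n_specific = integer(0), fraction = numeric(0)))
  gene_ids <- unique(spec$gene_id)
  gvals <- .gene_expression(expr, gene_ids, genes)
  gexpr <- expression_matrix(gvals, expr$design)
  gtsi <- call_tissue_specific(gexpr, threshold = threshold)
  gspec <- stats::setNames(gtsi$is_specific, gtsi$transcript_id)
  out <- do.call(rbind, lapply(split(spec, spec$max_tissue), function(d) {
    genes_t <- unique(d$gene_id)
    data.frame(tissue = d$max_tissue[1L],
               n_genes = length(genes_t),
               n_specific = sum(gspec[genes_t]),
               fraction = mean(gspec[genes_t]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
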