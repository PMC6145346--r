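# Spearman rank correlation of lncRNA-gene expression pairs, grouped by
# positional category, tissue, and binned pair distance. Gene-level
# expression is the sum over the gene's transcripts.

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. Constant vectors give `NA`
#' (undefined correlation); callers exclude those pairs from aggregates.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`, or `NA` when either vector is constant.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

# gene-level expression: sum of the gene's transcript rows (zero row when no
# transcript of the gene is in the matrix)
.gene_expression <- function(expr, gene_ids, genes) {
  tx <- genes$transcripts
  vals <- expr$values
  out <- matrix(0, nrow = length(gene_ids), ncol = ncol(vals),
                dimnames = list(gene_ids, colnames(vals)))
  for (i in seq_along(gene_ids)) {
    member <- tx$transcript_id[tx$gene_id == gene_ids[i]]
    member <- intersect(member, rownames(vals))
    if (length(member) > 0L)
      out[i, ] <- colSums(vals[member, , drop = FALSE])
  }
  out
}

#' Correlate lncRNA-gene pairs and summarise by positional group
#'
#' Computes Spearman's rho for every classified pair across the selected
#' libraries, the global mean rho over all pairs with defined rho (no
#' expression cutoff is applied), and each positional group's deviation from
#' that global mean.
#'
#' @param pairs Classified pairs from [classify_positions()]; distal-excluded
#'   and unclassified-strand rows are dropped.
#' @param expr An [expression_matrix()] covering lncRNA transcripts and the
#'   genes' transcripts.
#' @param genes The protein-coding [annotation_set()] (for the gene-level
#'   expression sums).
#' @param tissue Optional tissue name: restrict to that tissue's libraries
#'   (per-tissue mode); default uses every library.
#' @return list with `pair_rho` (per-pair data.frame: `lncrna_id`,
#'   `gene_id`, `category`, `distance`, `rho`), `global_mean`, `by_group`
#'   (data.frame `category`, `n`, `mean_rho`, `deviation`) and
#'   `n_undefined` (pairs excluded for constant expression).
#' @export
correlation_by_group <- function(pairs, expr, genes, tissue = NULL) {
  p <- pairs[!is.na(pairs$gene_id) & pairs$category != "Unclassified Strand", ,
             drop = FALSE]
  vals <- expr$values
  if (!is.null(tissue)) {
    libs <- expr$design$library[expr$design$tissue == tissue]
    if (length(libs) < 3L)
      stop("per-tissue mode needs >= 3 libraries for tissue ", tissue)
    vals <- vals[, libs, drop = FALSE]
  }
  missing_lnc <- setdiff(p$lncrna_id, rownames(vals))
  if (length(missing_lnc) > 0L)
    stop("expression matrix lacks lncRNA row(s): ",
         paste(utils::head(missing_lnc, 3L), collapse = ", "))
  gexp <- .gene_expression(list(values = vals), unique(p$gene_id), genes)
  rho <- vapply(seq_len(nrow(p)), function(i) {
    spearman_rho(vals[p$lncrna_id[i], ], gexp[p$gene_id[i], ])
  }, numeric(1))
  pair_rho <- data.frame(lncrna_id = p$lncrna_id, gene_id = p$gene_id,
                         category = p$category, distance = p$distance,
                         rho = rho, stringsAsFactors = FALSE)
  ok <- pair_rho[!is.na(pair_rho$rho), , drop = FALSE]
  global_mean <- mean(ok$rho)
  by_group <- do.call(rbind, lapply(split(ok, ok$category), function(d) {
    data.frame(category = d$category[1L], n = nrow(d),
               mean_rho = mean(d$rho),
               deviation = mean(d$rho) - global_mean,
               stringsAsFactors = FALSE)
  }))
  rownames(by_group) <- NULL
  list(pair_rho = pair_rho, global_mean = global_mean, by_group = by_group,
       n_undefined = sum(is.na(rho)))
}

#' Mean correlation of divergent pairs by distance bin
#'
#' Bins antisense-upstream (divergent) lncRNA-gene pairs by their span gap
#' into half-open distance bins `[edge_i, edge_{i+1})` and reports the mean
#' rho per bin. Empty bins are absent from the result.
#'
#' @param pair_rho Per-pair correlations (the `pair_rho` component of
#'   [correlation_by_group()]), already restricted to the wanted category by
#'   the caller or via `category`.
#' @param bin_edges Increasing numeric vector of bin edges covering every
#'   pair distance; the last edge is exclusive.
#' @param category Category to keep; default `"Antisense Intergenic
#'   Upstream"`. Use `NULL` to keep all rows.
#' @return data.frame `bin`, `n`, `mean_rho`, ordered by bin.
#' @export
correlation_by_distance <- function(pair_rho,
                                    bin_edges = c(0, 5000, 10000, 20000, 50001),
                                    category = "Antisense Intergenic Upstream") {
  d <- pair_rho
  if (!is.null(category)) d <- d[d$category == category, , drop = FALSE]
  d <- d[!is.na(d$rho), , drop = FALSE]
  if (nrow(d) == 0L)
    return(data.frame(bin = character(0), n = integer(0),
                      mean_rho = numeric(0)))
  b <- findInterval(d$distance, bin_edges)
  if (any(b < 1L | b >= length(bin_edges)))
    stop("pair distance outside the bin range")
  labels <- paste0("[", bin_edges[-length(bin_edges)], ",",
                   bin_edges[-1L], ")")
  d$bin <- labels[b]
  out <- do.call(rbind, lapply(split(d, factor(d$bin, levels = labels)),
                               function(g) {
    if (nrow(g) == 0L) return(NULL)
    data.frame(bin = g$bin[1L], n = nrow(g), mean_rho = mean(g$rho),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
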