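# Seeded generator of a complete five-species toy study: reference
# annotations, assembled transcriptomes with planted class-code relations,
# expression matrices with planted tissue specificity and planted
# lncRNA-gene co-expression, protein-homology hit tables, cross-species hit
# tables, ortholog groups with planted all-species conserved lncRNA loci —
# and a machine-readable truth ledger.
#
# Genome layout (per species): chromosomes of 1.36 Mb carrying 8
# protein-coding genes each at a 120 kb pitch with a 60 kb margin, plus a
# gene-free tail; neighbouring genes are therefore > 100 kb apart, so a
# lncRNA planted within 40 kb of its host gene has that gene as its
# unambiguous nearest neighbour, and the tail is > 50 kb from every gene so
# distal-excluded lncRNAs exist by construction.

.GENES_PER_CHROM <- 8L
.GENE_PITCH <- 120000
.GENE_OFFSET <- 60000
.CHROM_TAIL <- 400000

#' Configuration of a synthetic study
#'
#' @param seed Master seed; every per-species and per-component sub-seed is
#'   derived from it deterministically.
#' @param species Character vector of species names (default five).
#' @param tissues Tissue names (default the eight tissues of a multi-tissue
#'   atlas design).
#' @param replicates Replicate labels (default two biological replicates).
#' @param n_coding_genes Protein-coding genes per species.
#' @param planted Named list of planted counts:
#'   `conserved_groups` (ortholog groups with a paired lncRNA in all
#'   species; these lncRNAs are antisense-upstream), `intergenic_per_category`
#'   (lncRNAs per intergenic category: sense/antisense x up/downstream),
#'   `genic_per_category` (per genic class: novel isoform "j", antisense
#'   exonic "x", sense exonic no-shared-junction "o", antisense intronic
#'   "s"), `distal` (no gene within 50 kb), `eq` (planted "=" transcripts),
#'   `mono` (mono-exonic noise), `short` (spliced length below 200),
#'   `strong_homology` (protein hit below the e-value cutoff),
#'   `weak_homology` (protein hit above it), `annotated_lnc` (intergenic
#'   lncRNAs copied into the reference annotation), `novel_isoform`
#'   (intergenic lncRNAs given an annotated sibling sharing a junction),
#'   `specific_per_tissue` (tissue-specific lncRNAs per tissue).
#' @param expression Named list of expression parameters: `mrna_meanlog`,
#'   `lnc_meanlog`, `specific_base_meanlog` (log-scale means; mRNAs high,
#'   lncRNAs low), `tissue_noise`, `rep_noise` (log-scale spread across
#'   tissues / replicate libraries), `enrichment` (fold-change of a
#'   tissue-specific transcript in its tissue; values <= 1 plant no
#'   specificity), `coupling_scale`, `coupling_noise` (antisense-upstream
#'   lncRNAs track their gene's library profile times this scale, with this
#'   log-noise), `noise` (master noise factor; 0 gives noise-free,
#'   deterministic expression levels).
#' @return A `simulation_config` list, validated.
#' @export
simulation_config <- function(seed = 1,
    species = c("chicken", "cattle", "pig", "human", "mouse"),
    tissues = c("adipose", "cerebellum", "cortex", "hypothalamus",
                "liver", "lung", "muscle", "spleen"),
    replicates = c("A", "B"),
    n_coding_genes = 60,
    planted = list(),
    expression = list()) {
  planted_default <- list(
    conserved_groups = 5, intergenic_per_category = 6, genic_per_category = 4,
    distal = 5, eq = 5, mono = 5, short = 4,
    strong_homology = 4, weak_homology = 3,
    annotated_lnc = 6, novel_isoform = 4, specific_per_tissue = 2)
  expr_default <- list(
    mrna_meanlog = log(30), lnc_meanlog = log(3),
    specific_base_meanlog = log(0.5),
    tissue_noise = 0.4, rep_noise = 0.25,
    enrichment = 100, coupling_scale = 0.1, coupling_noise = 0.15,
    noise = 1)
  planted <- utils::modifyList(planted_default, planted)
  expression <- utils::modifyList(expr_default, expression)
  if (any(unlist(planted) < 0)) stop("planted counts must be non-negative")
  if (length(tissues) < 2L) stop("need at least 2 tissues")
  if (length(replicates) < 2L) stop("need at least 2 replicates")
  k <- planted$conserved_groups
  m <- 4L * planted$intergenic_per_category + 4L * planted$genic_per_category
  # extras pool excludes conserved hosts and the two incomplete-group genes
  pool <- seq(k + 1L, n_coding_genes - 2L)
  for (i in seq_along(species)) {
    avail <- pool[((pool - (k + 1L)) %% length(species)) + 1L != i]
    if (length(avail) < m)
      stop("n_coding_genes too small for the planted counts: species ",
           species[i], " has ", length(avail), " candidate host genes but ",
           m, " are needed")
  }
  if (planted$annotated_lnc > 2L * planted$intergenic_per_category)
    stop("annotated_lnc exceeds the sense-intergenic pool")
  if (planted$novel_isoform > planted$intergenic_per_category)
    stop("novel_isoform exceeds the antisense-downstream pool")
  if (planted$specific_per_tissue * length(tissues) >
      3L * planted$intergenic_per_category)
    stop("too many tissue-specific lncRNAs for the available intergenic pool")
  structure(list(seed = seed, species = species, tissues = tissues,
                 replicates = replicates, n_coding_genes = n_coding_genes,
                 planted = planted, expression = expression),
            class = "simulation_config")
}

# deterministic sub-seeds from the master seed
.sub_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# ---- per-species genome -----------------------------------------------------

# one gene: tx1 with n_ex exons (intron 2 fixed long so intronic lncRNAs
# fit), optional tx2 dropping the first exon
.gen_gene <- function(gene_id, idx) {
  chrom <- paste0("chr", (idx - 1L) %/% .GENES_PER_CHROM + 1L)
  slot <- (idx - 1L) %% .GENES_PER_CHROM
  start <- slot * .GENE_PITCH + .GENE_OFFSET
  strand <- sample(c("+", "-"), 1L)
  n_ex <- sample(3:5, 1L)
  ex_len <- sample(150:400, n_ex, replace = TRUE)
  introns <- sample(500:1500, n_ex - 1L, replace = TRUE)
  introns[2L] <- 3000L
  starts <- start + cumsum(c(0L, ex_len[-n_ex] + introns))
  ends <- starts + ex_len
  list(gene_id = gene_id, chrom = chrom, strand = strand,
       start = starts[1L], end = ends[n_ex],
       exon_starts = starts, exon_ends = ends,
       has_iso2 = idx %% 3L == 0L)
}

.gene_exon_rows <- function(g, biotype = "protein_coding") {
  rows <- data.frame(chrom = g$chrom, start = g$exon_starts,
                     end = g$exon_ends, strand = g$strand,
                     gene_id = g$gene_id,
                     transcript_id = paste0(g$gene_id, ".t1"),
                     biotype = biotype, stringsAsFactors = FALSE)
  if (isTRUE(g$has_iso2) && length(g$exon_starts) > 2L) {
    rows2 <- rows[-1L, , drop = FALSE]
    rows2$transcript_id <- paste0(g$gene_id, ".t2")
    rows <- rbind(rows, rows2)
  }
  rows
}

# a 3-exon lncRNA body: returns relative exon coordinates (span starts at 0)
.lnc_body <- function(n_ex = 3L, ex_range = 150:300, intron_range = 300:800) {
  ex_len <- sample(ex_range, n_ex, replace = TRUE)
  introns <- if (n_ex > 1L) sample(intron_range, n_ex - 1L, replace = TRUE) else integer(0)
  starts <- cumsum(c(0L, ex_len[-n_ex] + introns))
  list(starts = starts, ends = starts + ex_len, span = starts[n_ex] + ex_len[n_ex])
}

.place_body <- function(body, left) {
  list(starts = body$starts + left, ends = body$ends + left)
}

.lnc_rows <- function(tx_id, chrom, strand, placed) {
  data.frame(chrom = chrom, start = placed$starts, end = placed$ends,
             strand = strand, gene_id = paste0(tx_id, ".loc"),
             transcript_id = tx_id, biotype = "other",
             stringsAsFactors = FALSE)
}

flip <- function(s) if (s == "+") "-" else "+"

# ---- study generation -------------------------------------------------------

#' Generate a complete synthetic study
#'
#' @param config A [simulation_config()].
#' @return A `lnc_study` list with components `config`, `species`,
#'   `reference` (per-species [annotation_set()], coding genes plus
#'   annotated lncRNAs), `assembled` (per-species [annotation_set()]),
#'   `expression` (per-species [expression_matrix()]), `homology_hits`
#'   (per-species protein-hit data.frame in outfmt-6 layout), `cross_hits`
#'   (per ordered species pair, lncRNA-vs-lncRNA hit tables keyed
#'   `"A__B"`), `ortholog_groups` (data.frame `group_id`, `species`,
#'   `gene_id`), `chrom_sizes` (per-species named vector), and `truth`
#'   (the truth ledger: one row per assembled transcript with its true
#'   class code, removal stage, novelty and positional categories, paired
#'   gene and distance, tissue-specificity, conservation group), plus
#'   `truth_conservation` (expected conservation-matrix counts and the
#'   planted all-species group ids).
#' @export
generate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  sp <- config$species
  n_sp <- length(sp)
  seeds <- .sub_seeds(config$seed, 2L * n_sp + 2L)
  pl <- config$planted
  k <- pl$conserved_groups

  # host-gene scheme shared across species (gene index space is orthologous)
  pool <- seq(k + 1L, config$n_coding_genes - 2L)
  m <- 4L * pl$intergenic_per_category + 4L * pl$genic_per_category
  hosts_other <- lapply(seq_len(n_sp), function(i) {
    avail <- pool[((pool - (k + 1L)) %% n_sp) + 1L != i]
    avail[seq_len(m)]
  })
  names(hosts_other) <- sp

  out <- list(config = config, species = sp,
              reference = list(), assembled = list(), expression = list(),
              homology_hits = list(), cross_hits = list(),
              chrom_sizes = list())
  truth_all <- list()

  for (i in seq_len(n_sp)) {
    res <- .gen_species(sp[i], config, seeds[i], hosts = c(seq_len(k), hosts_other[[i]]))
    out$reference[[sp[i]]] <- res$reference
    out$assembled[[sp[i]]] <- res$assembled
    out$homology_hits[[sp[i]]] <- res$homology
    out$chrom_sizes[[sp[i]]] <- res$chrom_sizes
    truth_all[[sp[i]]] <- res$truth
    out$expression[[sp[i]]] <- .gen_expression_species(
      res$truth, res$reference, config, seeds[n_sp + i])
  }
  truth <- do.call(rbind, truth_all)
  rownames(truth) <- NULL
  out$truth <- truth

  # ortholog groups: one per gene index, complete except the last two
  grp <- expand.grid(idx = seq_len(config$n_coding_genes), species = sp,
                     stringsAsFactors = FALSE)
  grp$group_id <- sprintf("OG%04d", grp$idx)
  grp$gene_id <- sprintf("%s_g%03d", grp$species, grp$idx)
  incomplete <- grp$idx > config$n_coding_genes - 2L & grp$species %in% sp[c(1L, 2L)]
  grp <- grp[!incomplete, c("group_id", "species", "gene_id")]
  grp <- grp[order(grp$group_id, grp$species), , drop = FALSE]
  rownames(grp) <- NULL
  out$ortholog_groups <- grp

  out$cross_hits <- .gen_cross_hits(truth, sp, seeds[2L * n_sp + 1L])

  # expected conservation counts, derived from the planting scheme
  counts <- matrix(0L, n_sp, n_sp, dimnames = list(sp, sp))
  for (a in seq_len(n_sp)) for (b in seq_len(n_sp)) {
    counts[a, b] <- if (a == b) k + m else
      k + length(intersect(hosts_other[[a]], hosts_other[[b]]))
  }
  out$truth_conservation <- list(
    counts = counts,
    conserved_group_ids = sprintf("OG%04d", seq_len(k)))
  class(out) <- "lnc_study"
  out
}

#' @export
print.lnc_study <- function(x, ...) {
  cat(sprintf("Synthetic lncRNA study: %d species, %d tissues x %d replicates (seed %d)\n",
              length(x$species), length(x$config$tissues),
              length(x$config$replicates), x$config$seed))
  cat(sprintf("  %d assembled transcripts (%d planted lncRNAs) per species\n",
              sum(x$truth$species == x$species[1L]),
              sum(x$truth$species == x$species[1L] & x$truth$is_lncrna)))
  invisible(x)
}

# generate one species: reference + assembled + truth + homology hits
.gen_species <- function(sp, config, seed, hosts) {
  set.seed(seed)
  pl <- config$planted
  n_genes <- config$n_coding_genes
  k <- pl$conserved_groups
  n_chrom <- ceiling(n_genes / .GENES_PER_CHROM)
  chrom_len <- .GENES_PER_CHROM * .GENE_PITCH + .CHROM_TAIL
  chrom_sizes <- stats::setNames(rep(chrom_len, n_chrom),
                                 paste0("chr", seq_len(n_chrom)))

  genes <- lapply(seq_len(n_genes), function(g)
    .gen_gene(sprintf("%s_g%03d", sp, g), g))
  ref_rows <- do.call(rbind, lapply(genes, .gene_exon_rows))

  asm_rows <- list()
  truth <- list()
  tx_n <- 0L
  new_id <- function() {
    tx_n <<- tx_n + 1L
    sprintf("%s.T%04d", sp, tx_n)
  }
  add_truth <- function(id, role, class, stage, lnc, novelty, category,
                        gene = NA_character_, dist = NA_real_,
                        group = NA_character_) {
    truth[[length(truth) + 1L]] <<- data.frame(
      species = sp, transcript_id = id, role = role, true_class = class,
      removal_stage = stage, is_lncrna = lnc, novelty = novelty,
      category = category, paired_gene = gene, distance = dist,
      specific = FALSE, specific_tissue = NA_character_,
      conserved_group = group, stringsAsFactors = FALSE)
  }

  place_intergenic <- function(gene, sense, upstream) {
    d <- sample(1000:40000, 1L)
    body <- .lnc_body()
    left_side <- (upstream && gene$strand == "+") ||
      (!upstream && gene$strand == "-")
    left <- if (left_side) gene$start - d - body$span else gene$end + d
    list(placed = .place_body(body, left),
         strand = if (sense) gene$strand else flip(gene$strand),
         d = d)
  }

  host_i <- 0L
  next_host <- function() {
    host_i <<- host_i + 1L
    genes[[hosts[host_i]]]
  }

  # conserved antisense-upstream lncRNAs (hosts 1..k)
  for (ci in seq_len(k)) {
    g <- next_host()
    p <- place_intergenic(g, sense = FALSE, upstream = TRUE)
    id <- new_id()
    asm_rows[[length(asm_rows) + 1L]] <- .lnc_rows(id, g$chrom, p$strand, p$placed)
    add_truth(id, "conserved", "u", NA_character_, TRUE, "novel_locus",
              "Antisense Intergenic Upstream", g$gene_id, p$d,
              sprintf("OG%04d", ci))
  }

  # regular intergenic lncRNAs: sense-up, sense-down, antisense-up,
  # antisense-down, `intergenic_per_category` each
  inter_defs <- list(
    list(sense = TRUE, up = TRUE, cat = "Sense Intergenic Upstream"),
    list(sense = TRUE, up = FALSE, cat = "Sense Intergenic Downstream"),
    list(sense = FALSE, up = TRUE, cat = "Antisense Intergenic Upstream"),
    list(sense = FALSE, up = FALSE, cat = "Antisense Intergenic Downstream"))
  inter_ids <- list(su = character(0), sd = character(0),
                    au = character(0), ad = character(0))
  inter_geom <- list()
  for (ci in seq_along(inter_defs)) {
    def <- inter_defs[[ci]]
    for (j in seq_len(pl$intergenic_per_category)) {
      g <- next_host()
      p <- place_intergenic(g, def$sense, def$up)
      id <- new_id()
      asm_rows[[length(asm_rows) + 1L]] <- .lnc_rows(id, g$chrom, p$strand, p$placed)
      add_truth(id, "intergenic", "u", NA_character_, TRUE, "novel_locus",
                def$cat, g$gene_id, p$d)
      inter_ids[[ci]] <- c(inter_ids[[ci]], id)
      inter_geom[[id]] <- list(chrom = g$chrom, strand = p$strand,
                               placed = p$placed)
    }
  }

  # genic lncRNAs -------------------------------------------------------------
  for (j in seq_len(pl$genic_per_category)) {   # "j": novel isoform
    g <- next_host()
    starts <- g$exon_starts; ends <- g$exon_ends
    ends[2L] <- ends[2L] + 37L    # shift one junction into the long intron 2
    id <- new_id()
    asm_rows[[length(asm_rows) + 1L]] <- .lnc_rows(
      id, g$chrom, g$strand, list(starts = starts, ends = ends))
    add_truth(id, "genic_j", "j", NA_character_, TRUE, "novel_isoform",
              "Sense Nested Exonic", g$gene_id, 0)
  }
  for (j in seq_len(pl$genic_per_category)) {   # "x": antisense exonic
    g <- next_host()
    placed <- list(starts = c(g$start - 800L, g$start + 500L),
                   ends = c(g$start + 100L, g$start + 800L))
    id <- new_id()
    asm_rows[[length(asm_rows) + 1L]] <- .lnc_rows(id, g$chrom, flip(g$strand), placed)
    add_truth(id, "genic_x", "x", NA_character_, TRUE, "novel_isoform",
              "Antisense Overlapping Exonic", g$gene_id, 0)
  }
  for (j in seq_len(pl$genic_per_category)) {   # "o": sense exonic, no shared junction
    g <- next_host()
    placed <- list(starts = c(g$start + 50L, g$start + 370L),
                   ends = c(g$start + 120L, g$start + 670L))
    id <- new_id()
    asm_rows[[length(asm_rows) + 1L]] <- .lnc_rows(id, g$chrom, g$strand, placed)
    add_truth(id, "genic_o", "o", NA_character_, TRUE, "novel_isoform",
              "Sense Nested Exonic", g$gene_id, 0)
  }
  for (j in seq_len(pl$genic_per_category)) {   # "s": antisense intronic
    g <- next_host()
    i2s <- g$exon_ends[2L]        # start of the long intron 2
    placed <- list(starts = c(i2s + 200L, i2s + 650L),
                   ends = c(i2s + 350L, i2s + 800L))
    id <- new_id()
    asm_rows[[length(asm_rows) + 1L]] <- .lnc_rows(id, g$chrom, flip(g$strand), placed)
    add_truth(id, "genic_s", "s", NA_character_, TRUE, "novel_isoform",
              "Antisense Nested Intronic", g$gene_id, 0)
  }

  # tail region: distal lncRNAs and the removed categories --------------------
  tail_i <- 0L
  tail_slot <- function() {
    tail_i <<- tail_i + 1L
    chrom_i <- (tail_i - 1L) %% n_chrom + 1L
    slot <- (tail_i - 1L) %/% n_chrom
    list(chrom = paste0("chr", chrom_i),
         left = .GENES_PER_CHROM * .GENE_PITCH + 120000 + slot * 20000)
  }
  for (j in seq_len(pl$distal)) {
    ts <- tail_slot()
    body <- .lnc_body()
    id <- new_id()
    asm_rows[[length(asm_rows) + 1L]] <- .lnc_rows(
      id, ts$chrom, sample(c("+", "-"), 1L), .place_body(body, ts$left))
    add_truth(id, "distal", "u", NA_character_, TRUE, "novel_locus",
              "Intergenic, No Gene Within Window")
  }
  for (j in seq_len(pl$weak_homology)) {
    ts <- tail_slot()
    body <- .lnc_body()
    id <- new_id()
    asm_rows[[length(asm_rows) + 1L]] <- .lnc_rows(
      id, ts$chrom, sample(c("+", "-"), 1L), .place_body(body, ts$left))
    add_truth(id, "weak_homology", "u", NA_character_, TRUE, "novel_locus",
              "Intergenic, No Gene Within Window")
  }
  for (j in seq_len(pl$strong_homology)) {
    ts <- tail_slot()
    body <- .lnc_body()
    id <- new_id()
    asm_rows[[length(asm_rows) + 1L]] <- .lnc_rows(
      id, ts$chrom, sample(c("+", "-"), 1L), .place_body(body, ts$left))
    add_truth(id, "strong_homology", "u", "protein_homology", FALSE,
              NA_character_, NA_character_)
  }
  for (j in seq_len(pl$mono)) {
    ts <- tail_slot()
    id <- new_id()
    asm_rows[[length(asm_rows) + 1L]] <- .lnc_rows(
      id, ts$chrom, sample(c("+", "-"), 1L),
      list(starts = ts$left, ends = ts$left + 1000L))
    add_truth(id, "mono_exonic", "u", "mono_exonic", FALSE,
              NA_character_, NA_character_)
  }
  for (j in seq_len(pl$short)) {
    ts <- tail_slot()
    id <- new_id()
    asm_rows[[length(asm_rows) + 1L]] <- .lnc_rows(
      id, ts$chrom, sample(c("+", "-"), 1L),
      list(starts = c(ts$left, ts$left + 280L),
           ends = c(ts$left + 80L, ts$left + 360L)))
    add_truth(id, "short", "u", "short", FALSE, NA_character_, NA_character_)
  }

  # planted "=": copies of coding transcripts with jittered terminal exons
  eq_hosts <- seq(from = n_genes - 1L, by = -1L, length.out = pl$eq)
  for (j in seq_len(pl$eq)) {
    g <- genes[[eq_hosts[j]]]
    starts <- g$exon_starts; ends <- g$exon_ends
    starts[1L] <- starts[1L] - sample(20:80, 1L)
    ends[length(ends)] <- ends[length(ends)] + sample(20:80, 1L)
    id <- new_id()
    asm_rows[[length(asm_rows) + 1L]] <- .lnc_rows(
      id, g$chrom, g$strand, list(starts = starts, ends = ends))
    add_truth(id, "eq", "=", "annotation_match", FALSE,
              NA_character_, NA_character_)
  }

  truth <- do.call(rbind, truth)

  # annotated lncRNAs in the reference: exact copies of the first
  # `annotated_lnc` sense-intergenic lncRNAs, and one-junction siblings of
  # the first `novel_isoform` antisense-downstream lncRNAs
  annotated_ids <- utils::head(c(inter_ids$su, inter_ids$sd), pl$annotated_lnc)
  for (idx in seq_along(annotated_ids)) {
    id <- annotated_ids[idx]
    gm <- inter_geom[[id]]
    ref_rows <- rbind(ref_rows, data.frame(
      chrom = gm$chrom, start = gm$placed$starts, end = gm$placed$ends,
      strand = gm$strand, gene_id = sprintf("%s_alnc%02d", sp, idx),
      transcript_id = sprintf("%s_alnc%02d.t1", sp, idx),
      biotype = "lncRNA", stringsAsFactors = FALSE))
    truth$novelty[truth$transcript_id == id] <- "previously_annotated"
  }
  sibling_ids <- utils::head(inter_ids$ad, pl$novel_isoform)
  for (idx in seq_along(sibling_ids)) {
    id <- sibling_ids[idx]
    gm <- inter_geom[[id]]
    ref_rows <- rbind(ref_rows, data.frame(
      chrom = gm$chrom, start = gm$placed$starts[1:2],
      end = gm$placed$ends[1:2],
      strand = gm$strand, gene_id = sprintf("%s_slnc%02d", sp, idx),
      transcript_id = sprintf("%s_slnc%02d.t1", sp, idx),
      biotype = "lncRNA", stringsAsFactors = FALSE))
    truth$novelty[truth$transcript_id == id] <- "novel_isoform"
  }

  # tissue-specific planting: sense-up, sense-down, then the tail of the
  # antisense-downstream pool (antisense-upstream stays fully co-expressed
  # with its gene)
  n_spec <- pl$specific_per_tissue * length(config$tissues)
  spec_pool <- c(inter_ids$su, inter_ids$sd, rev(inter_ids$ad))
  spec_ids <- utils::head(spec_pool, n_spec)
  spec_tissue <- rep(config$tissues, each = pl$specific_per_tissue,
                     length.out = length(spec_ids))
  truth$specific[match(spec_ids, truth$transcript_id)] <- TRUE
  truth$specific_tissue[match(spec_ids, truth$transcript_id)] <- spec_tissue
  # every fourth specific lncRNA's host gene is itself tissue specific
  gene_spec_idx <- seq_along(spec_ids) %% 4L == 0L
  truth$gene_specific <- FALSE
  truth$gene_specific[match(spec_ids[gene_spec_idx], truth$transcript_id)] <- TRUE

  # protein-homology hits (blastx-style, 12 columns)
  hom <- truth$transcript_id[truth$role == "strong_homology"]
  weak <- truth$transcript_id[truth$role == "weak_homology"]
  mk_hit <- function(q, s, e, bits) data.frame(
    qseqid = q, sseqid = s, pident = round(runif(length(q), 40, 90), 1),
    length = sample(80:300, length(q), replace = TRUE), mismatch = 0L,
    gapopen = 0L, qstart = 1L, qend = 300L, sstart = 1L, send = 100L,
    evalue = e, bitscore = bits, stringsAsFactors = FALSE)
  homology <- rbind(
    if (length(hom) > 0L)
      mk_hit(hom, paste0("sp|P", seq_along(hom)), 1e-10, 180),
    if (length(hom) > 0L)
      mk_hit(hom, paste0("pfam|PF", seq_along(hom)), 5e-4, 90),
    if (length(weak) > 0L)
      mk_hit(weak, paste0("sp|Q", seq_along(weak)), 0.01, 40))

  list(reference = annotation_set(ref_rows),
       assembled = annotation_set(do.call(rbind, asm_rows)),
       truth = truth, homology = homology, chrom_sizes = chrom_sizes)
}

# ---- expression -------------------------------------------------------------

# library values for one species. Profiles:
#   coding gene       : lognormal around mrna_meanlog, per-tissue spread
#   specific gene     : low base, enrichment fold in its tissue
#   plain lncRNA      : lognormal around lnc_meanlog (lower than mRNA)
#   specific lncRNA   : low base, enrichment fold in its tissue
#   antisense-up lncRNA (conserved + au pool): tracks its host gene's
#                       library profile times coupling_scale
.gen_expression_species <- function(truth_sp, reference, config, seed,
                                    params = NULL) {
  set.seed(seed)
  pp <- if (is.null(params)) config$expression else params
  tissues <- config$tissues
  reps <- config$replicates
  noise <- pp$noise
  libs <- as.vector(outer(tissues, reps, paste, sep = "."))
  design <- data.frame(
    library = libs,
    tissue = rep(tissues, times = length(reps)),
    replicate = rep(reps, each = length(tissues)),
    stringsAsFactors = FALSE)

  ref_tx <- reference$transcripts
  coding_tx <- ref_tx[ref_tx$biotype == "protein_coding", , drop = FALSE]

  spec_genes <- unique(truth_sp$paired_gene[truth_sp$gene_specific %in% TRUE])
  spec_gene_tissue <- stats::setNames(
    truth_sp$specific_tissue[truth_sp$gene_specific %in% TRUE],
    truth_sp$paired_gene[truth_sp$gene_specific %in% TRUE])

  lib_values <- function(base_by_tissue) {
    v <- numeric(length(libs))
    for (li in seq_along(libs)) {
      t <- design$tissue[li]
      v[li] <- base_by_tissue[[t]] * exp(rnorm(1L, 0, pp$rep_noise * noise))
    }
    v
  }
  tissue_base <- function(meanlog, enriched_tissue = NULL, enrichment = 1) {
    b <- exp(meanlog + rnorm(length(tissues), 0, pp$tissue_noise * noise))
    names(b) <- tissues
    if (!is.null(enriched_tissue) && enrichment > 1)
      b[enriched_tissue] <- b[enriched_tissue] * enrichment
    b
  }

  rows <- c(coding_tx$transcript_id, truth_sp$transcript_id)
  vals <- matrix(0, nrow = length(rows), ncol = length(libs),
                 dimnames = list(rows, libs))

  # genes first (coupled lncRNAs need their library sums)
  gene_lib_sum <- list()
  for (gid in unique(coding_tx$gene_id)) {
    members <- coding_tx$transcript_id[coding_tx$gene_id == gid]
    base <- if (gid %in% spec_genes)
      tissue_base(log(2), spec_gene_tissue[[gid]], pp$enrichment)
    else tissue_base(pp$mrna_meanlog)
    acc <- numeric(length(libs))
    for (tx in members) {
      v <- lib_values(base / length(members))
      vals[tx, ] <- v
      acc <- acc + v
    }
    gene_lib_sum[[gid]] <- acc
  }

  coupled <- truth_sp$role %in% c("conserved", "intergenic") &
    truth_sp$category == "Antisense Intergenic Upstream" & !truth_sp$specific
  for (ri in seq_len(nrow(truth_sp))) {
    id <- truth_sp$transcript_id[ri]
    if (isTRUE(coupled[ri])) {
      g <- gene_lib_sum[[truth_sp$paired_gene[ri]]]
      vals[id, ] <- g * pp$coupling_scale *
        exp(rnorm(length(libs), 0, pp$coupling_noise * noise))
    } else if (isTRUE(truth_sp$specific[ri])) {
      base <- tissue_base(pp$specific_base_meanlog,
                          truth_sp$specific_tissue[ri], pp$enrichment)
      vals[id, ] <- lib_values(base)
    } else {
      vals[id, ] <- lib_values(tissue_base(pp$lnc_meanlog))
    }
  }
  expression_matrix(vals, design)
}

#' Regenerate the expression matrix of one species
#'
#' Rebuilds a species' expression matrix from the study's truth ledger,
#' optionally with overridden expression parameters — e.g. enrichment 1 to
#' plant no tissue specificity, or `noise = 0` for noise-free levels.
#'
#' @param study A study from [generate_study()].
#' @param species One species name of the study.
#' @param params Optional list overriding entries of the study's
#'   `expression` parameters.
#' @param seed Seed for the regeneration; default the study seed.
#' @return An [expression_matrix()].
#' @export
generate_expression <- function(study, species, params = NULL, seed = NULL) {
  stopifnot(inherits(study, "lnc_study"))
  if (!species %in% study$species) stop("unknown species: ", species)
  truth_sp <- study$truth[study$truth$species == species, , drop = FALSE]
  pp <- utils::modifyList(study$config$expression,
                          if (is.null(params)) list() else params)
  if (is.null(seed)) seed <- study$config$seed
  .gen_expression_species(truth_sp, study$reference[[species]],
                          study$config, seed, params = pp)
}

# ---- cross-species lncRNA hit tables (RBH inputs) ---------------------------

# mutual best hits between the conserved lncRNAs of every species pair, plus
# decoys: a secondary worse hit, an asymmetric best hit, and a mutual pair
# above the e-value cutoff
.gen_cross_hits <- function(truth, species, seed) {
  set.seed(seed)
  out <- list()
  cons <- split(truth$transcript_id[truth$role == "conserved"],
                truth$species[truth$role == "conserved"])
  inter <- split(truth$transcript_id[truth$role == "intergenic"],
                 truth$species[truth$role == "intergenic"])
  hit_row <- function(q, s, e, bits) data.frame(
    qseqid = q, sseqid = s, pident = 80, length = 200, mismatch = 10L,
    gapopen = 1L, qstart = 1L, qend = 200L, sstart = 1L, send = 200L,
    evalue = e, bitscore = bits, stringsAsFactors = FALSE)
  for (a in species) for (b in species) {
    if (a == b) next
    ca <- cons[[a]]; cb <- cons[[b]]
    n <- min(length(ca), length(cb))
    rows <- list()
    if (n > 0L) {
      rows[[1L]] <- hit_row(ca[seq_len(n)], cb[seq_len(n)], 1e-30, 250)
      if (n > 1L)  # secondary, worse hit: best hit stays the planted one
        rows[[2L]] <- hit_row(ca[seq_len(n - 1L)], cb[seq_len(n - 1L) + 1L],
                              1e-12, 120)
    }
    ia <- inter[[a]]; ib <- inter[[b]]
    if (length(ia) >= 2L && length(ib) >= 2L) {
      # asymmetric: a's first intergenic hits b's first, but not reciprocally
      rows[[length(rows) + 1L]] <- hit_row(ia[1L], ib[1L], 1e-8, 90)
      # mutual but above the cutoff
      rows[[length(rows) + 1L]] <- hit_row(ia[2L], ib[2L], 1e-3, 45)
    }
    out[[paste(a, b, sep = "__")]] <- do.call(rbind, rows)
  }
  # break the asymmetric decoy's reciprocity: b's first intergenic prefers
  # a's second
  for (a in species) for (b in species) {
    if (a == b) next
    tbl <- out[[paste(b, a, sep = "__")]]
    ia <- inter[[a]]; ib <- inter[[b]]
    if (length(ia) >= 2L && length(ib) >= 2L) {
      sel <- tbl$qseqid == ib[1L] & tbl$sseqid == ia[1L]
      tbl$sseqid[sel] <- ia[2L]
      out[[paste(b, a, sep = "__")]] <- tbl
    }
  }
  out
}
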