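test_that("nearest-gene pairing matches a linear-scan oracle with ties broken deterministically", {
  set.seed(11)
  for (rep in 1:10) {
    n_genes <- sample(3:12, 1)
    gene_rows <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
      s <- sample(0:500000, 1)
      tx_rows(sprintf("g%02d.t", i), s, s + sample(2000:20000, 1),
              sample(c("+", "-"), 1), gene = sprintf("g%02d", i),
              biotype = "protein_coding")
    }))
    genes <- annotation_set(gene_rows)
    lnc_rows <- do.call(rbind, lapply(1:15, function(i) {
      s <- sample(0:600000, 1)
      tx_rows(sprintf("l%02d", i), c(s, s + 1000), c(s + 300, s + 1400),
              sample(c("+", "-"), 1))
    }))
    lnc <- annotation_set(lnc_rows)
    pairs <- pair_nearest_genes(lnc, genes)
    gs <- lncscout:::.gene_spans(genes)
    for (i in seq_len(nrow(pairs))) {
      lr <- lnc$transcripts[lnc$transcripts$transcript_id == pairs$lncrna_id[i], ]
      want <- oracle_nearest(lr, gs)
      expect_identical(pairs$gene_id[i], want$gene_id)
      expect_identical(pairs$distance[i], want$distance)
    }
  }
  # exact tie: equidistant genes resolve to the smaller gene_id
  genes <- ann(tx_rows("gb.t", 20000, 25000, "+", gene = "gb",
                       biotype = "protein_coding"),
               tx_rows("ga.t", 0, 5000, "+", gene = "ga",
                       biotype = "protein_coding"))
  lnc <- ann(tx_rows("mid", c(10000, 14000), c(10500, 15000), "+"))
  p <- pair_nearest_genes(lnc, genes)
  expect_equal(p$gene_id, "ga")
  expect_equal(p$distance, 5000)
})

test_that("genes beyond the window leave the lncRNA distal-excluded", {
  genes <- ann(tx_rows("g.t", 0, 1000, "+", gene = "g",
                       biotype = "protein_coding"))
  near <- ann(tx_rows("l", c(51000, 52000), c(51400, 52400), "+"))
  far <- ann(tx_rows("l", c(61000, 62000), c(61400, 62400), "+"))
  expect_equal(pair_nearest_genes(near, genes)$gene_id, "g")  # gap 50000
  expect_true(is.na(pair_nearest_genes(far, genes)$gene_id))  # gap 60000
  cls <- classify_positions(pair_nearest_genes(far, genes), far, genes)
  expect_equal(cls$category, "Intergenic, No Gene Within Window")
})

# one gene used by the classification cases: + strand, two exons, long intron
.pos_gene <- ann(tx_rows("g.t", c(100000, 110000), c(101000, 112000), "+",
                         gene = "g", biotype = "protein_coding"))

classify_one <- function(lnc) {
  p <- pair_nearest_genes(lnc, .pos_gene)
  classify_positions(p, lnc, .pos_gene)
}

test_that("positional categories follow strand, side and containment", {
  cases <- list(
    # antisense, entirely inside the intron -> Antisense Nested Intronic
    list(tx_rows("l", c(103000, 105000), c(103500, 105600), "-"),
         "Antisense Nested Intronic"),
    # same strand, inside intron -> Sense Nested Intronic
    list(tx_rows("l", c(103000, 105000), c(103500, 105600), "+"),
         "Sense Nested Intronic"),
    # antisense, fully 5' of the + gene -> Antisense Intergenic Upstream
    list(tx_rows("l", c(80000, 81000), c(80400, 81500), "-"),
         "Antisense Intergenic Upstream"),
    # sense, 3' side -> Sense Intergenic Downstream
    list(tx_rows("l", c(120000, 121000), c(120400, 121500), "+"),
         "Sense Intergenic Downstream"),
    # span containing the whole gene, exons over gene exons -> Containing Exonic
    list(tx_rows("l", c(95000, 100500), c(95400, 113000), "+"),
         "Sense Containing Exonic"),
    # partial span overlap hitting exon 1 -> Overlapping Exonic
    list(tx_rows("l", c(99000, 100500), c(99400, 100800), "-"),
         "Antisense Overlapping Exonic"),
    # unstranded lncRNA -> unclassified bucket
    list(tx_rows("l", c(80000, 81000), c(80400, 81500), "."),
         "Unclassified Strand"))
  for (cs in cases) {
    got <- classify_one(annotation_set(cs[[1]]))
    expect_equal(got$category, cs[[2]])
  }
})

test_that("upstream/downstream follow the gene's transcriptional direction", {
  minus_gene <- ann(tx_rows("g.t", c(100000, 110000), c(101000, 112000), "-",
                            gene = "g", biotype = "protein_coding"))
  left <- ann(tx_rows("l", c(80000, 81000), c(80400, 81500), "-"))
  p <- classify_positions(pair_nearest_genes(left, minus_gene), left, minus_gene)
  # physically left of a minus-strand gene = its 3' side = downstream
  expect_equal(p$category, "Sense Intergenic Downstream")
})

test_that("each lncRNA lands in exactly one category and counts sum to the total", {
  st <- small_study()
  sp <- st$species[1]
  ref <- st$reference[[sp]]
  coding <- subset_transcripts(
    ref, ref$transcripts$transcript_id[ref$transcripts$biotype == "protein_coding"])
  res <- run_filter_cascade(st$assembled[[sp]], coding, st$homology_hits[[sp]])
  pairs <- classify_positions(pair_nearest_genes(res$lncrnas, coding),
                              res$lncrnas, coding)
  expect_false(anyNA(pairs$category))
  tab <- tabulate_categories(pairs)
  expect_equal(sum(tab$count), nrow(res$lncrnas$transcripts))
  # order invariance
  tab2 <- tabulate_categories(pairs[rev(seq_len(nrow(pairs))), ])
  expect_equal(tab, tab2)
  # counts equal the truth ledger
  tr <- st$truth[st$truth$species == sp & st$truth$is_lncrna, ]
  want <- table(tr$category)
  for (cat in names(want))
    expect_equal(tab$count[tab$category == cat], unname(unclass(want[cat])),
                 label = cat)
})

test_that("distal genome fraction has its closed form and monotonicity", {
  genes <- ann(tx_rows("g.t", 0, 1000, "+", gene = "g",
                       biotype = "protein_coding"))
  sizes <- c(chr1 = 1e6)
  expect_equal(distal_genome_fraction(genes, sizes, window = 50000), 0.949)
  # tiling genes leave nothing distal; empty set leaves everything
  tiling <- ann(tx_rows("t1", 0, 5e5, "+", gene = "t1", biotype = "protein_coding"),
                tx_rows("t2", 4e5, 1e6, "+", gene = "t2", biotype = "protein_coding"))
  expect_equal(distal_genome_fraction(tiling, sizes), 0)
  expect_equal(distal_genome_fraction(NULL, sizes), 1.0)
  # monotone non-increasing in window size
  f <- vapply(c(0, 1e4, 5e4, 2e5), function(w)
    distal_genome_fraction(genes, sizes, window = w), numeric(1))
  expect_true(all(diff(f) <= 0))
  expect_error(distal_genome_fraction(genes, c(chr1 = 500)), "beyond")
})
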