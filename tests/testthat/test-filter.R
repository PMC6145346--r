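# a small assembled set traced through each stage by hand
make_filter_fixture <- function() {
  coding <- ann(tx_rows("ref1", c(1000, 2000, 5000), c(1500, 2500, 5600),
                        "+", gene = "g1", biotype = "protein_coding"))
  asm <- ann(
    tx_rows("a_eq", c(950, 2000, 5000), c(1500, 2500, 5700), "+"),  # "=" -> stage 1
    tx_rows("a_mono", 20000, 25000, "+"),                 # mono, len 5000 -> stage 2
    tx_rows("a_short", c(30000, 30300), c(30080, 30380), "+"),  # 160 bp -> stage 3
    tx_rows("a_hit", c(40000, 41000, 42000), c(40300, 41300, 42300), "+"),  # -> stage 4
    tx_rows("a_keep", c(50000, 51000, 52000), c(50300, 51250, 52250), "+")) # survives
  hits <- data.frame(qseqid = c("a_hit", "a_keep", "ghost"),
                     sseqid = c("sp|P1", "sp|P2", "sp|P3"),
                     pident = 60, length = 100, mismatch = 0, gapopen = 0,
                     qstart = 1, qend = 100, sstart = 1, send = 100,
                     evalue = c(5e-4, 0.02, 1e-30), bitscore = 100)
  list(coding = coding, asm = asm, hits = hits)
}

test_that("the cascade removes each planted transcript at its stage", {
  fx <- make_filter_fixture()
  expect_warning(
    res <- run_filter_cascade(fx$asm, fx$coding, fx$hits),
    "unknown query")
  expect_equal(unname(res$report$removed_by_stage),
               c(1L, 1L, 1L, 1L))
  expect_equal(res$report$surviving_ids, "a_keep")
  expect_equal(res$lncrnas$transcripts$biotype, "lncRNA")
  # count conservation: input = removed + surviving
  expect_equal(res$report$input_count,
               sum(res$report$removed_by_stage) + length(res$report$surviving_ids))
})

test_that("the length stage keeps only spliced length strictly above 200", {
  coding <- ann(tx_rows("r", c(0, 500), c(100, 600), "+",
                        biotype = "protein_coding"))
  asm <- ann(
    tx_rows("len200", c(10000, 10500), c(10100, 10600), "+"),   # exactly 200
    tx_rows("len201", c(20000, 20500), c(20100, 20601), "+"))   # 201
  res <- run_filter_cascade(asm, coding, hits = NULL)
  expect_equal(res$report$surviving_ids, "len201")
})

test_that("stage order can be permuted without changing the survivors", {
  fx <- make_filter_fixture()
  hits <- fx$hits[fx$hits$qseqid != "ghost", ]
  full <- run_filter_cascade(fx$asm, fx$coding, hits)
  # commutation: apply homology/length/mono removals in a different order by
  # hand and compare the surviving set
  tx <- fx$asm$transcripts
  alive <- tx$transcript_id
  alive <- setdiff(alive, unique(hits$qseqid[hits$evalue < 0.001]))   # 4 first
  alive <- setdiff(alive, tx$transcript_id[tx$spliced_length <= 200]) # 3
  alive <- setdiff(alive, tx$transcript_id[tx$n_exons == 1])          # 2
  codes <- assign_class_codes(fx$asm, fx$coding)
  alive <- setdiff(alive, codes$transcript_id[codes$class_code == "="]) # 1 last
  expect_setequal(alive, full$report$surviving_ids)
})

test_that("survivors equal the planted lncRNA set on the synthetic study", {
  st <- small_study()
  for (sp in st$species[1:2]) {
    ref <- st$reference[[sp]]
    coding <- subset_transcripts(
      ref, ref$transcripts$transcript_id[ref$transcripts$biotype == "protein_coding"])
    res <- run_filter_cascade(st$assembled[[sp]], coding,
                              st$homology_hits[[sp]])
    tr <- st$truth[st$truth$species == sp, ]
    expect_setequal(res$report$surviving_ids, tr$transcript_id[tr$is_lncrna])
    # each removed transcript left at its planted stage
    removed <- tr[!tr$is_lncrna, ]
    for (stage in unique(removed$removal_stage))
      expect_equal(res$report$removed_by_stage[[stage]],
                   sum(removed$removal_stage == stage))
  }
})

test_that("noncode overlap applies all three strict thresholds and best bitscore", {
  lnc <- ann(tx_rows("l1", c(0, 500), c(300, 900), "+"),
             tx_rows("l2", c(5000, 5500), c(5300, 5900), "+"),
             tx_rows("l3", c(9000, 9500), c(9300, 9900), "+"))
  hit <- function(q, s, pid, cov, ev, bits)
    data.frame(qseqid = q, sseqid = s, pident = pid, length = 100,
               mismatch = 0, gapopen = 0, qstart = 1, qend = 100,
               sstart = 1, send = 100, evalue = ev, bitscore = bits,
               qcovs = cov)
  hits <- rbind(
    hit("l1", "NONHSAT001", 60, 70, 1e-10, 85),   # passes
    hit("l1", "NONHSAT002", 70, 80, 1e-12, 120),  # passes, higher bitscore
    hit("l2", "NONHSAT003", 40, 90, 1e-20, 200),  # pident fails
    hit("l3", "NONHSAT004", 60, 50, 1e-20, 200))  # qcovs not strictly > 50
  res <- noncode_overlap(lnc, hits)
  expect_equal(res$matches$transcript_id, "l1")
  expect_equal(res$matches$subject_id, "NONHSAT002")
  expect_equal(res$overlap_fraction, 1 / 3)
})

test_that("structure summaries bin lengths, exon counts and isoforms", {
  lnc <- ann(tx_rows("a", 0, 300, gene = "L1"),
             tx_rows("b", c(1000, 2000), c(1500, 2700), gene = "L2"),
             tx_rows("c", c(10000, 30000), c(17000, 40000), gene = "L2"))
  mrna <- ann(tx_rows("m1", 0, 500, gene = "G1"),
              tx_rows("m2", c(0, 1000), c(400, 1600), gene = "G1"),
              tx_rows("m3", c(5000, 9000), c(5400, 9600), gene = "G1"))
  s <- summarize_structure(lnc, mrna)
  # lncRNA spliced lengths 300, 1200, 17000 -> one per bin
  expect_equal(s$length$lncRNA, c(1, 1, 1) / 3)
  expect_equal(sum(s$length$mRNA), 1)
  expect_equal(s$exons$lncRNA[1:2], c(1, 2) / 3)
  # loci: L1 has 1 isoform, L2 has 2; G1 has 3
  expect_equal(s$isoforms$lncRNA[1:2], c(0.5, 0.5))
  expect_equal(s$isoforms$mRNA[3], 1)
})
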