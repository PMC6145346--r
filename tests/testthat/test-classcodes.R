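# reference used across the hand-built cases: one 3-exon coding gene
ref_gene <- ann(tx_rows("ref1", c(1000, 2000, 5000), c(1500, 2500, 5600),
                        "+", gene = "g1", biotype = "protein_coding"))

test_that("each planted relationship gets its class code", {
  asm <- ann(
    # identical intron chain, jittered terminal exons -> "="
    tx_rows("q_eq", c(950, 2000, 5000), c(1500, 2500, 5700), "+"),
    # shared junction plus a novel one -> "j"
    tx_rows("q_j", c(1000, 2000, 5100), c(1500, 2560, 5600), "+"),
    # same-strand exon overlap, no shared junction -> "o"
    tx_rows("q_o", c(1100, 1700), c(1300, 1900), "+"),
    # opposite-strand exon overlap -> "x"
    tx_rows("q_x", c(1200, 1700), c(1450, 1900), "-"),
    # inside intron 2 on the opposite strand -> "s"
    tx_rows("q_s", c(2700, 3400), c(2900, 3600), "-"),
    # no overlap anywhere -> "u"
    tx_rows("q_u", c(20000, 21000), c(20500, 21500), "+"))
  codes <- assign_class_codes(asm, ref_gene)
  got <- setNames(codes$class_code, codes$transcript_id)
  expect_equal(got[["q_eq"]], "=")
  expect_equal(got[["q_j"]], "j")
  expect_equal(got[["q_o"]], "o")
  expect_equal(got[["q_x"]], "x")
  expect_equal(got[["q_s"]], "s")
  expect_equal(got[["q_u"]], "u")
  expect_equal(codes$matched_reference_id[codes$transcript_id != "q_u"],
               rep("ref1", 5))
  expect_true(is.na(codes$matched_reference_id[codes$transcript_id == "q_u"]))
})

test_that("mono-exonic queries can never be '=' or 'j'", {
  asm <- ann(
    tx_rows("m_over", 1100, 1400, "+"),   # overlaps exon 1, same strand
    tx_rows("m_anti", 1100, 1400, "-"),
    tx_rows("m_intron", 2700, 3000, "-"), # inside intron 2, antisense
    tx_rows("m_free", 30000, 31000, "+"))
  got <- setNames(assign_class_codes(asm, ref_gene)$class_code,
                  asm$transcripts$transcript_id)
  expect_equal(unname(got[c("m_over", "m_anti", "m_intron", "m_free")]),
               c("o", "x", "s", "u"))
})

test_that("unstranded queries take no sense/antisense decision", {
  asm <- ann(
    tx_rows("u_over", 1100, 1400, "."),   # exon overlap -> "o" regardless
    tx_rows("u_free", 30000, 31000, "."))
  got <- setNames(assign_class_codes(asm, ref_gene)$class_code,
                  asm$transcripts$transcript_id)
  expect_equal(unname(got[c("u_over", "u_free")]), c("o", "u"))
})

test_that("totality and uniqueness: every query gets exactly one code", {
  case <- random_case(seed = 99)
  codes <- assign_class_codes(case$asm, case$ref)
  expect_equal(nrow(codes), nrow(case$asm$transcripts))
  expect_true(all(codes$class_code %in% c("=", "j", "o", "x", "s", "u")))
  expect_false(anyDuplicated(codes$transcript_id) > 0)
  counts <- tabulate_class_codes(codes)
  expect_equal(sum(counts), nrow(codes))
})

test_that("'=' is symmetric under query/reference role swap", {
  case <- random_case(seed = 17)
  fwd <- assign_class_codes(case$asm, case$ref)
  rev <- assign_class_codes(case$ref, case$asm)
  eq_fwd <- fwd$transcript_id[fwd$class_code == "="]
  eq_rev_targets <- rev$matched_reference_id[rev$class_code == "="]
  # every query judged "=" has a multi-exon witness; swapping roles, those
  # witnesses must find an "=" partner too
  for (id in eq_fwd) {
    w <- fwd$matched_reference_id[fwd$transcript_id == id]
    expect_equal(rev$class_code[rev$transcript_id == w], "=")
  }
  expect_true(all(eq_rev_targets %in% eq_fwd))
})

test_that("class codes equal the exhaustive pairwise oracle on random cases", {
  for (seed in 1:40) {
    case <- random_case(seed = 3000 + seed)
    got <- assign_class_codes(case$asm, case$ref)
    want <- oracle_class_codes(case$asm, case$ref)
    expect_identical(got$class_code, want$class_code,
                     label = sprintf("seed %d", seed))
  }
})

test_that("novelty categorization partitions the lncRNA set", {
  full_ref <- ann(
    tx_rows("cod1", c(1000, 2000), c(1500, 2500), "+", gene = "g1",
            biotype = "protein_coding"),
    tx_rows("alnc1", c(8000, 9000), c(8400, 9500), "+", gene = "al1",
            biotype = "lncRNA"))
  lnc <- ann(
    # same intron chain as the annotated lncRNA
    tx_rows("known", c(7900, 9000), c(8400, 9600), "+"),
    # shares the junction but adds a novel one
    tx_rows("iso", c(8000, 9000, 10000), c(8400, 9500, 10200), "+"),
    # overlaps the coding gene without matching its chain
    tx_rows("touch", c(1100, 1800), c(1300, 1950), "+"),
    # overlaps nothing
    tx_rows("fresh", c(40000, 41000), c(40300, 41400), "+"))
  nv <- categorize_novelty(lnc, full_ref)
  got <- setNames(nv$category, nv$transcript_id)
  expect_equal(unname(got[c("known", "iso", "touch", "fresh")]),
               c("previously_annotated", "novel_isoform", "novel_isoform",
                 "novel_locus"))
  expect_true(all(nv$category %in% c("previously_annotated", "novel_isoform",
                                     "novel_locus")))
})

test_that("assigned codes equal the truth ledger on a noise-free study", {
  st <- small_study()
  for (sp in st$species[1:2]) {
    ref <- st$reference[[sp]]
    coding <- subset_transcripts(
      ref, ref$transcripts$transcript_id[ref$transcripts$biotype == "protein_coding"])
    codes <- assign_class_codes(st$assembled[[sp]], coding)
    tr <- st$truth[st$truth$species == sp, ]
    m <- merge(codes, tr[, c("transcript_id", "true_class")])
    expect_equal(m$class_code, m$true_class)
  }
})
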