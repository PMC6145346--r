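test_that("tau closed forms hold exactly", {
  expect_equal(compute_tau(c(5, 0, 0, 0, 0, 0, 0, 0)), 1)
  expect_equal(compute_tau(rep(3, 8)), 0)
  expect_equal(compute_tau(c(10, 5, 0, 0, 0, 0, 0, 0)), 6.5 / 7,
               tolerance = 1e-12)
  expect_true(is.na(compute_tau(rep(0, 8))))
  expect_error(compute_tau(c(-1, 2)), "non-negative")
  expect_error(compute_tau(5), "two tissues")
})

test_that("tau is scale invariant and monotone in the dominant tissue", {
  set.seed(77)
  violations <- 0L
  for (i in 1:2000) {
    v <- rlnorm(8, meanlog = 0, sdlog = 1.5)
    tau <- compute_tau(v)
    if (tau < 0 || tau > 1) violations <- violations + 1L
    # scale invariance
    if (abs(compute_tau(v * runif(1, 0.01, 100)) - tau) > 1e-12)
      violations <- violations + 1L
    # raising the dominant tissue never decreases tau
    w <- v
    w[which.max(v)] <- w[which.max(v)] * (1 + runif(1, 0, 5))
    if (compute_tau(w) < tau - 1e-12) violations <- violations + 1L
  }
  expect_identical(violations, 0L)
})

test_that("the F1 combination is idempotent, symmetric and annihilated by zero", {
  grid <- seq(0, 1, length.out = 100)
  expect_equal(combine_replicates(grid, grid), grid, tolerance = 1e-12)
  a <- rep(grid, each = 10)[1:100]
  b <- rev(grid)
  expect_equal(combine_replicates(a, b), combine_replicates(b, a),
               tolerance = 1e-15)
  expect_equal(combine_replicates(1, 0), 0)
  expect_equal(combine_replicates(0, 0), 0)
  expect_equal(combine_replicates(0.8, 0.6), 0.96 / 1.4, tolerance = 1e-12)
  expect_error(combine_replicates(1.2, 0.5))
})

make_tsi_fixture <- function() {
  tissues <- paste0("t", 1:8)
  libs <- as.vector(outer(tissues, c("A", "B"), paste, sep = "."))
  design <- data.frame(library = libs, tissue = rep(tissues, 2),
                       replicate = rep(c("A", "B"), each = 8))
  specific <- c(rep(0.5, 8), rep(0.5, 8)); specific[c(3, 11)] <- 60
  near_miss <- c(rep(0.5, 8), rep(0.5, 8)); near_miss[3] <- 60  # only rep A
  disagree <- rep(0.1, 16); disagree[3] <- 60; disagree[12] <- 60  # different argmax
  flat <- rep(2, 16)
  silent <- rep(0, 16)
  v <- rbind(specific = specific, near_miss = near_miss,
             disagree = disagree, flat = flat, silent = silent)
  colnames(v) <- libs
  expression_matrix(v, design)
}

test_that("specific calls need tau above threshold in both replicates with one argmax tissue", {
  tsi <- call_tissue_specific(make_tsi_fixture())
  got <- setNames(tsi$is_specific, tsi$transcript_id)
  expect_true(got[["specific"]])
  expect_false(got[["near_miss"]])
  expect_false(got[["disagree"]])
  expect_false(got[["flat"]])
  expect_false(got[["silent"]])
  expect_equal(tsi$max_tissue[tsi$transcript_id == "specific"], "t3")
  expect_true(is.na(tsi$tau_A[tsi$transcript_id == "silent"]))
  # combined score is the F1 of the replicate values
  row <- tsi[tsi$transcript_id == "specific", ]
  expect_equal(row$tau_combined,
               combine_replicates(row$tau_A, row$tau_B), tolerance = 1e-12)
  # a tie exactly at the threshold fails the strict rule
  expect_false(call_tissue_specific(make_tsi_fixture(),
                                    threshold = row$tau_A)$is_specific[1])
})

test_that("cutoff curves start at 1, are monotone, and vanish above the maximum", {
  fx <- make_tsi_fixture()
  tsi <- call_tissue_specific(fx)
  curve <- expression_cutoff_curve(tsi, fx, cutoffs = c(0, 1, 30, 1000))
  c3 <- curve[curve$tissue == "t3", ]
  expect_equal(c3$fraction[c3$cutoff == 0], 1)
  expect_true(all(diff(c3$fraction) <= 0))
  expect_equal(c3$fraction[c3$cutoff == 1000], 0)
})

test_that("the specific fraction of paired genes recovers planted ratios", {
  st <- small_study()
  sp <- st$species[2]
  ref <- st$reference[[sp]]
  coding <- subset_transcripts(
    ref, ref$transcripts$transcript_id[ref$transcripts$biotype == "protein_coding"])
  res <- run_filter_cascade(st$assembled[[sp]], coding, st$homology_hits[[sp]])
  pairs <- pair_nearest_genes(res$lncrnas, coding)
  expr <- st$expression[[sp]]
  tsi <- call_tissue_specific(expr, transcripts = res$report$surviving_ids)
  frac <- specific_gene_fraction(tsi, pairs, expr, coding)
  tr <- st$truth[st$truth$species == sp & st$truth$specific, ]
  want <- aggregate(gene_specific ~ specific_tissue, tr, mean)
  got <- merge(frac, want, by.x = "tissue", by.y = "specific_tissue")
  expect_equal(got$fraction, got$gene_specific)
})

test_that("planted tissue-specific lncRNAs are recovered from generated expression", {
  st <- small_study()
  sp <- st$species[1]
  tr <- st$truth[st$truth$species == sp, ]
  tsi <- call_tissue_specific(st$expression[[sp]],
                              transcripts = tr$transcript_id[tr$is_lncrna])
  m <- merge(tsi, tr[, c("transcript_id", "specific", "specific_tissue")])
  expect_equal(m$is_specific, m$specific)
  called <- m[m$is_specific, ]
  expect_equal(called$max_tissue, called$specific_tissue)
})

test_that("zero enrichment plants no specificity signal", {
  st <- small_study()
  sp <- st$species[1]
  expr_null <- generate_expression(st, sp, params = list(enrichment = 1),
                                   seed = 123)
  tr <- st$truth[st$truth$species == sp, ]
  tsi <- call_tissue_specific(expr_null, transcripts = tr$transcript_id[tr$is_lncrna])
  m <- merge(tsi, tr[, c("transcript_id", "specific")])
  mean_spec <- mean(m$tau_combined[m$specific], na.rm = TRUE)
  mean_bg <- mean(m$tau_combined[!m$specific], na.rm = TRUE)
  expect_lt(abs(mean_spec - mean_bg), 0.15)
  expect_false(any(m$is_specific[m$specific]))
})
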