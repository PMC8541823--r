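make_matrix <- function(ab, genes = rownames(ab)) {
  abundance_matrix(ab, gene_symbol = genes)
}

test_that("TOP3 abundance is the mean of the three highest peptides", {
  pep <- data.frame(
    protein_id = "P1", gene_symbol = "g1",
    peptide_id = paste0("p", 1:5), experiment = 1, group = "bait",
    intensity = c(5, 4, 3, 2, 1), stringsAsFactors = FALSE)
  m <- top3_abundance(pep)
  expect_equal(unname(m$abundance["P1", "e1.bait"]), 4)
  expect_false(attr(m, "few_peptides")["P1", "e1.bait"])

  # fewer than three peptides: mean of those present, flagged
  pep2 <- pep[1:2, ]; pep2$intensity <- c(6, 2)
  m2 <- top3_abundance(pep2)
  expect_equal(unname(m2$abundance["P1", "e1.bait"]), 4)
  expect_true(attr(m2, "few_peptides")["P1", "e1.bait"])

  # permutation invariance
  m3 <- top3_abundance(pep[sample(5), ])
  expect_equal(m3$abundance, m$abundance)

  expect_error(top3_abundance(pep[, -6]), "missing columns")
})

test_that("presence filter matches the exhaustive 2^6 pattern oracle", {
  cols <- c("e1.bait", "e1.control", "e2.bait", "e2.control",
            "e3.bait", "e3.control")
  exper <- substr(cols, 1, 2)
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), 6))
  ab <- matrix(NA_real_, nrow(patterns), 6,
               dimnames = list(sprintf("P%02d", seq_len(nrow(patterns))), cols))
  for (k in seq_len(nrow(patterns)))
    ab[k, unlist(patterns[k, ])] <- 10
  kept <- rownames(presence_filter(make_matrix(ab))$abundance)
  # oracle: count distinct experiments with any observed value, per pattern
  oracle_keep <- vapply(seq_len(nrow(patterns)), function(k)
    length(unique(exper[unlist(patterns[k, ])])) >= 2, logical(1))
  expect_setequal(kept, rownames(ab)[oracle_keep])

  # single-experiment protein dropped, two-experiment bait-only kept
  ab2 <- matrix(NA_real_, 2, 6, dimnames = list(c("only1", "bait13"), cols))
  ab2["only1", c("e1.bait", "e1.control")] <- 5
  ab2["bait13", c("e1.bait", "e3.bait")] <- 5
  kept2 <- rownames(presence_filter(make_matrix(ab2))$abundance)
  expect_equal(kept2, "bait13")
})

test_that("imputation fills missing cells with the experiment minimum", {
  cols <- c("e1.bait", "e1.control", "e2.bait", "e2.control")
  ab <- matrix(c(10, 8.1, 9, 12,
                 NA, 7.2, 11, NA), 2, 4, byrow = TRUE,
               dimnames = list(c("A", "B"), cols))
  mat <- make_matrix(ab)
  mat$stage <- "filtered"
  imp <- impute_missing(mat)
  expect_equal(unname(imp$abundance["B", "e1.bait"]), 7.2)   # min of exp 1
  expect_equal(unname(imp$abundance["B", "e2.control"]), 9)  # min of exp 2
  # observed values untouched; per-experiment minimum unchanged
  expect_equal(imp$abundance["A", ], ab["A", ])
  expect_equal(min(imp$abundance[, 1:2]), min(ab[, 1:2], na.rm = TRUE))

  # identity on complete data
  full <- make_matrix(matrix(1:8 + 0.5, 2, 4, dimnames = list(c("A", "B"), cols)))
  full$stage <- "filtered"
  expect_equal(impute_missing(full)$abundance, full$abundance)
})

test_that("log2 ratios are bait/control per experiment and antisymmetric", {
  cols <- c("e1.bait", "e1.control")
  ab <- matrix(c(8, 2), 1, 2, dimnames = list("A", cols))
  mat <- make_matrix(ab); mat$stage <- "imputed"
  r <- log2_ratios(mat)
  expect_equal(r$log2_R1, 2)

  swapped <- matrix(c(2, 8), 1, 2, dimnames = list("A", cols))
  ms <- make_matrix(swapped); ms$stage <- "imputed"
  expect_equal(log2_ratios(ms)$log2_R1, -r$log2_R1)

  eq <- make_matrix(matrix(c(5, 5), 1, 2, dimnames = list("A", cols)))
  eq$stage <- "imputed"
  expect_equal(log2_ratios(eq)$log2_R1, 0)
})

test_that("pipeline order is enforced", {
  cols <- c("e1.bait", "e1.control", "e2.bait", "e2.control")
  mat <- make_matrix(matrix(2, 2, 4, dimnames = list(c("A", "B"), cols)))
  expect_error(impute_missing(mat), "expected stage 'filtered'")
  expect_error(log2_ratios(mat), "expected stage 'imputed'")
  expect_error(presence_filter(impute_missing(presence_filter(mat))),
               "expected stage 'raw'")
  # the correct order runs through
  expect_s3_class(log2_ratios(impute_missing(presence_filter(mat))),
                  "enrichment_result")
})

test_that("enrichment call uses an inclusive >= 2-fold boundary in all experiments", {
  df <- data.frame(gene_symbol = c("at", "just_below", "one_low"),
                   log2_R1 = c(1.0, 1.0, 5.0),
                   log2_R2 = c(1.0, 1.0, 5.0),
                   log2_R3 = c(1.0, 0.999, 0.5))
  res <- call_enriched(enrichment_from_ratios(df))
  expect_equal(res$enriched, c(TRUE, FALSE, FALSE))
})

test_that("enrichment call is invariant under per-experiment rescaling", {
  pep <- simulate_coip(n_proteins = 40,
                       spiked = list(SPK1 = c(8, 8, 8), SPK2 = c(6, 5, 7)),
                       seed = 12)
  mat <- top3_abundance(pep)
  res1 <- coip_enrichment_chain(mat)
  # multiply all abundances of experiment 2 by a constant
  mat2 <- mat
  cols2 <- grep("^e2\\.", colnames(mat2$abundance))
  mat2$abundance[, cols2] <- mat2$abundance[, cols2] * 37
  res2 <- coip_enrichment_chain(mat2)
  expect_equal(res2$enriched, res1$enriched)
})

test_that("spiked proteins >= 4-fold are recovered exactly on synthetic tables", {
  for (seed in 1:20) {
    spiked <- list(SPK1 = c(4, 5, 4.5), SPK2 = c(8, 8, 8), SPK3 = c(16, 6, 4))
    pep <- simulate_coip(n_proteins = 60, spiked = spiked, seed = seed)
    res <- call_enriched(log2_ratios(impute_missing(presence_filter(
      top3_abundance(pep)))), fold_threshold = 2)
    expect_setequal(res$gene_symbol[res$enriched], names(spiked))
  }
})

test_that("the packaged worked-example table reproduces its printed ratios", {
  t3 <- load_table3()
  expect_equal(nrow(t3), 12)
  # spot-check bit-for-bit parsing, including the comma-decimal cell
  atp <- t3[t3$gene_symbol == "ATP6AP2", ]
  expect_identical(atp$log2_R1, 6.154281057)
  expect_identical(atp$log2_R2, 9.481786693)
  expect_identical(atp$log2_R3, 5.17436482)
  bait <- t3[t3$gene_symbol == "CG31030", ]
  expect_identical(bait$log2_R3, 5.19465574)

  res <- annotate_vatpase(call_enriched(t3))
  expect_equal(sum(res$enriched), 12)
  expect_equal(attr(res, "n_vatpase_nonbait"), 3)
  expect_setequal(res$gene_symbol[res$is_vatpase],
                  c("ATP6AP2", "Vha100-1", "VhaAC39-1"))
  expect_true(res$is_bait[res$gene_symbol == "CG31030"])
  expect_false(res$is_vatpase[res$gene_symbol == "CG31030"])
  # empty gene list: nothing flagged
  res0 <- annotate_vatpase(call_enriched(t3), subunit_genes = character(0))
  expect_equal(sum(res0$is_vatpase), 0)
})
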