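test_that("CSR curve of uniform counts is the diagonal: AUC 0.5, P50 50", {
  sc <- scaffold_counts_from_table(stats::setNames(rep(1L, 100),
                                                   sprintf("S%03d", 1:100)))
  cv <- csr_curve(sc)
  expect_equal(cv$auc, 0.5)
  expect_equal(cv$p50, 50)
  expect_equal(cv$points[1, ], data.frame(pct_scaffolds = 0, pct_compounds = 0))
  expect_equal(unlist(cv$points[nrow(cv$points), ], use.names = FALSE),
               c(100, 100))
})

test_that("CSR curve matches hand-computed two-scaffold example", {
  cv <- csr_curve(scaffold_counts_from_table(c(A = 9, B = 1)))
  expect_equal(cv$points$pct_scaffolds, c(0, 50, 100))
  expect_equal(cv$points$pct_compounds, c(0, 90, 100))
  expect_equal(cv$auc, 0.70)                    # 0.25*(0+.9) + 0.25*(.9+1)
  expect_equal(cv$p50, 50 * 50 / 90, tolerance = 1e-10)  # 27.78

  # degenerate single scaffold: straight line to (100, 100)
  cv1 <- csr_curve(scaffold_counts_from_table(c(A = 1)))
  expect_equal(cv1$auc, 0.5)
})

test_that("trapezoid AUC equals an independent summation on random tables", {
  set.seed(101)
  for (rep in 1:25) {
    counts <- sample.int(30, sample(2:15, 1), replace = TRUE)
    names(counts) <- sprintf("S%02d", seq_along(counts))
    cv <- csr_curve(scaffold_counts_from_table(counts))
    expect_equal(cv$auc, oracle_csr_auc(counts), tolerance = 1e-12)
    expect_gte(cv$auc, 0.5 - 1e-12)
    expect_lte(cv$auc, 1)
    expect_gt(cv$p50, 0)
    expect_lte(cv$p50, 50 + 1e-12)
    # curve monotone non-decreasing in both axes
    expect_true(all(diff(cv$points$pct_scaffolds) >= 0))
    expect_true(all(diff(cv$points$pct_compounds) >= 0))
  }
})

test_that("AUC is 0.5 exactly iff all scaffold counts are equal", {
  expect_equal(csr_curve(scaffold_counts_from_table(c(A = 7, B = 7, C = 7)))$auc,
               0.5)
  expect_gt(csr_curve(scaffold_counts_from_table(c(A = 8, B = 7, C = 6)))$auc,
            0.5)
})

test_that("SSE hits its analytic extremes", {
  even <- scaffold_counts_from_table(c(A = 4, B = 4, C = 4, D = 4, E = 4))
  expect_equal(as.numeric(sse(even, 5)), 1)
  single <- scaffold_counts_from_table(c(A = 20))
  expect_equal(as.numeric(sse(single, 5)), 0)
  expect_true(isTRUE(attr(sse(single, 5), "truncated")))
  expect_error(sse(even, 1), ">= 2")
})

test_that("SSE matches hand evaluation and is relabel-invariant", {
  sc <- scaffold_counts_from_table(c(A = 8, B = 4, C = 2, D = 1, E = 1))
  p <- c(8, 4, 2, 1, 1) / 16
  se_hand <- -sum(p * log2(p))           # = 1.875
  expect_equal(se_hand, 1.875)
  expect_equal(as.numeric(sse(sc, 5)), 1.875 / log2(5), tolerance = 1e-12)

  relabeled <- scaffold_counts_from_table(c(Z = 8, Q = 4, W = 2, X = 1, Y = 1))
  expect_equal(as.numeric(sse(relabeled, 5)), as.numeric(sse(sc, 5)))

  prof <- sse_profile(sc, c(2, 3, 5))
  expect_equal(prof$P, c(12, 14, 16))
  expect_true(all(prof$sse >= 0 & prof$sse <= 1))
})

test_that("concentrating molecules on common scaffolds lowers every diversity metric", {
  set.seed(77)
  for (rep in 1:10) {
    counts <- sort(sample.int(20, 6, replace = TRUE) + 1, decreasing = TRUE)
    names(counts) <- paste0("S", 1:6)
    moved <- counts
    moved[1] <- moved[1] + 1L   # move one molecule from rarest to commonest
    moved[6] <- moved[6] - 1L
    a0 <- csr_curve(scaffold_counts_from_table(counts))
    a1 <- csr_curve(scaffold_counts_from_table(moved))
    expect_gte(a1$auc, a0$auc - 1e-12)
    expect_lte(a1$p50, a0$p50 + 1e-12)
    expect_lte(as.numeric(sse(scaffold_counts_from_table(moved), 6)),
               as.numeric(sse(scaffold_counts_from_table(counts), 6)) + 1e-12)
  }
})

test_that("diversity summary reports census ratios at full precision", {
  sc <- scaffold_counts_from_table(c(A = 5))
  row <- diversity_summary(
    scaffold_counts_from_table(stats::setNames(c(5L), "A")))
  expect_equal(row$N_over_M, 0.2)
  expect_equal(row$Nsing_over_M, 0)
  expect_equal(row$Nsing_over_N, 0)
  expect_named(row, c("library", "M", "N", "N_sing", "N_over_M",
                      "Nsing_over_M", "Nsing_over_N", "AUC", "P50"))
})
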