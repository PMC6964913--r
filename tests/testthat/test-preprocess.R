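test_that("per-cell QC metrics follow their definitions", {
  m <- toy_counts(matrix(c(5, 5, 0, 0), nrow = 2),
                  genes = c("actb1", "mt-nd1"))
  qc <- compute_cell_qc(m)
  expect_equal(qc$n_umi, c(10L, 0L))
  expect_equal(qc$n_genes, c(2L, 0L))
  expect_equal(qc$pct_mito, c(0.5, 0))
  expect_equal(qc$flagged, c(FALSE, TRUE))  # all-zero cell flagged

  m2 <- toy_counts(matrix(c(5, 5, 1, 2), nrow = 2),
                   genes = c("actb1", "gfap"))
  expect_equal(compute_cell_qc(m2)$pct_mito, c(0, 0))
})

test_that("cell filters use inclusive bounds and the gene 5-cell rule", {
  # cells straddling the UMI bounds, one mito outlier, one gene left in
  # fewer than 5 surviving cells
  n_genes <- 600
  build_cell <- function(total) {
    v <- rep(0, n_genes)
    v[seq_len(500)] <- floor(total / 500)
    v[1] <- v[1] + total - sum(v)
    v
  }
  m <- sapply(c(999, 1000, 15000, 15001, 2000, 2000, 2000, 2000),
              build_cell)
  rownames(m) <- c(sprintf("g%03d", seq_len(n_genes - 2)), "mt-nd1", "rare")
  colnames(m) <- sprintf("c%d", 1:8)
  # cell 5 gets >6% mito; "rare" is detected in cells 5-8 only
  m["mt-nd1", 5] <- ceiling(0.07 / 0.93 * sum(m[, 5]))
  m["rare", 5:8] <- 1
  m <- toy_counts(m, genes = rownames(m), cells = colnames(m))
  th <- qc_thresholds(genes_min = 400, genes_max = 600)
  f <- filter_cells_genes(m, compute_cell_qc(m), th)
  kept <- colnames(f)
  expect_false("c1" %in% kept)  # 999 UMIs: below inclusive lower bound
  expect_true("c2" %in% kept)   # exactly 1000: kept
  expect_true("c3" %in% kept)   # exactly 15000: kept
  expect_false("c4" %in% kept)  # 15001: above upper bound
  expect_false("c5" %in% kept)  # 7% mito
  # after c5 falls, "rare" survives in 3 cells (c6-c8) < 5 -> dropped
  expect_false("rare" %in% rownames(f))
  rep <- attr(f, "qc_report")
  expect_equal(rep$cells_kept, 5)
  expect_gte(rep$genes_removed, 1)
})

test_that("filtering is idempotent", {
  fx <- default_fixture()
  once <- fx$filtered
  twice <- filter_cells_genes(once, compute_cell_qc(once))
  expect_equal(dim(twice), dim(once))
  expect_identical(as.matrix(twice), as.matrix(once))
})

test_that("thresholds violating their own invariants are rejected", {
  expect_error(qc_thresholds(umi_min = 2000, umi_max = 1000), "umi_min")
  expect_error(qc_thresholds(mito_max = 1.5), "mito_max")
})

test_that("log-normalization follows its formula and preserves structure", {
  m <- toy_counts(matrix(c(10, 9990, 0, 5, 4995, 0), nrow = 3),
                  genes = c("a", "b", "c"))
  nm <- log_normalize(m)
  # total 10,000, count 10 -> ln(1 + 1e4*10/1e4) = ln(11)
  expect_equal(nm["a", "c1"], log(11), tolerance = 1e-12)
  # proportional cell at half depth: same normalized value
  expect_equal(nm["a", "c2"], log(11), tolerance = 1e-12)
  expect_equal(nm["c", "c1"], 0)  # zero stays exactly zero
  expect_equal(length(nm@x), length(m@x))  # sparsity pattern preserved

  expect_error(log_normalize(m, scale_factor = 0), "positive")
  m0 <- toy_counts(matrix(c(1, 0), nrow = 1))
  expect_error(log_normalize(m0), "all-zero cells")
})

test_that("normalization preserves within-cell rank order of counts", {
  fx <- default_fixture()
  m <- fx$filtered[, 1:20]
  nm <- fx$nm[, 1:20]
  for (j in 1:20) {
    expect_equal(order(as.numeric(m[, j])), order(as.numeric(nm[, j])))
  }
})

test_that("variable-gene selection merges per-sample top lists", {
  fx <- default_fixture()
  # two copies of the same sample share the same top list: union == top_n
  nm <- fx$nm[, 1:400]
  labels <- rep(c("s1", "s2"), each = 200)
  nm2 <- cbind(nm[, 1:200], nm[, 1:200])
  colnames(nm2) <- sprintf("c%d", seq_len(400))
  hv_same <- select_variable_genes(nm2, labels, top_n = 100)
  expect_equal(length(hv_same), 100)
  prov <- attr(hv_same, "provenance")
  expect_identical(sort(prov$s1), sort(prov$s2))

  # markers are bimodal across types: planted high-variance genes rank high
  hv <- select_variable_genes(fx$nm, fx$cells$sample_id, top_n = 200)
  expect_true("htr1d" %in% hv)
  marker_genes <- grep("^mk\\.", rownames(fx$nm), value = TRUE)
  expect_gt(mean(marker_genes %in% hv), 0.9)

  expect_warning(select_variable_genes(fx$nm[1:50, 1:100], top_n = 100),
                 "returning all genes")
  expect_error(select_variable_genes(fx$nm, sample_labels = "s1"),
               "one entry per cell")
})
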