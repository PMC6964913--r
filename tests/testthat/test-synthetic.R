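test_that("identical seeds give bit-identical datasets", {
  d <- synthetic_design(n_genes = 200, cell_types = c(A = 30, B = 30),
                        conditions = c("control", "treat"))
  a <- simulate_dataset(d, seed = 7)
  b <- simulate_dataset(d, seed = 7)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$cells, b$cells)
  c2 <- simulate_dataset(d, seed = 8)
  expect_false(identical(as.matrix(a$counts), as.matrix(c2$counts)))
})

test_that("generator hits its expected mean in the Poisson limit", {
  d <- synthetic_design(n_genes = 150, cell_types = c(A = 10000),
                        conditions = c("control", "treat"),
                        dispersion = Inf, size_factor_shape = Inf,
                        mito_fraction_range = c(0, 0))
  d$program[, ] <- 5
  ds <- simulate_dataset(d, seed = 3)
  ctrl <- ds$cells$cell_id[ds$cells$condition == "control"]
  mt <- startsWith(rownames(ds$counts), "mt-")
  sub <- ds$counts[!mt, ctrl]
  emp <- sum(sub) / (nrow(sub) * ncol(sub))
  expect_lt(abs(emp - 5) / 5, 0.02)
})

test_that("a zero condition factor silences the gene in that type", {
  d <- synthetic_design(n_genes = 200, cell_types = c(A = 40, B = 40),
                        conditions = c("control", "treat"))
  d$program["bdnf", ] <- 5
  d$condition_effects <- rbind(
    d$condition_effects,
    data.frame(condition = "treat", cell_type = "A", gene = "bdnf",
               factor = 0, stringsAsFactors = FALSE))
  ds <- simulate_dataset(d, seed = 4)
  treat_a <- ds$cells$cell_id[ds$cells$condition == "treat" &
                                ds$cells$cluster == "A"]
  treat_b <- ds$cells$cell_id[ds$cells$condition == "treat" &
                                ds$cells$cluster == "B"]
  expect_equal(sum(ds$counts["bdnf", treat_a]), 0)
  expect_gt(sum(ds$counts["bdnf", treat_b]), 0)
})

test_that("degenerate designs are rejected", {
  expect_error(synthetic_design(n_genes = 50), "too small")
  d <- synthetic_design(n_genes = 200, cell_types = c(A = 10, B = 10),
                        conditions = c("control", "treat"))
  d$genes <- character(0)
  expect_error(simulate_dataset(d), "zero genes")
})

test_that("planting marks exactly the requested edges in the truth ledger", {
  d <- synthetic_design()
  lose <- data.frame(source_cluster = "neuron_htr1d", ligand = "bdnf",
                     receptor = "ngfra", target_cluster = "PC2",
                     stringsAsFactors = FALSE)
  d2 <- plant_differential_interactions(d, "5ht", lose = lose)
  truth <- ground_truth(d2)$differential
  lost <- truth[truth$treatment == "5ht" & truth$status == "lost", ]
  expect_true(any(lost$ligand == "bdnf" & lost$receptor == "ngfra" &
                    lost$target_cluster == "PC2"))

  gain <- data.frame(source_cluster = "immune", ligand = "il4",
                     receptor = "il4r.1", target_cluster = "PC0",
                     stringsAsFactors = FALSE)
  expect_error(
    plant_differential_interactions(d, "5ht", gain = gain, lose = gain),
    "both gained and lost")

  # empty request leaves the design unchanged
  expect_identical(plant_differential_interactions(d, "5ht"), d)

  bad <- gain; bad$ligand <- "nonexistent"
  expect_error(plant_differential_interactions(d, "5ht", gain = bad),
               "absent from lr_table")
  bad2 <- gain; bad2$source_cluster <- "nope"
  expect_error(plant_differential_interactions(d, "5ht", gain = bad2),
               "undeclared cell type")
})

test_that("ground-truth gained and lost sets are disjoint per comparison", {
  d <- synthetic_design()
  truth <- ground_truth(d)$differential
  for (tr in unique(truth$treatment)) {
    sub <- truth[truth$treatment == tr, ]
    keys <- paste(sub$source_cluster, sub$ligand, sub$receptor,
                  sub$target_cluster)
    expect_equal(anyDuplicated(keys), 0)
  }
})

test_that("fixtures round-trip through the package readers", {
  d <- synthetic_design(n_genes = 200, cell_types = c(A = 20, B = 20),
                        conditions = c("control", "treat"))
  ds <- simulate_dataset(d, seed = 9)
  dir <- withr::local_tempdir()
  paths <- write_fixture(ds, dir)
  expect_equal(length(list.files(dir)), 5)
  back <- read_mtx_triplet(file.path(dir, "matrix.mtx"),
                           file.path(dir, "features.tsv"),
                           file.path(dir, "barcodes.tsv"))
  expect_equal(as.matrix(back), as.matrix(ds$counts))
  cells <- read_cell_table(file.path(dir, "cells.tsv"))
  expect_equal(cells$cell_id, ds$cells$cell_id)
  truth <- utils::read.delim(file.path(dir, "truth_edges.tsv"))
  expect_equal(nrow(truth), nrow(ds$truth$differential))
})

test_that("designs rebuild from their YAML parameters", {
  d <- synthetic_design(n_genes = 200, cell_types = c(A = 15, B = 15),
                        conditions = c("control", "treat"), seed = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  design_to_yaml(d, path)
  d2 <- design_from_yaml(path)
  expect_identical(d2$program, d$program)
  expect_identical(d2$cell_types, d$cell_types)
  expect_identical(as.matrix(simulate_dataset(d2, seed = 1)$counts),
                   as.matrix(simulate_dataset(d, seed = 1)$counts))
})

test_that("planted DEGs are recovered from the dissected subpopulation", {
  fx <- default_fixture()
  ctrl <- fx$cells$condition == "control"
  trt <- fx$cells$condition == "5ht"
  pos_t <- select_positive_cells(fx$filtered[, trt], "htr1d")$positive
  pos_c <- select_positive_cells(fx$filtered[, ctrl], "htr1d")$positive
  degs <- find_degs(fx$nm, pos_t, pos_c)
  planted <- c(fx$design$deg_truth_genes$up, fx$design$deg_truth_genes$down)
  expect_gte(mean(planted %in% degs$gene), 0.95)
  # planted directions match the truth ledger
  truth <- fx$ds$truth$deg_lfc
  truth <- truth[truth$comparison == "5ht_vs_control" &
                   truth$gene %in% degs$gene, ]
  obs <- degs$avg_logFC[match(truth$gene, degs$gene)]
  expect_true(all(sign(obs) == sign(truth$true_lfc)))
})
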