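toy_profile <- function() {
  # cluster N expresses the ligand, P the receptor, Q neither
  data.frame(
    cluster = rep(c("N", "P", "Q"), each = 2),
    gene = rep(c("bdnf", "ntrk2"), 3),
    frac_expressing = c(0.5, 0.02, 0.05, 0.3, 0.0, 0.05),
    n_expressing = c(25L, 1L, 2L, 15L, 0L, 2L),
    mean_norm = c(1.2, 0.1, 0.1, 0.8, 0, 0.1),
    n_cells = 50L, stringsAsFactors = FALSE)
}

lr_toy <- data.frame(ligand = "bdnf", receptor = "ntrk2",
                     stringsAsFactors = FALSE)

test_that("cluster expression profiles compute fractions per cluster", {
  m <- toy_counts(matrix(c(2, 0, 1, 0, 0, 0, 3, 0, 0, 5, 0, 0), nrow = 2),
                  genes = c("bdnf", "ntrk2"))
  prof <- cluster_expression_profile(m, log1p(m),
                                     clusters = c("A", "A", "A", "A", "A",
                                                  "B"))
  a_bdnf <- prof[prof$cluster == "A" & prof$gene == "bdnf", ]
  expect_equal(a_bdnf$frac_expressing, 3 / 5)
  expect_equal(a_bdnf$n_cells, 5)
  b_ntrk2 <- prof[prof$cluster == "B" & prof$gene == "ntrk2", ]
  expect_equal(b_ntrk2$frac_expressing, 0)  # absent from cluster
  # single-cell cluster: fraction is 0 or 1
  b_bdnf <- prof[prof$cluster == "B" & prof$gene == "bdnf", ]
  expect_true(b_bdnf$frac_expressing %in% c(0, 1))
  expect_error(cluster_expression_profile(m, log1p(m),
                                          c("A", "A", "A", "A", "A", NA)),
               "unlabeled")
  expect_error(cluster_expression_profile(m, log1p(m), "A"), "one label")
})

test_that("edges require both sides to pass the expression rule", {
  e <- build_interaction_graph(toy_profile(), lr_toy)
  expect_equal(nrow(e), 1)
  expect_equal(e$source_cluster, "N")
  expect_equal(e$target_cluster, "P")
  expect_true("weight" %in% names(e))

  # receptor fraction below min_frac: no edge
  p2 <- toy_profile()
  p2$frac_expressing[p2$cluster == "P" & p2$gene == "ntrk2"] <- 0.05
  expect_equal(nrow(build_interaction_graph(p2, lr_toy)), 0)

  # a cluster expressing both ligand and receptor yields a self-edge
  p3 <- toy_profile()
  p3$frac_expressing[p3$cluster == "N" & p3$gene == "ntrk2"] <- 0.4
  p3$n_expressing[p3$cluster == "N" & p3$gene == "ntrk2"] <- 20L
  e3 <- build_interaction_graph(p3, lr_toy)
  expect_true(any(e3$source_cluster == "N" & e3$target_cluster == "N"))

  # n_expressing gate: high fraction but fewer than min_cells_expr cells
  p4 <- toy_profile()
  p4$n_expressing[p4$cluster == "P" & p4$gene == "ntrk2"] <- 2L
  expect_equal(nrow(build_interaction_graph(p4, lr_toy)), 0)
})

test_that("anchoring restricts the pair table and validates the anchor", {
  lr <- lr_demo_pairs()
  prof <- do.call(rbind, lapply(c("N", "P"), function(cl)
    data.frame(cluster = cl, gene = unique(unlist(lr[1:2])),
               frac_expressing = 0.5, n_expressing = 25L, mean_norm = 1,
               n_cells = 50L, stringsAsFactors = FALSE)))
  e_lig <- build_interaction_graph(prof, lr, anchor = "bdnf",
                                   direction = "ligand_anchored")
  expect_setequal(unique(e_lig$receptor), c("ntrk2", "ngfra"))
  e_rec <- build_interaction_graph(prof, lr, anchor = "ngfra",
                                   direction = "receptor_anchored")
  expect_equal(unique(e_rec$ligand), "bdnf")
  expect_equal(unique(e_rec$receptor), "ngfra")
  expect_error(build_interaction_graph(prof, lr, anchor = "htr1d"),
               "anchor gene not found")
})

test_that("raising min_frac never adds edges", {
  fx <- default_fixture()
  lr_genes <- unique(unlist(lr_demo_pairs()[c("ligand", "receptor")]))
  prof <- condition_profile(fx, "control", lr_genes)
  fracs <- c(0.05, 0.1, 0.25, 0.5)
  sizes <- vapply(fracs, function(fr)
    nrow(build_interaction_graph(prof, lr_demo_pairs(), min_frac = fr)),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("differential classification is exact set algebra", {
  e1 <- data.frame(source_cluster = "N", ligand = "bdnf",
                   receptor = "ntrk2", target_cluster = "P",
                   stringsAsFactors = FALSE)
  e2 <- data.frame(source_cluster = "I", ligand = "il4",
                   receptor = "il4r.1", target_cluster = "P",
                   stringsAsFactors = FALSE)
  cmp <- c("5ht", "control")
  expect_equal(classify_differential(e1, e1, cmp)$status, "unchanged")
  expect_equal(classify_differential(e1, e1[0, ], cmp)$status, "lost")
  expect_equal(classify_differential(e1[0, ], e2, cmp)$status, "gained")
  both <- classify_differential(rbind(e1, e2), e2, cmp)
  expect_setequal(both$status, c("lost", "unchanged"))

  # partition property: every edge of the union appears exactly once
  d <- classify_differential(rbind(e1, e2), rbind(e2, e1, e1), cmp)
  keys <- paste(d$source_cluster, d$ligand, d$receptor, d$target_cluster)
  expect_equal(anyDuplicated(keys), 0)
  expect_equal(nrow(d), 2)
  # order independence
  d2 <- classify_differential(rbind(e2, e1), rbind(e1, e2), cmp)
  expect_identical(d[order(keys), ], d2[order(paste(
    d2$source_cluster, d2$ligand, d2$receptor, d2$target_cluster)), ])
})

test_that("target clusters are ranked by incoming arrows", {
  d <- data.frame(
    source_cluster = c("N", "N", "I", "O"),
    ligand = "bdnf", receptor = "ngfra",
    target_cluster = c("PC0", "PC0", "PC0", "PC2"),
    status = c("gained", "gained", "gained", "lost"),
    stringsAsFactors = FALSE)
  r <- rank_target_clusters(d)
  expect_equal(r$target_cluster[1], "PC0")
  expect_equal(r$gained[1], 3)
  expect_equal(r$total, c(3, 1))
  expect_equal(nrow(rank_target_clusters(d[0, ])), 0)
})

test_that("planted gains concentrate on the planted target cluster", {
  fx <- default_fixture()
  truth <- fx$ds$truth$differential
  il4_diff <- truth[truth$treatment == "il4", ]
  r <- rank_target_clusters(il4_diff[il4_diff$status == "gained", ])
  expect_true(r$target_cluster[1] %in% c("PC0", "PC2"))
})
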