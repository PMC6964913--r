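# shared fixtures, built once per test session

.fixture_env <- new.env(parent = emptyenv())

# the default demo dataset: 5 clusters x 4 conditions, planted effects
default_fixture <- function() {
  if (is.null(.fixture_env$fx)) {
    design <- synthetic_design()
    ds <- simulate_dataset(design, seed = 20200106)
    filtered <- filter_cells_genes(ds$counts)
    nm <- log_normalize(filtered)
    cells <- ds$cells[match(colnames(filtered), ds$cells$cell_id), ]
    .fixture_env$fx <- list(design = design, ds = ds, filtered = filtered,
                            nm = nm, cells = cells)
  }
  .fixture_env$fx
}

# small well-separated 3-type design for classifier tests
transfer_fixture <- function() {
  if (is.null(.fixture_env$tf)) {
    d <- synthetic_design(n_genes = 600,
                          cell_types = c(A = 200, B = 200, C = 200),
                          conditions = c("control", "treat"))
    ref <- simulate_dataset(d, seed = 11)
    query <- simulate_dataset(d, seed = 22)
    .fixture_env$tf <- list(design = d, ref = ref, query = query,
                            nm_ref = log_normalize(ref$counts),
                            nm_query = log_normalize(query$counts))
  }
  .fixture_env$tf
}

# build a small dense count matrix with names
toy_counts <- function(mat, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(mat)))
  if (is.null(cells)) cells <- sprintf("c%d", seq_len(ncol(mat)))
  dimnames(mat) <- list(genes, cells)
  methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix")
}

# subset helpers for condition-wise pipeline stages
condition_cells <- function(fx, condition) {
  fx$cells$cell_id[fx$cells$condition == condition]
}

condition_profile <- function(fx, condition, genes) {
  idx <- fx$cells$condition == condition
  cluster_expression_profile(fx$filtered[, idx], fx$nm[, idx],
                             fx$cells$cluster[idx], genes = genes)
}
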