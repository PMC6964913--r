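#' Quality-control thresholds
#'
#' Default cell/gene filters: cells kept with 1,000-15,000 UMIs and
#' 500-2,500 detected genes (closed intervals) and at most 6 percent
#' mitochondrial counts; genes kept when detected in at least 5 surviving
#' cells. All bounds are overridable.
#'
#' @param umi_min,umi_max Inclusive bounds on per-cell total UMIs.
#' @param genes_min,genes_max Inclusive bounds on detected genes per cell.
#' @param mito_max Maximum mitochondrial count fraction (0-1).
#' @param min_cells_per_gene Minimum surviving cells a gene must be
#'   detected in.
#' @return A list of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(umi_min = 1000, umi_max = 15000,
                          genes_min = 500, genes_max = 2500,
                          mito_max = 0.06, min_cells_per_gene = 5) {
  if (umi_min > umi_max) stop("umi_min must not exceed umi_max")
  if (genes_min > genes_max) stop("genes_min must not exceed genes_max")
  if (mito_max < 0 || mito_max > 1) stop("mito_max must lie in [0, 1]")
  structure(list(umi_min = umi_min, umi_max = umi_max,
                 genes_min = genes_min, genes_max = genes_max,
                 mito_max = mito_max,
                 min_cells_per_gene = min_cells_per_gene),
            class = "qc_thresholds")
}

#' Per-cell quality-control metrics
#'
#' Computes total UMIs, detected genes and the mitochondrial count
#' fraction per cell. Mitochondrial genes are identified by symbol prefix.
#' Cells with zero total counts get \code{pct_mito = 0} and are flagged.
#'
#' @param m Count matrix.
#' @param mito_prefix Gene-symbol prefix marking mitochondrial genes.
#' @return Data.frame with columns cell_id, n_umi, n_genes, pct_mito,
#'   flagged.
#' @export
compute_cell_qc <- function(m, mito_prefix = "mt-") {
  m <- validate_count_matrix(m)
  if (ncol(m) == 0 || nrow(m) == 0) stop("empty count matrix")
  n_umi <- Matrix::colSums(m)
  n_genes <- Matrix::colSums(m > 0)
  mito <- startsWith(rownames(m), mito_prefix)
  mito_counts <- if (any(mito)) Matrix::colSums(m[mito, , drop = FALSE])
                 else rep(0, ncol(m))
  pct_mito <- ifelse(n_umi > 0, mito_counts / n_umi, 0)
  data.frame(cell_id = colnames(m), n_umi = as.integer(n_umi),
             n_genes = as.integer(n_genes), pct_mito = pct_mito,
             flagged = n_umi == 0, stringsAsFactors = FALSE)
}

#' Filter cells and genes on QC metrics
#'
#' Keeps cells inside the UMI, detected-gene and mitochondrial bounds, then
#' drops genes detected in fewer than \code{min_cells_per_gene} of the
#' surviving cells. The operation is idempotent. A per-rule removal report
#' is attached as attribute \code{"qc_report"}.
#'
#' @param m Count matrix.
#' @param qc Output of \code{\link{compute_cell_qc}} on \code{m}.
#' @param thresholds A \code{\link{qc_thresholds}} object.
#' @return Filtered count matrix.
#' @export
filter_cells_genes <- function(m, qc = compute_cell_qc(m),
                               thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  m <- validate_count_matrix(m)
  qc <- qc[match(colnames(m), qc$cell_id), , drop = FALSE]
  if (anyNA(qc$cell_id)) stop("qc table does not cover all matrix cells")
  ok_umi <- qc$n_umi >= thresholds$umi_min & qc$n_umi <= thresholds$umi_max
  ok_genes <- qc$n_genes >= thresholds$genes_min &
    qc$n_genes <= thresholds$genes_max
  ok_mito <- qc$pct_mito <= thresholds$mito_max
  keep_cells <- ok_umi & ok_genes & ok_mito
  out <- m[, keep_cells, drop = FALSE]
  cells_detected <- Matrix::rowSums(out > 0)
  keep_genes <- cells_detected >= thresholds$min_cells_per_gene
  out <- out[keep_genes, , drop = FALSE]
  attr(out, "qc_report") <- list(
    removed_umi = sum(!ok_umi),
    removed_genes_per_cell = sum(ok_umi & !ok_genes),
    removed_mito = sum(ok_umi & ok_genes & !ok_mito),
    cells_kept = sum(keep_cells),
    genes_removed = sum(!keep_genes),
    genes_kept = sum(keep_genes))
  out
}

#' Log-normalize a count matrix
#'
#' value(g, c) = ln(1 + scale_factor * count(g, c) / total(c)); the
#' sparsity pattern is preserved (zeros map to zero exactly).
#'
#' @param m Count matrix with no all-zero cells (filter first).
#' @param scale_factor Library-size scale factor (default 1e4).
#' @return Sparse normalized matrix with the same dimnames.
#' @export
log_normalize <- function(m, scale_factor = 1e4) {
  if (scale_factor <= 0) stop("scale_factor must be positive")
  m <- validate_count_matrix(m)
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) stop("all-zero cells present; filter before normalizing")
  nm <- m
  # per-entry division by the column total, then log1p, nonzeros only
  nm@x <- log1p(scale_factor * m@x / rep.int(totals, diff(m@p)))
  nm
}

#' Select highly variable genes per sample and merge
#'
#' Per sample, genes are ranked by the dispersion (variance/mean) of the
#' de-logged normalized expression, z-scored within 20 equal-frequency
#' mean bins; the top \code{top_n} from each sample are merged.
#'
#' @param nm Normalized matrix (\code{\link{log_normalize}}).
#' @param sample_labels Per-cell sample labels (one sample if \code{NULL}).
#' @param top_n Genes to take per sample (default 1,000).
#' @param n_bins Mean bins used for the dispersion z-score.
#' @return Character vector of the merged gene union; attribute
#'   \code{"provenance"} maps each sample to its selected genes.
#' @export
select_variable_genes <- function(nm, sample_labels = NULL, top_n = 1000,
                                  n_bins = 20) {
  nm <- methods::as(nm, "CsparseMatrix")
  if (is.null(sample_labels)) sample_labels <- rep("sample", ncol(nm))
  if (length(sample_labels) != ncol(nm))
    stop("sample_labels must have one entry per cell")
  if (top_n > nrow(nm)) {
    warning("top_n exceeds gene count; returning all genes")
    top_n <- nrow(nm)
  }
  per_sample <- lapply(split(seq_len(ncol(nm)), sample_labels), function(idx) {
    x <- expm1(nm[, idx, drop = FALSE])
    mu <- Matrix::rowMeans(x)
    v <- Matrix::rowMeans(x^2) - mu^2
    disp <- ifelse(mu > 0, v / mu, NA_real_)
    usable <- which(!is.na(disp) & is.finite(disp))
    bins <- cut(rank(mu[usable], ties.method = "first"),
                breaks = min(n_bins, length(usable)), labels = FALSE)
    z <- disp[usable]
    for (b in unique(bins)) {
      in_b <- bins == b
      s <- stats::sd(z[in_b])
      z[in_b] <- if (is.na(s) || s == 0) 0 else
        (z[in_b] - mean(z[in_b])) / s
    }
    ord <- usable[order(z, decreasing = TRUE)]
    rownames(nm)[utils::head(ord, top_n)]
  })
  merged <- unique(unlist(per_sample, use.names = FALSE))
  attr(merged, "provenance") <- per_sample
  merged
}
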