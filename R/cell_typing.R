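#' One-vs-rest marker genes per cluster
#'
#' Tests every sufficiently expressed gene cluster-vs-rest with the
#' rank-sum test, computes the average log fold change and expressing
#' fractions, and applies Benjamini-Hochberg FDR within each cluster's
#' test family. Only positive markers (elevated in-cluster) are reported:
#' identity transfer needs positive features. Clusters with fewer than
#' \code{min_cells} cells are skipped with a warning.
#'
#' @param nm Normalized matrix.
#' @param clusters Per-cell cluster labels (aligned to \code{colnames(nm)}).
#' @param min_cells Minimum cluster size to test (default 3).
#' @param min_pct Minimum expressing fraction in- or out-of-cluster.
#' @return Data.frame with columns cluster, gene, avg_logFC, p, fdr,
#'   pct_in, pct_out, sorted within cluster by avg_logFC descending
#'   (ties: lower p, then gene symbol).
#' @export
find_markers <- function(nm, clusters, min_cells = 3, min_pct = 0.1) {
  nm <- methods::as(nm, "CsparseMatrix")
  if (length(clusters) != ncol(nm))
    stop("clusters must have one label per cell")
  clusters <- as.character(clusters)
  sizes <- table(clusters)
  usable <- names(sizes)[sizes >= min_cells]
  skipped <- setdiff(names(sizes), usable)
  if (length(skipped))
    warning("clusters below ", min_cells, " cells skipped: ",
            paste(skipped, collapse = ", "))
  if (length(usable) < 2)
    stop("need at least 2 clusters with >= ", min_cells, " cells")
  out <- lapply(usable, function(cl) {
    in_cells <- colnames(nm)[clusters == cl]
    out_cells <- colnames(nm)[clusters != cl]
    degs <- find_degs(nm, in_cells, out_cells, p_max = 1.01, lfc_min = 0,
                      min_cells = min_cells, min_pct = min_pct)
    degs <- degs[degs$avg_logFC > 0 | degs$pct_1 > degs$pct_2, , drop = FALSE]
    if (nrow(degs) == 0) return(NULL)
    data.frame(cluster = cl, gene = degs$gene, avg_logFC = degs$avg_logFC,
               p = degs$p, fdr = stats::p.adjust(degs$p, method = "BH"),
               pct_in = degs$pct_1, pct_out = degs$pct_2,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(cluster = character(), gene = character(),
                      avg_logFC = numeric(), p = numeric(),
                      fdr = numeric(), pct_in = numeric(),
                      pct_out = numeric(), stringsAsFactors = FALSE))
  res <- res[order(res$cluster, -res$avg_logFC, res$p, res$gene), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

top_markers <- function(markers, top_k = 5, fdr_max = 0.1) {
  sig <- markers[markers$fdr < fdr_max & markers$avg_logFC > 0, ,
                 drop = FALSE]
  sig <- sig[order(sig$cluster, -sig$avg_logFC, sig$p, sig$gene), ,
             drop = FALSE]
  do.call(rbind, lapply(split(sig, sig$cluster), utils::head, top_k))
}

#' Train a cell-type label-transfer classifier
#'
#' Collects the union of each reference cluster's top-\code{top_k} markers
#' (ranked by avg_logFC among those with FDR < 0.1) and fits a seeded
#' random forest (500 trees, class-balanced bootstrap) on the reference
#' cells' normalized expression over those features. Clusters without a
#' qualifying marker remain classes, represented by the other clusters'
#' features (with a warning).
#'
#' @param nm_ref Reference normalized matrix.
#' @param clusters Reference per-cell cluster labels.
#' @param top_k Markers per cluster (default 5).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param n_trees Forest size (default 500).
#' @param fdr_max Marker qualification cutoff (default 0.1).
#' @return Object of class \code{label_transfer_model} with elements
#'   \code{feature_genes}, \code{forest}, \code{classes}, \code{seed}.
#' @export
train_label_transfer <- function(nm_ref, clusters, top_k = 5, seed = 1L,
                                 n_trees = 500, fdr_max = 0.1) {
  stopifnot(top_k >= 1)
  clusters <- as.character(clusters)
  if (length(unique(clusters)) < 2)
    stop("label transfer needs at least 2 reference classes")
  markers <- find_markers(nm_ref, clusters)
  top <- top_markers(markers, top_k = top_k, fdr_max = fdr_max)
  no_marker <- setdiff(unique(clusters), unique(top$cluster))
  if (length(no_marker))
    warning("no qualifying markers for cluster(s): ",
            paste(no_marker, collapse = ", "))
  features <- sort(unique(top$gene))
  if (length(features) == 0) stop("no cluster yielded a qualifying marker")
  x <- t(as.matrix(nm_ref[features, , drop = FALSE]))
  y <- factor(clusters)
  n_min <- min(table(y))
  set.seed(seed)
  forest <- randomForest::randomForest(
    x = x, y = y, ntree = n_trees,
    strata = y, sampsize = rep(n_min, nlevels(y)))
  structure(list(feature_genes = features, forest = forest,
                 classes = levels(y), seed = as.integer(seed)),
            class = "label_transfer_model")
}

#' Predict cell-type labels for a query sample
#'
#' Applies a trained \code{\link{train_label_transfer}} model to the query
#' cells' normalized expression over the model's feature genes. Feature
#' genes missing from the query are imputed as zero with a warning.
#' Confidence is the ensemble vote fraction of the winning class; all-zero
#' query cells are flagged.
#'
#' @param model A \code{label_transfer_model}.
#' @param nm_query Query normalized matrix.
#' @return Data.frame with columns cell_id, label, confidence, flagged.
#' @export
predict_labels <- function(model, nm_query) {
  stopifnot(inherits(model, "label_transfer_model"))
  if (ncol(nm_query) == 0)
    return(data.frame(cell_id = character(), label = character(),
                      confidence = numeric(), flagged = logical(),
                      stringsAsFactors = FALSE))
  feats <- model$feature_genes
  missing <- setdiff(feats, rownames(nm_query))
  x <- matrix(0, nrow = ncol(nm_query), ncol = length(feats),
              dimnames = list(colnames(nm_query), feats))
  present <- setdiff(feats, missing)
  if (length(missing))
    warning(length(missing), " feature gene(s) absent from query, ",
            "imputed as zero: ", paste(utils::head(missing, 5),
                                       collapse = ", "))
  x[, present] <- t(as.matrix(nm_query[present, , drop = FALSE]))
  votes <- stats::predict(model$forest, newdata = x, type = "vote")
  label <- colnames(votes)[max.col(votes, ties.method = "first")]
  confidence <- votes[cbind(seq_len(nrow(votes)),
                            max.col(votes, ties.method = "first"))]
  data.frame(cell_id = colnames(nm_query), label = label,
             confidence = as.numeric(confidence),
             flagged = rowSums(x) == 0,
             stringsAsFactors = FALSE, row.names = NULL)
}
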