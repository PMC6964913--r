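#' Cluster-level expression profile of ligand/receptor genes
#'
#' For every (cluster, gene) pair over the genes of interest, computes the
#' fraction of cells with a nonzero raw count, the mean normalized
#' expression and the cluster size.
#'
#' @param m Count matrix.
#' @param nm Matching normalized matrix.
#' @param clusters Per-cell cluster labels (all cells must be labeled).
#' @param genes Genes to profile (default: all genes of \code{m}; pass the
#'   ligand-receptor universe for interaction mapping).
#' @return Data.frame with columns cluster, gene, frac_expressing,
#'   n_expressing, mean_norm, n_cells.
#' @export
cluster_expression_profile <- function(m, nm, clusters,
                                       genes = rownames(m)) {
  m <- validate_count_matrix(m)
  if (length(clusters) != ncol(m))
    stop("clusters must have one label per cell")
  if (anyNA(clusters) || any(!nzchar(as.character(clusters))))
    stop("unlabeled cells present")
  genes <- intersect(genes, rownames(m))
  clusters <- as.character(clusters)
  out <- lapply(unique(clusters), function(cl) {
    idx <- which(clusters == cl)
    sub <- m[genes, idx, drop = FALSE]
    nsub <- nm[genes, idx, drop = FALSE]
    data.frame(cluster = cl, gene = genes,
               frac_expressing = as.numeric(Matrix::rowMeans(sub > 0)),
               n_expressing = as.integer(Matrix::rowSums(sub > 0)),
               mean_norm = as.numeric(Matrix::rowMeans(nsub)),
               n_cells = length(idx),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

profile_lookup <- function(profile, cluster, gene, col) {
  i <- profile$cluster == cluster & profile$gene == gene
  if (!any(i)) return(0)
  profile[[col]][which(i)[1]]
}

#' Build a per-condition ligand-receptor interaction graph
#'
#' Emits a directed edge (A, L, R, B) whenever cluster A expresses the
#' ligand L and cluster B expresses its cognate receptor R, where a
#' cluster "expresses" a gene iff its expressing fraction is at least
#' \code{min_frac} and at least \code{min_cells_expr} of its cells are
#' positive. Self-edges (A = B) are allowed. Anchoring restricts the pair
#' table to one gene: \code{ligand_anchored} takes all receptors of an
#' anchor ligand, \code{receptor_anchored} all ligands of an anchor
#' receptor; with \code{anchor = NULL} all pairs are used. A mean-
#' expression edge weight is emitted as an auxiliary column but plays no
#' role in edge calls or classification.
#'
#' @param profile Output of \code{\link{cluster_expression_profile}}.
#' @param lr Ligand-receptor pair table.
#' @param min_frac Minimum expressing fraction (default 0.1).
#' @param min_cells_expr Minimum expressing cells (default 3).
#' @param direction "ligand_anchored" or "receptor_anchored".
#' @param anchor Anchor gene symbol, or \code{NULL} for all pairs.
#' @param condition Optional condition label copied onto the edges.
#' @return Data.frame of edges (source_cluster, ligand, receptor,
#'   target_cluster, condition, weight).
#' @export
build_interaction_graph <- function(profile, lr, min_frac = 0.1,
                                    min_cells_expr = 3,
                                    direction = c("ligand_anchored",
                                                  "receptor_anchored"),
                                    anchor = NULL, condition = NA_character_) {
  direction <- match.arg(direction)
  lr <- validate_lr_table(lr)
  if (nrow(profile) == 0 || nrow(lr) == 0)
    stop("profile and ligand-receptor table must be nonempty")
  if (!is.null(anchor)) {
    lr <- if (direction == "ligand_anchored")
      lr[lr$ligand == anchor, , drop = FALSE]
    else lr[lr$receptor == anchor, , drop = FALSE]
    if (nrow(lr) == 0)
      stop("anchor gene not found in the ligand-receptor table as ",
           if (direction == "ligand_anchored") "a ligand: " else
             "a receptor: ", anchor)
  }
  expressing <- profile$frac_expressing >= min_frac &
    profile$n_expressing >= min_cells_expr
  clusters <- unique(profile$cluster)
  edges <- list(); k <- 0
  for (i in seq_len(nrow(lr))) {
    src <- clusters[vapply(clusters, function(cl) any(
      expressing & profile$cluster == cl & profile$gene == lr$ligand[i]),
      logical(1))]
    tgt <- clusters[vapply(clusters, function(cl) any(
      expressing & profile$cluster == cl & profile$gene == lr$receptor[i]),
      logical(1))]
    if (length(src) && length(tgt)) {
      grid <- expand.grid(source_cluster = src, target_cluster = tgt,
                          stringsAsFactors = FALSE)
      w <- vapply(seq_len(nrow(grid)), function(j) mean(c(
        profile_lookup(profile, grid$source_cluster[j], lr$ligand[i],
                       "mean_norm"),
        profile_lookup(profile, grid$target_cluster[j], lr$receptor[i],
                       "mean_norm"))), numeric(1))
      k <- k + 1
      edges[[k]] <- data.frame(source_cluster = grid$source_cluster,
                               ligand = lr$ligand[i],
                               receptor = lr$receptor[i],
                               target_cluster = grid$target_cluster,
                               condition = condition, weight = w,
                               stringsAsFactors = FALSE)
    }
  }
  if (k == 0)
    return(data.frame(source_cluster = character(), ligand = character(),
                      receptor = character(), target_cluster = character(),
                      condition = character(), weight = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, edges)
  rownames(res) <- NULL
  res
}

edge_key <- function(edges) {
  if (nrow(edges) == 0) return(character())
  paste(edges$source_cluster, edges$ligand, edges$receptor,
        edges$target_cluster, sep = "\r")
}

#' Classify interactions as unchanged, lost or gained
#'
#' Set algebra over the control and treatment edge lists: an edge active in
#' both conditions is unchanged (rendered black), active in the control
#' only is lost (cyan), active in the treatment only is gained (magenta).
#' Every edge of the union appears exactly once; output is deterministic
#' and independent of input order.
#'
#' @param control_edges,treatment_edges Edge tables from
#'   \code{\link{build_interaction_graph}} over the same pair table and
#'   cluster universe.
#' @param comparison Length-2 character vector (treatment, control).
#' @return Data.frame with edge columns plus status, treatment, control.
#' @export
classify_differential <- function(control_edges, treatment_edges,
                                  comparison) {
  stopifnot(length(comparison) == 2)
  kc <- unique(edge_key(control_edges))
  kt <- unique(edge_key(treatment_edges))
  all_keys <- sort(unique(c(kc, kt)))
  status <- ifelse(all_keys %in% kc & all_keys %in% kt, "unchanged",
                   ifelse(all_keys %in% kc, "lost", "gained"))
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  res <- data.frame(
    source_cluster = if (length(all_keys)) parts[, 1] else character(),
    ligand = if (length(all_keys)) parts[, 2] else character(),
    receptor = if (length(all_keys)) parts[, 3] else character(),
    target_cluster = if (length(all_keys)) parts[, 4] else character(),
    status = status,
    treatment = rep(comparison[1], length(all_keys)),
    control = rep(comparison[2], length(all_keys)),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Rank target clusters by incoming differential edges
#'
#' Counts, per target cluster, the incoming edges of each status and sorts
#' by total descending -- the "most arrows pointing toward them" summary
#' identifying the hub clusters of an interaction map.
#'
#' @param diff_edges Output of \code{\link{classify_differential}}.
#' @return Data.frame with columns target_cluster, unchanged, lost,
#'   gained, total.
#' @export
rank_target_clusters <- function(diff_edges) {
  if (nrow(diff_edges) == 0)
    return(data.frame(target_cluster = character(), unchanged = integer(),
                      lost = integer(), gained = integer(),
                      total = integer(), stringsAsFactors = FALSE))
  tab <- table(diff_edges$target_cluster,
               factor(diff_edges$status,
                      levels = c("unchanged", "lost", "gained")))
  res <- data.frame(target_cluster = rownames(tab),
                    unchanged = as.integer(tab[, "unchanged"]),
                    lost = as.integer(tab[, "lost"]),
                    gained = as.integer(tab[, "gained"]),
                    stringsAsFactors = FALSE)
  res$total <- res$unchanged + res$lost + res$gained
  res <- res[order(-res$total, res$target_cluster), , drop = FALSE]
  rownames(res) <- NULL
  res
}
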