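#' Dissect the cells positive for a gene
#'
#' In-silico dissection: the positive set is all cells with a nonzero raw
#' count of \code{gene}, optionally intersected with a cell scope (e.g.
#' the progenitor clusters); the complement within the scope is returned
#' alongside.
#'
#' @param m Count matrix.
#' @param gene Gene symbol (case-sensitive).
#' @param cell_scope Optional character vector of cell ids to restrict to.
#' @return List with \code{positive} and \code{negative} cell-id vectors.
#' @export
select_positive_cells <- function(m, gene, cell_scope = NULL) {
  m <- validate_count_matrix(m)
  if (!gene %in% rownames(m)) stop("gene not present in matrix: ", gene)
  scope <- if (is.null(cell_scope)) colnames(m)
           else intersect(colnames(m), cell_scope)
  v <- m[gene, scope]
  pos <- scope[v > 0]
  if (length(pos) == 0) warning("no cells positive for ", gene)
  list(positive = pos, negative = setdiff(scope, pos))
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration for small tie-free samples (n1 + n2 <= 12), normal
#' approximation with tie and continuity correction otherwise. Complete
#' ties (all values equal) return p = 1.
#'
#' @param x,y Numeric value vectors for the two groups (both nonempty).
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("both groups must be nonempty")
  if (length(unique(c(x, y))) == 1) return(1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y) <= 12)
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
  if (is.nan(p)) 1 else min(p, 1)
}

#' Average log fold change between two cell groups
#'
#' ln(mean(expm1(normalized)) + pseudocount) over group 1 minus the same
#' over group 2 -- the convention under which the 0.25 threshold of
#' \code{\link{find_degs}} is meaningful (natural-log scale).
#'
#' @param nm Normalized matrix.
#' @param group1,group2 Cell-id vectors (nonempty).
#' @param gene Gene symbol.
#' @param pseudocount Added to both de-logged means (default 1).
#' @return Natural-log fold change (group 1 over group 2).
#' @export
average_log_fc <- function(nm, group1, group2, gene, pseudocount = 1) {
  if (!gene %in% rownames(nm)) stop("gene not present in matrix: ", gene)
  if (length(group1) == 0 || length(group2) == 0)
    stop("both groups must be nonempty")
  m1 <- mean(expm1(nm[gene, group1]))
  m2 <- mean(expm1(nm[gene, group2]))
  log(m1 + pseudocount) - log(m2 + pseudocount)
}

# vectorized internals shared by find_degs and find_markers
group_stats <- function(nm, cells) {
  x <- expm1(nm[, cells, drop = FALSE])
  list(mean = Matrix::rowMeans(x),
       pct = Matrix::rowMeans(x > 0))
}

#' Thresholded differential expression between two cell groups
#'
#' Genes detected in at least \code{min_pct} of either group are tested
#' with the rank-sum test on normalized expression; records passing
#' p < \code{p_max} and |avg_logFC| >= \code{lfc_min} are returned, sorted
#' by |avg_logFC| descending. No multiple-testing correction is applied at
#' this stage.
#'
#' @param nm Normalized matrix.
#' @param group1,group2 Cell-id vectors, each of at least \code{min_cells}.
#' @param p_max Raw p-value cutoff (default 0.05).
#' @param lfc_min Minimum absolute average log fold change (default 0.25).
#' @param min_cells Minimum cells per group (default 3).
#' @param min_pct Minimum expressing fraction in either group for a gene
#'   to be tested (default 0.1; set 0 to test everything).
#' @param pseudocount Passed to the fold-change computation.
#' @return Data.frame of DEG records (gene, avg_logFC, p, pct_1, pct_2);
#'   the number of genes tested is attached as attribute \code{"n_tested"}.
#' @export
find_degs <- function(nm, group1, group2, p_max = 0.05, lfc_min = 0.25,
                      min_cells = 3, min_pct = 0.1, pseudocount = 1) {
  if (length(group1) < min_cells || length(group2) < min_cells)
    stop("each group needs at least ", min_cells, " cells")
  nm <- methods::as(nm, "CsparseMatrix")
  s1 <- group_stats(nm, group1)
  s2 <- group_stats(nm, group2)
  testable <- which(pmax(s1$pct, s2$pct) >= min_pct)
  lfc <- log(s1$mean[testable] + pseudocount) -
    log(s2$mean[testable] + pseudocount)
  sub1 <- as.matrix(nm[testable, group1, drop = FALSE])
  sub2 <- as.matrix(nm[testable, group2, drop = FALSE])
  p <- vapply(seq_along(testable), function(i)
    rank_sum_test(sub1[i, ], sub2[i, ]), numeric(1))
  res <- data.frame(gene = rownames(nm)[testable],
                    avg_logFC = lfc, p = p,
                    pct_1 = s1$pct[testable], pct_2 = s2$pct[testable],
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[res$p < p_max & abs(res$avg_logFC) >= lfc_min, , drop = FALSE]
  res <- res[order(abs(res$avg_logFC), decreasing = TRUE), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_tested") <- length(testable)
  res
}

#' Genes changing reciprocally across two treatments
#'
#' Genes present in both DEG tables with opposite-signed average log fold
#' changes -- e.g. ligands that go up after one treatment and down after
#' another in the same dissected subpopulation.
#'
#' @param table_a,table_b DEG tables from \code{\link{find_degs}} on the
#'   same subpopulation definition.
#' @return Character vector of gene symbols (possibly empty).
#' @export
reciprocal_genes <- function(table_a, table_b) {
  common <- intersect(table_a$gene, table_b$gene)
  if (length(common) == 0) return(character())
  a <- table_a$avg_logFC[match(common, table_a$gene)]
  b <- table_b$avg_logFC[match(common, table_b$gene)]
  common[sign(a) * sign(b) == -1]
}
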