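#' Overlap of two receptor-defined subpopulations
#'
#' Splits the cells positive for at least one of two genes (raw count > 0)
#' into gene-a-only, gene-b-only and double-positive compartments, with
#' percentages over that union -- e.g. how many neural-stem cells are
#' il4r-only, ngfra-only or both.
#'
#' @param m Count matrix.
#' @param gene_a,gene_b Gene symbols.
#' @param cell_scope Optional cell-id vector restricting the population
#'   (e.g. the glial clusters).
#' @return List with counts n_only_a, n_only_b, n_both and percentages
#'   pct_only_a, pct_only_b, pct_both (of the union; sums to 100).
#' @export
receptor_overlap <- function(m, gene_a, gene_b, cell_scope = NULL) {
  m <- validate_count_matrix(m)
  for (g in c(gene_a, gene_b))
    if (!g %in% rownames(m)) stop("gene not present in matrix: ", g)
  scope <- if (is.null(cell_scope)) colnames(m)
           else intersect(colnames(m), cell_scope)
  if (length(scope) == 0) stop("cell scope is empty")
  a <- scope[m[gene_a, scope] > 0]
  b <- scope[m[gene_b, scope] > 0]
  both <- intersect(a, b)
  n_both <- length(both)
  n_only_a <- length(a) - n_both
  n_only_b <- length(b) - n_both
  n_union <- n_only_a + n_only_b + n_both
  pct <- function(n) if (n_union == 0) 0 else 100 * n / n_union
  list(n_only_a = n_only_a, n_only_b = n_only_b, n_both = n_both,
       pct_only_a = pct(n_only_a), pct_only_b = pct(n_only_b),
       pct_both = pct(n_both))
}

#' Overlap of two DEG lists
#'
#' Set arithmetic over unique gene symbols; the headline percentage is
#' 100 * |A intersect B| / |A union B| (the union of unique DEGs as
#' denominator). \code{deg_overlap(a, b)} equals \code{deg_overlap(b, a)}
#' with the only-counts swapped.
#'
#' @param genes_a,genes_b Character vectors of gene symbols.
#' @return List with n_common, n_union, pct_common_of_union, n_only_a,
#'   n_only_b.
#' @export
deg_overlap <- function(genes_a, genes_b) {
  a <- unique(genes_a); b <- unique(genes_b)
  common <- intersect(a, b)
  uni <- union(a, b)
  list(n_common = length(common), n_union = length(uni),
       pct_common_of_union = if (length(uni) == 0) 0 else
         100 * length(common) / length(uni),
       n_only_a = length(setdiff(a, b)),
       n_only_b = length(setdiff(b, a)))
}

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail hypergeometric p-value per named gene set: the
#' probability of drawing at least the observed overlap when sampling the
#' study set from the universe. A generic stand-in for database-bound
#' GO/KEGG enrichment: the collection is user-supplied and the universe is
#' an explicit, logged parameter (conventionally all genes surviving QC).
#'
#' @param study Character vector of study genes (must lie in the universe).
#' @param collection Named list of character vectors (the gene sets).
#' @param universe Character vector: the gene population.
#' @param p_max Significance flag threshold (default 0.05).
#' @return Data.frame with columns set, n_set, n_overlap, p, fdr,
#'   significant, sorted by p.
#' @export
hypergeometric_ora <- function(study, collection, universe, p_max = 0.05) {
  study <- unique(study); universe <- unique(universe)
  bad <- setdiff(study, universe)
  if (length(bad))
    stop("study genes outside the universe: ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (is.null(names(collection)) || any(!nzchar(names(collection))))
    stop("collection sets must be named")
  N <- length(universe); n <- length(study)
  res <- do.call(rbind, lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(study, set))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, n_set = K, n_overlap = k, p = p,
               stringsAsFactors = FALSE)
  }))
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p < p_max
  res <- res[order(res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}
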