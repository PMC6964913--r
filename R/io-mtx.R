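#' Validate a count matrix
#'
#' Checks the invariants of the package's count container: a sparse
#' genes x cells matrix of non-negative integers with unique row
#' (gene) and column (cell) identifiers.
#'
#' @param m A \code{\link[Matrix]{dgCMatrix}} (or coercible sparse matrix)
#'   with gene symbols as rownames and cell barcodes as colnames.
#' @return The validated matrix, invisibly coerced to \code{dgCMatrix}.
#' @export
validate_count_matrix <- function(m) {
  m <- methods::as(m, "CsparseMatrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix must carry gene rownames and cell colnames")
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene identifiers in count matrix")
  if (anyDuplicated(colnames(m)))
    stop("duplicate cell identifiers in count matrix")
  v <- m@x
  if (length(v) && (any(v < 0) || any(v != trunc(v))))
    stop("count matrix entries must be non-negative integers")
  m
}

#' Read a CellRanger-style MatrixMarket triplet
#'
#' Reads \code{matrix.mtx} plus its companion \code{features.tsv} and
#' \code{barcodes.tsv} into a sparse gene x cell count matrix. Features
#' files may have one column (symbol) or two or more (id, symbol, ...);
#' when a second column is present it is used as the working gene symbol,
#' matching the CellRanger convention. Symbols are matched case-sensitively.
#'
#' @param matrix_path Path to the MatrixMarket coordinate file.
#' @param features_path Path to the features/genes TSV (no header).
#' @param barcodes_path Path to the barcodes TSV (no header).
#' @return A sparse \code{dgCMatrix} with genes in features-file order and
#'   cells in barcodes-file order.
#' @export
read_mtx_triplet <- function(matrix_path, features_path, barcodes_path) {
  for (p in c(matrix_path, features_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) stop("malformed MatrixMarket file: ",
                                         conditionMessage(e)))
  feats <- utils::read.delim(features_path, header = FALSE,
                             colClasses = "character")
  bcs <- utils::read.delim(barcodes_path, header = FALSE,
                           colClasses = "character")
  if (nrow(feats) != nrow(m))
    stop("features file has ", nrow(feats), " rows but matrix header declares ",
         nrow(m), " genes")
  if (nrow(bcs) != ncol(m))
    stop("barcodes file has ", nrow(bcs), " rows but matrix header declares ",
         ncol(m), " cells")
  symbols <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  if (any(!nzchar(symbols))) stop("empty gene symbol in features file")
  if (anyDuplicated(symbols)) {
    warning("duplicate gene symbols in features file; made unique")
    symbols <- make.unique(symbols)
  }
  barcodes <- bcs[[1]]
  if (anyDuplicated(barcodes)) stop("duplicate cell barcodes in barcodes file")
  dimnames(m) <- list(symbols, barcodes)
  validate_count_matrix(m)
}

#' Write a count matrix as a MatrixMarket triplet
#'
#' Inverse of \code{\link{read_mtx_triplet}}; the round trip is lossless
#' (identical nonzeros, identifiers and shape).
#'
#' @param m Count matrix (genes x cells).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths written.
#' @export
write_mtx_triplet <- function(m, dir) {
  m <- validate_count_matrix(m)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dir)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  Matrix::writeMM(m, paths[1])
  utils::write.table(data.frame(id = rownames(m), symbol = rownames(m)),
                     paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(colnames(m), paths[3])
  invisible(paths)
}
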