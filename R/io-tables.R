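#' Read a per-cell annotation table
#'
#' Reads a TSV with one row per cell. Mandatory columns: \code{cell_id},
#' \code{sample_id}, \code{condition}; an optional \code{cluster} column and
#' any further columns are preserved untouched.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @return A data.frame with one row per cell.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "sample_id", "condition")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("cell table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$cell_id))
    stop("duplicate cell_id in cell table: ",
         paste(unique(tab$cell_id[duplicated(tab$cell_id)]), collapse = ", "))
  tab
}

#' Join a cell table to a count matrix
#'
#' Orders the annotation rows to match the matrix columns, failing loudly
#' on cells present in one but not the other.
#'
#' @param m Count matrix.
#' @param cells Data.frame from \code{\link{read_cell_table}}.
#' @return The annotation reordered to \code{colnames(m)}.
#' @export
align_cells <- function(m, cells) {
  missing_in_tab <- setdiff(colnames(m), cells$cell_id)
  if (length(missing_in_tab))
    stop("cells present in matrix but absent from cell table: ",
         paste(utils::head(missing_in_tab, 5), collapse = ", "))
  missing_in_mat <- setdiff(cells$cell_id, colnames(m))
  if (length(missing_in_mat))
    stop("cells present in cell table but absent from matrix: ",
         paste(utils::head(missing_in_mat, 5), collapse = ", "))
  cells[match(colnames(m), cells$cell_id), , drop = FALSE]
}

#' Read a ligand-receptor pair table
#'
#' @param path TSV with header columns \code{ligand} and \code{receptor}.
#' @return Data.frame with columns ligand, receptor; duplicates rejected.
#' @export
read_lr_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(tab)))
    stop("ligand-receptor table needs columns 'ligand' and 'receptor'")
  validate_lr_table(tab[c("ligand", "receptor")])
}

validate_lr_table <- function(lr) {
  if (any(!nzchar(lr$ligand)) || any(!nzchar(lr$receptor)))
    stop("empty gene symbol in ligand-receptor table")
  if (anyDuplicated(lr[c("ligand", "receptor")]))
    stop("duplicate (ligand, receptor) rows")
  lr
}

#' Built-in zebrafish demo ligand-receptor table
#'
#' The neurotrophin/interleukin axis used throughout the documentation:
#' bdnf binds its receptors ntrk2 and ngfra, and il4 binds il4r.1.
#'
#' @return Data.frame with columns ligand, receptor.
#' @export
lr_demo_pairs <- function() {
  data.frame(ligand   = c("bdnf", "bdnf", "il4"),
             receptor = c("ntrk2", "ngfra", "il4r.1"),
             stringsAsFactors = FALSE)
}

edge_cols <- c("source_cluster", "ligand", "receptor", "target_cluster")
status_colors <- c(unchanged = "black", lost = "cyan", gained = "magenta")

#' Write a differential interaction edge list
#'
#' Serializes classified edges as TSV (lossless round trip via
#' \code{\link{read_edge_table}}), GraphML, or Graphviz DOT. Edge status is
#' carried as a color attribute: unchanged = black, lost = cyan,
#' gained = magenta.
#'
#' @param edges Data.frame of differential edges
#'   (see \code{\link{classify_differential}}).
#' @param path Output file.
#' @param format One of "tsv", "graphml", "dot".
#' @return Invisibly, \code{path}.
#' @export
write_edge_graph <- function(edges, path, format = c("tsv", "graphml", "dot")) {
  format <- match.arg(format)
  miss <- setdiff(edge_cols, names(edges))
  if (length(miss))
    stop("edge table is missing column(s): ", paste(miss, collapse = ", "))
  if (format == "tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  status <- if ("status" %in% names(edges)) as.character(edges$status)
            else rep("unchanged", nrow(edges))
  g <- igraph::make_empty_graph(directed = TRUE)
  verts <- unique(c(edges$source_cluster, edges$target_cluster))
  g <- igraph::add_vertices(g, length(verts), name = verts)
  if (nrow(edges)) {
    g <- igraph::add_edges(
      g, rbind(match(edges$source_cluster, verts),
               match(edges$target_cluster, verts)),
      ligand = edges$ligand, receptor = edges$receptor,
      status = status, color = unname(status_colors[status]))
  }
  igraph::write_graph(g, path,
                      format = if (format == "graphml") "graphml" else "dot")
  invisible(path)
}

#' Read back an edge TSV written by \code{\link{write_edge_graph}}
#'
#' @param path TSV file.
#' @return Data.frame of edges.
#' @export
read_edge_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(edge_cols, names(tab))
  if (length(miss))
    stop("edge table is missing column(s): ", paste(miss, collapse = ", "))
  tab
}
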