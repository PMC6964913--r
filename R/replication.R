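#' Read a supplementary DEG table
#'
#' Loads a published differential-expression table and auto-detects its
#' gene, fold-change, p-value and FDR columns by case-insensitive header
#' heuristics (gene/symbol/id; avg_logfc/logfc/log2fc/fold; p/p_val/pval;
#' fdr/padj/q_val). Delimited text (.tsv/.txt/.csv) is read natively;
#' .xlsx files are converted through the system Python's openpyxl when one
#' is available. The detected column mapping is echoed via \code{message}.
#'
#' @param path Path to the table.
#' @param sheet Sheet index for xlsx input (default 1).
#' @return Data.frame with standardized columns gene, logfc (if found),
#'   p (if found), fdr (if found); the raw table is attached as attribute
#'   \code{"raw"} and the mapping as \code{"column_map"}.
#' @export
read_supp_deg_table <- function(path, sheet = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext == "xlsx") read_xlsx_via_python(path, sheet)
         else if (ext == "csv") utils::read.csv(path,
                                                stringsAsFactors = FALSE)
         else utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0 && ncol(tab) == 0) stop("empty table: ", path)
  h <- tolower(names(tab))
  pick <- function(patterns) {
    for (pat in patterns) {
      hit <- grep(pat, h)
      if (length(hit)) return(hit[1])
    }
    NA_integer_
  }
  gene_i <- pick(c("^gene", "symbol", "^id$"))
  if (is.na(gene_i)) {
    char_cols <- which(vapply(tab, is.character, logical(1)))
    if (!length(char_cols)) stop("cannot identify a gene column in ", path)
    gene_i <- char_cols[1]
  }
  fc_i <- pick(c("avg_logfc", "^logfc", "log2fc", "log2foldchange", "fold"))
  p_i <- pick(c("^p_val$", "^pval(ue)?$", "^p\\.val", "^p$"))
  fdr_i <- pick(c("^fdr", "padj", "^q_?val"))
  map <- c(gene = names(tab)[gene_i],
           logfc = if (!is.na(fc_i)) names(tab)[fc_i] else NA,
           p = if (!is.na(p_i)) names(tab)[p_i] else NA,
           fdr = if (!is.na(fdr_i)) names(tab)[fdr_i] else NA)
  message("column mapping for ", basename(path), ": ",
          paste(names(map), map, sep = "=", collapse = ", "))
  out <- data.frame(gene = as.character(tab[[gene_i]]),
                    stringsAsFactors = FALSE)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(tab[[i]]))
    if (all(is.na(v)) && nrow(tab) > 0)
      stop("column '", names(tab)[i], "' is not numeric (", what, ")")
    v
  }
  if (!is.na(fc_i)) out$logfc <- num(fc_i, "fold change")
  if (!is.na(p_i)) out$p <- num(p_i, "p-value")
  if (!is.na(fdr_i)) out$fdr <- num(fdr_i, "FDR")
  attr(out, "raw") <- tab
  attr(out, "column_map") <- map
  out
}

read_xlsx_via_python <- function(path, sheet = 1) {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("reading .xlsx needs a system Python with openpyxl; ",
         "export the sheet as TSV instead")
  out <- tempfile(fileext = ".tsv")
  code <- paste0(
    "import sys, openpyxl, csv\n",
    "wb = openpyxl.load_workbook(sys.argv[1], read_only=True)\n",
    "ws = wb.worksheets[int(sys.argv[3]) - 1]\n",
    "with open(sys.argv[2], 'w', newline='') as fh:\n",
    "    w = csv.writer(fh, delimiter='\\t')\n",
    "    for row in ws.iter_rows(values_only=True):\n",
    "        w.writerow(['' if v is None else v for v in row])\n")
  status <- system2(py, c("-c", shQuote(code), shQuote(path), shQuote(out),
                          sheet))
  if (status != 0) stop("xlsx conversion failed for ", path)
  utils::read.delim(out, stringsAsFactors = FALSE)
}

#' Count up- and down-regulated genes in a DEG table
#'
#' @param t Table from \code{\link{read_supp_deg_table}} (or any data.frame
#'   with a \code{logfc} column).
#' @return Named list: n_up (positive fold change), n_down (negative).
#' @export
count_directional <- function(t) {
  if (!"logfc" %in% names(t))
    stop("no fold-change column identified; available columns: ",
         paste(names(t), collapse = ", "))
  list(n_up = sum(t$logfc > 0, na.rm = TRUE),
       n_down = sum(t$logfc < 0, na.rm = TRUE))
}

#' Count unique DEGs in a table
#'
#' Reports the number of unique genes as listed, and -- because published
#' tables sometimes include all tested genes -- also after re-applying the
#' raw p < 0.05 filter and the joint p < 0.05, |logFC| >= 0.25 filter when
#' those columns are present, so the filter matching a printed count can
#' be identified.
#'
#' @param t Table from \code{\link{read_supp_deg_table}}.
#' @param p_max,lfc_min Thresholds for the refiltered counts.
#' @return Named list: n, n_p (NA without a p column), n_p_lfc (NA without
#'   both columns).
#' @export
count_degs <- function(t, p_max = 0.05, lfc_min = 0.25) {
  n <- length(unique(t$gene))
  n_p <- if ("p" %in% names(t))
    length(unique(t$gene[!is.na(t$p) & t$p < p_max])) else NA_integer_
  n_p_lfc <- if (all(c("p", "logfc") %in% names(t)))
    length(unique(t$gene[!is.na(t$p) & t$p < p_max &
                           abs(t$logfc) >= lfc_min])) else NA_integer_
  list(n = n, n_p = n_p, n_p_lfc = n_p_lfc)
}

#' Overlap report for two DEG tables
#'
#' Delegates to \code{\link{deg_overlap}} on the unique gene sets of two
#' tables -- the same code path the synthetic pipeline uses.
#'
#' @param t_a,t_b Tables from \code{\link{read_supp_deg_table}}.
#' @return See \code{\link{deg_overlap}}.
#' @export
overlap_report <- function(t_a, t_b) deg_overlap(t_a$gene, t_b$gene)
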