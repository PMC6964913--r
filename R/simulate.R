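#' Construct a synthetic multi-condition scRNA-seq design
#'
#' Defines the generative model behind the package's verification data: a
#' gene universe with cluster-exclusive marker programs, ligand/receptor
#' genes wired to a pair table, mitochondrial genes (prefix \code{mt-}),
#' negative-binomial counts with gamma-distributed per-cell size factors,
#' and per-condition multiplicative effects on named genes in named cell
#' types. The defaults emulate a zebrafish telencephalon experiment with a
#' serotonin-responsive neuronal cluster (\code{neuron_htr1d}), two
#' progenitor clusters (\code{PC0}, \code{PC2}), oligodendrocytes and
#' immune cells under four conditions (control, ab42, il4, 5ht): serotonin
#' shuts down neuronal \code{bdnf} (losing its edges onto progenitor
#' \code{ntrk2}/\code{ngfra}), while amyloid and il4 switch on immune
#' \code{il4} (gaining edges onto \code{il4r.1}-positive progenitors).
#' A block of planted differentially expressed genes in the
#' \code{neuron_htr1d} cluster (20 up at fold 4, 20 down at fold 4 under
#' 5ht, of which 3 reverse direction under il4/ab42) exercises the
#' dissection and reciprocal-change machinery.
#'
#' @param n_genes Total genes in the universe (background + named).
#' @param cell_types Named integer vector: cells per type per condition.
#' @param conditions Condition labels; the first is the control.
#' @param marker_fold Fold elevation of a type's exclusive markers.
#' @param n_markers Exclusive markers per cell type.
#' @param dispersion NB inverse-dispersion (size); \code{Inf} = Poisson.
#' @param size_factor_shape Gamma shape (= rate) of per-cell size factors,
#'   mean 1; \code{Inf} = constant 1.
#' @param mito_fraction_range Per-cell mitochondrial count fraction is drawn
#'   uniformly from this interval.
#' @param n_mito_genes Number of \code{mt-} prefixed genes.
#' @param depth_target Expected UMIs per cell at size factor 1.
#' @param on_mean,off_mean Expected expression of a ligand/receptor gene in
#'   a cluster where it is active / silent.
#' @param lr_table Ligand-receptor pair table
#'   (default \code{\link{lr_demo_pairs}}).
#' @param seed Seed for the (deterministic) base-program draw.
#' @return An object of class \code{lrmap_design}.
#' @export
synthetic_design <- function(n_genes = 2000,
                             cell_types = c(neuron_htr1d = 250, PC0 = 250,
                                            PC2 = 250, oligo = 250,
                                            immune = 250),
                             conditions = c("control", "ab42", "il4", "5ht"),
                             marker_fold = 8,
                             n_markers = 10,
                             dispersion = 2,
                             size_factor_shape = 10,
                             mito_fraction_range = c(0.01, 0.08),
                             n_mito_genes = 10,
                             depth_target = 3000,
                             on_mean = 3,
                             off_mean = 0.02,
                             lr_table = lr_demo_pairs(),
                             seed = 1L) {
  stopifnot(length(cell_types) >= 1, all(cell_types > 0),
            length(conditions) >= 2, !anyDuplicated(conditions),
            dispersion > 0, size_factor_shape > 0,
            length(mito_fraction_range) == 2,
            all(mito_fraction_range >= 0), all(mito_fraction_range < 1),
            marker_fold > 0, on_mean > 0, off_mean > 0)
  lr_table <- validate_lr_table(lr_table)
  types <- names(cell_types)
  if (is.null(types) || any(!nzchar(types)))
    stop("cell_types must be a named vector")

  named_genes <- unique(c(lr_table$ligand, lr_table$receptor, "htr1d"))
  marker_genes <- unlist(lapply(types, function(t)
    sprintf("mk.%s.%d", t, seq_len(n_markers))))
  mito_genes <- sprintf("mt-g%d", seq_len(n_mito_genes))
  n_bg <- n_genes - length(named_genes) - length(marker_genes) -
    length(mito_genes)
  if (n_bg < 100)
    stop("n_genes too small for the named/marker/mito genes plus background")
  bg_genes <- sprintf("g%04d", seq_len(n_bg))
  genes <- c(named_genes, marker_genes, mito_genes, bg_genes)

  # deterministic base program, independent of the global RNG stream
  prog <- with_local_seed(seed, {
    base <- stats::rlnorm(n_bg, meanlog = 0, sdlog = 1)
    matrix(rep(c(rep(off_mean, length(named_genes)),
                 rep(0.25, length(marker_genes)),
                 rep(0, length(mito_genes)),   # allocated per cell later
                 base),
               length(types)),
           nrow = length(genes), ncol = length(types),
           dimnames = list(genes, types))
  })
  # exclusive marker elevation
  for (i in seq_along(types))
    prog[sprintf("mk.%s.%d", types[i], seq_len(n_markers)), i] <-
      0.25 * marker_fold

  # wiring of the default cast when the canonical clusters are present
  set_if <- function(gene, type, value) {
    if (gene %in% genes && type %in% types) prog[gene, type] <<- value
  }
  set_if("htr1d",  "neuron_htr1d", on_mean)
  set_if("bdnf",   "neuron_htr1d", on_mean)
  set_if("ntrk2",  "PC0", on_mean)
  set_if("ngfra",  "PC2", on_mean)
  set_if("il4r.1", "PC0", on_mean)
  set_if("il4r.1", "PC2", on_mean)

  effects <- data.frame(condition = character(), cell_type = character(),
                        gene = character(), factor = numeric(),
                        stringsAsFactors = FALSE)
  eff <- function(condition, cell_type, gene, factor)
    data.frame(condition = condition, cell_type = cell_type, gene = gene,
               factor = factor, stringsAsFactors = FALSE)
  deg_up <- deg_down <- reciprocal <- character()
  if ("neuron_htr1d" %in% types && all(c("ab42", "il4", "5ht") %in%
                                       conditions)) {
    effects <- rbind(effects,
      eff("5ht", "neuron_htr1d", "bdnf", off_mean / on_mean),
      eff("il4", "immune", "il4", on_mean / off_mean),
      eff("ab42", "immune", "il4", on_mean / off_mean))
    # planted DEG block in the serotonin-responsive neurons
    deg_up <- bg_genes[1:20]
    deg_down <- bg_genes[21:40]
    reciprocal <- deg_up[1:3]
    prog[c(deg_up, deg_down), ] <- 1.5
    effects <- rbind(effects,
      eff("5ht", "neuron_htr1d", deg_up, 4),
      eff("5ht", "neuron_htr1d", deg_down, 0.25),
      eff("il4", "neuron_htr1d", reciprocal, 0.25),
      eff("ab42", "neuron_htr1d", reciprocal, 0.25))
  }

  # rescale the background so total depth at size factor 1 hits the target
  mito_mid <- mean(mito_fraction_range)
  for (i in seq_along(types)) {
    fixed <- sum(prog[c(named_genes, marker_genes,
                        if (length(deg_up)) c(deg_up, deg_down)), i])
    free <- setdiff(bg_genes, c(deg_up, deg_down))
    target_bg <- depth_target * (1 - mito_mid) - fixed
    prog[free, i] <- prog[free, i] * target_bg / sum(prog[free, i])
  }

  structure(list(genes = genes, cell_types = cell_types,
                 conditions = conditions, program = prog,
                 lr_table = lr_table, condition_effects = effects,
                 dispersion = dispersion,
                 size_factor_shape = size_factor_shape,
                 mito_fraction_range = mito_fraction_range,
                 mito_genes = mito_genes,
                 on_mean = on_mean, off_mean = off_mean,
                 deg_truth_genes = list(up = deg_up, down = deg_down,
                                        reciprocal = reciprocal),
                 seed = as.integer(seed)),
            class = "lrmap_design")
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

effective_means <- function(design, condition) {
  mu <- design$program
  fx <- design$condition_effects
  fx <- fx[fx$condition == condition, , drop = FALSE]
  if (nrow(fx)) {
    for (i in seq_len(nrow(fx)))
      mu[fx$gene[i], fx$cell_type[i]] <-
        mu[fx$gene[i], fx$cell_type[i]] * fx$factor[i]
  }
  mu
}

# expected probability of a nonzero count at size factor 1
detect_prob <- function(mu, size) {
  if (is.finite(size)) 1 - (1 + mu / size)^(-size) else 1 - exp(-mu)
}

#' Ground-truth interaction edges and differential classification
#'
#' Derives, from a design's expected expression alone (no sampling), which
#' ligand-receptor edges are active per condition under the pipeline's
#' cluster-expression rule (expected detection fraction >= \code{min_frac}
#' and expected expressing cells >= \code{min_cells_expr}), and classifies
#' each treatment-vs-control comparison into gained/lost/unchanged edges.
#'
#' @param design An \code{lrmap_design}.
#' @param min_frac,min_cells_expr Cluster-expression rule thresholds.
#' @return List with \code{edges} (per-condition active edges),
#'   \code{differential} (per-comparison status table) and
#'   \code{deg_lfc} (true natural-log fold changes of condition-modulated
#'   genes per cell type and comparison).
#' @export
ground_truth <- function(design, min_frac = 0.1, min_cells_expr = 3) {
  types <- names(design$cell_types)
  lr <- design$lr_table
  expresses <- function(condition) {
    mu <- effective_means(design, condition)
    p <- detect_prob(mu, design$dispersion)
    (p >= min_frac) & (p * rep(design$cell_types, each = nrow(mu)) >=
                         min_cells_expr)
  }
  edges_for <- function(condition) {
    ex <- expresses(condition)
    out <- list()
    for (i in seq_len(nrow(lr))) {
      src <- types[ex[lr$ligand[i], ]]
      tgt <- types[ex[lr$receptor[i], ]]
      if (length(src) && length(tgt))
        out[[i]] <- expand.grid(source_cluster = src,
                                target_cluster = tgt,
                                stringsAsFactors = FALSE)
    }
    keep <- !vapply(out, is.null, TRUE)
    if (!any(keep))
      return(data.frame(source_cluster = character(), ligand = character(),
                        receptor = character(), target_cluster = character(),
                        condition = character(), stringsAsFactors = FALSE))
    res <- do.call(rbind, lapply(which(keep), function(i)
      data.frame(source_cluster = out[[i]]$source_cluster,
                 ligand = lr$ligand[i], receptor = lr$receptor[i],
                 target_cluster = out[[i]]$target_cluster,
                 stringsAsFactors = FALSE)))
    res$condition <- condition
    res
  }
  edges <- do.call(rbind, lapply(design$conditions, edges_for))
  control <- design$conditions[1]
  diffs <- do.call(rbind, lapply(design$conditions[-1], function(tr)
    classify_differential(edges[edges$condition == control, , drop = FALSE],
                          edges[edges$condition == tr, , drop = FALSE],
                          comparison = c(tr, control))))
  fx <- design$condition_effects
  deg <- if (nrow(fx)) data.frame(comparison = paste0(fx$condition, "_vs_",
                                                      control),
                                  cell_type = fx$cell_type, gene = fx$gene,
                                  true_lfc = log(fx$factor),
                                  stringsAsFactors = FALSE)
         else NULL
  list(edges = edges, differential = diffs, deg_lfc = deg)
}

#' Simulate a dataset from a design
#'
#' Draws counts NB(mean = program x condition factor x per-cell size factor,
#' size = dispersion); mitochondrial genes receive, per cell, a share of the
#' cell's expected depth equal to a uniformly drawn mitochondrial fraction.
#' Identical seeds give bit-identical output.
#'
#' @param design An \code{lrmap_design}.
#' @param seed Integer seed; defaults to the design's seed.
#' @return List of class \code{lrmap_dataset}: \code{counts} (sparse
#'   gene x cell matrix), \code{cells} (annotation with true type as
#'   \code{cluster}), \code{truth} (see \code{\link{ground_truth}}).
#' @export
simulate_dataset <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "lrmap_design"))
  if (length(design$genes) == 0 || sum(design$cell_types) == 0)
    stop("design has zero genes or zero cells")
  set.seed(seed)
  types <- names(design$cell_types)
  mito_idx <- match(design$mito_genes, design$genes)
  n_mt <- length(mito_idx)
  blocks <- list(); ann <- list(); k <- 0
  for (cond in design$conditions) {
    mu_all <- effective_means(design, cond)
    for (ty in types) {
      n <- design$cell_types[[ty]]
      s <- if (is.finite(design$size_factor_shape))
        stats::rgamma(n, shape = design$size_factor_shape,
                      rate = design$size_factor_shape) else rep(1, n)
      f <- stats::runif(n, design$mito_fraction_range[1],
                        design$mito_fraction_range[2])
      mu0 <- mu_all[, ty]
      total_nonmito <- sum(mu0)
      mu_mat <- outer(mu0, s)
      if (n_mt > 0)
        mu_mat[mito_idx, ] <- outer(rep(1 / n_mt, n_mt),
                                    s * f / (1 - f) * total_nonmito)
      counts <- if (is.finite(design$dispersion))
        stats::rnbinom(length(mu_mat), mu = mu_mat, size = design$dispersion)
      else stats::rpois(length(mu_mat), lambda = mu_mat)
      dim(counts) <- dim(mu_mat)
      k <- k + 1
      ids <- sprintf("%s_%s_c%04d", cond, ty, seq_len(n))
      dimnames(counts) <- list(design$genes, ids)
      blocks[[k]] <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                 "CsparseMatrix")
      ann[[k]] <- data.frame(cell_id = ids,
                             sample_id = paste0("s_", cond),
                             condition = cond, cluster = ty,
                             stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, blocks)
  structure(list(counts = validate_count_matrix(counts),
                 cells = do.call(rbind, ann),
                 truth = ground_truth(design),
                 design = design),
            class = "lrmap_dataset")
}

#' Plant gained/lost interactions for one comparison
#'
#' Rewires a design so that, in the named treatment condition, the listed
#' edges are gained (ligand switched on in the source cluster only under
#' the treatment) or lost (ligand switched off under the treatment), with
#' the receptor held active in the target cluster throughout. The ground
#' truth of a subsequent \code{\link{simulate_dataset}} then lists exactly
#' the requested states for those edges.
#'
#' @param design An \code{lrmap_design}.
#' @param comparison Treatment condition label (compared to the control,
#'   the design's first condition).
#' @param gain,lose Data.frames with columns source_cluster, ligand,
#'   receptor, target_cluster (or lists of 4-element character vectors).
#' @return The modified design.
#' @export
plant_differential_interactions <- function(design, comparison,
                                            gain = NULL, lose = NULL) {
  stopifnot(inherits(design, "lrmap_design"))
  if (!comparison %in% design$conditions[-1])
    stop("unknown treatment condition: ", comparison)
  as_edges <- function(x) {
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0) ||
        (is.list(x) && !is.data.frame(x) && length(x) == 0))
      return(NULL)
    if (!is.data.frame(x))
      x <- as.data.frame(do.call(rbind, x), stringsAsFactors = FALSE,
                         col.names = edge_cols)
    names(x)[1:4] <- edge_cols
    x
  }
  gain <- as_edges(gain); lose <- as_edges(lose)
  if (is.null(gain) && is.null(lose)) return(design)
  check <- function(e) {
    if (is.null(e)) return()
    ok_pair <- paste(e$ligand, e$receptor) %in%
      paste(design$lr_table$ligand, design$lr_table$receptor)
    if (!all(ok_pair)) stop("edge references a pair absent from lr_table")
    tys <- c(e$source_cluster, e$target_cluster)
    if (!all(tys %in% names(design$cell_types)))
      stop("edge references an undeclared cell type")
  }
  check(gain); check(lose)
  if (!is.null(gain) && !is.null(lose)) {
    key <- function(e) do.call(paste, e[edge_cols])
    clash <- intersect(key(gain), key(lose))
    if (length(clash))
      stop("edge requested as both gained and lost: ", clash[1])
  }
  set_effect <- function(cond, type, gene, factor) {
    fx <- design$condition_effects
    hit <- fx$condition == cond & fx$cell_type == type & fx$gene == gene
    fx <- fx[!hit, , drop = FALSE]
    design$condition_effects <<- rbind(fx,
      data.frame(condition = cond, cell_type = type, gene = gene,
                 factor = factor, stringsAsFactors = FALSE))
  }
  clear_effect <- function(cond, type, gene) {
    fx <- design$condition_effects
    hit <- fx$condition == cond & fx$cell_type == type & fx$gene == gene
    design$condition_effects <- fx[!hit, , drop = FALSE]
    design
  }
  apply_edge <- function(e, gained) {
    for (i in seq_len(nrow(e))) {
      src <- e$source_cluster[i]; tgt <- e$target_cluster[i]
      lg <- e$ligand[i]; rc <- e$receptor[i]
      if (gained) {
        design$program[lg, src] <<- design$off_mean
        set_effect(comparison, src, lg, design$on_mean / design$off_mean)
      } else {
        design$program[lg, src] <<- design$on_mean
        set_effect(comparison, src, lg, design$off_mean / design$on_mean)
      }
      design$program[rc, tgt] <<- design$on_mean
      design <<- clear_effect(comparison, tgt, rc)
    }
  }
  if (!is.null(gain)) apply_edge(gain, gained = TRUE)
  if (!is.null(lose)) apply_edge(lose, gained = FALSE)

  truth <- ground_truth(design)
  d <- truth$differential
  d <- d[d$treatment == comparison, , drop = FALSE]
  key <- function(e) do.call(paste, as.data.frame(e)[edge_cols])
  if (!is.null(gain) &&
      !all(key(gain) %in% key(d[d$status == "gained", , drop = FALSE])))
    stop("requested gained edge not realizable under this design")
  if (!is.null(lose) &&
      !all(key(lose) %in% key(d[d$status == "lost", , drop = FALSE])))
    stop("requested lost edge not realizable under this design")
  design
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Emits the MatrixMarket triplet, the per-cell annotation table and the
#' ground-truth differential-edge table (5 files), all readable by the
#' package's own readers.
#'
#' @param dataset An \code{lrmap_dataset}.
#' @param dir Output directory.
#' @return Invisibly, the file paths.
#' @export
write_fixture <- function(dataset, dir) {
  stopifnot(inherits(dataset, "lrmap_dataset"))
  paths <- write_mtx_triplet(dataset$counts, dir)
  cells_path <- file.path(dir, "cells.tsv")
  utils::write.table(dataset$cells, cells_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(dir, "truth_edges.tsv")
  utils::write.table(dataset$truth$differential, truth_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(paths, cells_path, truth_path))
}

#' Serialize / load a design's parameters as YAML
#'
#' Writes the constructor parameters of a design (not post-hoc planted
#' rewirings) so a design can be rebuilt reproducibly from a config file.
#'
#' @param design An \code{lrmap_design}.
#' @param path YAML file path.
#' @return \code{design_to_yaml}: invisibly, \code{path};
#'   \code{design_from_yaml}: a rebuilt \code{lrmap_design}.
#' @export
design_to_yaml <- function(design, path) {
  yaml::write_yaml(list(
    n_genes = length(design$genes),
    cell_types = as.list(design$cell_types),
    conditions = design$conditions,
    dispersion = design$dispersion,
    size_factor_shape = design$size_factor_shape,
    mito_fraction_range = design$mito_fraction_range,
    seed = design$seed), path)
  invisible(path)
}

#' @rdname design_to_yaml
#' @export
design_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  synthetic_design(n_genes = cfg$n_genes,
                   cell_types = unlist(cfg$cell_types),
                   conditions = cfg$conditions,
                   dispersion = cfg$dispersion,
                   size_factor_shape = cfg$size_factor_shape,
                   mito_fraction_range = cfg$mito_fraction_range,
                   seed = cfg$seed)
}
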