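---
title: "Differential ligand-receptor interaction mapping: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential ligand-receptor interaction mapping: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrmap)
```

## Scope and model

`lrmap` quantifies how treatments remodel cluster-to-cluster
ligand-receptor communication in single-cell RNA-seq. The package takes
cluster labels as an input (from upstream clustering, from its own
label-transfer classifier, or from synthetic ground truth); de novo
clustering and embedding are deliberately outside its scope, as are
alignment/quantification and live pathway-database queries (the
over-representation test takes user-supplied gene sets instead).

The core object is the per-condition interaction graph. A cluster $A$
*expresses* gene $g$ in a condition when

$$\mathrm{frac}(A,g) \ge \texttt{min\_frac}
  \quad\text{and}\quad n_{\mathrm{expressing}}(A,g) \ge \texttt{min\_cells\_expr},$$

with $\mathrm{frac}$ the fraction of the cluster's cells having a nonzero
raw count. An edge $(A, L, R, B)$ exists when $A$ expresses the ligand
$L$ and $B$ expresses a cognate receptor $R$ from the pair table;
self-edges are admitted. Edges are presence/absence calls — arrows on a
map, not weighted scores — so differential analysis is set algebra:
comparing treatment to control, an edge of the union is *unchanged*
(both), *lost* (control only) or *gained* (treatment only). A
mean-expression weight is carried along as an auxiliary column for
plotting but never influences a call.

The expression rule is the single most consequential constant in this
style of analysis and has no canonical value; we default to
`min_frac = 0.1` with `min_cells_expr = 3` (the same 3-cell floor used
for differential testing) and surface both as mandatory, logged
parameters of `build_interaction_graph()` so sensitivity sweeps are
one-liners. An optional stricter mode — requiring the ligand or receptor
to be differentially expressed rather than merely expressed — was
considered and rejected as the default: the expression-only criterion is
the literal reading of anchored mapping (anchor a ligand, match every
cluster expressing any of its receptors, and vice versa), and the
differential requirement can be recovered by intersecting edges with
`find_degs()` output.

## Upstream stages and their parameters

**QC** (`qc_thresholds()`): cells kept with 1,000–15,000 total UMIs and
500–2,500 detected genes, both read as closed intervals (the bounds'
inclusivity is genuinely ambiguous in common usage; we pick the symmetric
reading and expose every bound), and at most 6 % mitochondrial counts —
"%mito" is interpreted as a fraction of counts, the standard droplet-QC
usage, computed over genes with the `mt-` symbol prefix. Genes detected
in fewer than 5 surviving cells are dropped. Doublet removal beyond the
upper detected-gene bound is out of scope (no algorithm is assumed).
Filtering is idempotent by construction.

**Normalization**: $\ln(1 + 10^4 \cdot \mathrm{count}/\mathrm{total})$,
sparsity-preserving. Gene symbols are matched case-sensitively
throughout (zebrafish symbols are lowercase; case carries meaning across
species).

**Variable genes** (`select_variable_genes()`): per sample, the
dispersion (variance/mean) of the de-logged normalized expression is
z-scored within 20 equal-frequency mean bins and the top 1,000 genes per
sample are merged with per-sample provenance. This is the classic
mean-variance-plot family of selectors; the bin count and `top_n` are
arguments.

**Markers and label transfer**: `find_markers()` tests each gene
cluster-vs-rest (rank-sum), reports only positive markers (elevated
in-cluster — identity transfer needs positive features) and applies
Benjamini–Hochberg FDR within each cluster's family; markers qualify at
FDR < 0.1. `train_label_transfer()` takes the union of each cluster's
top-5 qualifying markers (ties broken by higher avg_logFC, then lower p,
then gene symbol — deterministic outputs) and fits a random forest of
500 trees with a class-balanced bootstrap, seeded. The forest size and
balancing are our choices — the algorithm family fixes neither — picked
for stability on small reference sets and recorded in the model object.
Marker ranking uses fold change rather than p-value; both orderings were
defensible and the choice is confined to `top_markers()`.

**Dissection and differential expression**: receptor-positive
subpopulations are cells with raw count > 0 for the receptor gene — the
minimal faithful reading of in-silico dissection; the threshold is
configurable. `find_degs()` tests genes expressed in at least 10 % of
either group (`min_pct`, settable to 0 for strict replication), requires
3 cells per group, and filters at raw p < 0.05 with |avg_logFC| ≥ 0.25
on the natural-log scale with pseudocount 1 applied to the de-logged
group means. No FDR is applied at the DEG stage while marker detection
uses FDR < 0.1 — the two stages deliberately follow two different
conventions, each tied to its downstream use (thresholded candidate
lists vs. classifier features).

**Rank-sum test**: `rank_sum_test()` wraps the standard two-sided
Wilcoxon machinery — exact enumeration when $n_1 + n_2 \le 12$ with no
ties, otherwise the normal approximation with tie and continuity
correction. The all-tied degenerate case is defined as $p = 1$. Tests
validate the exact path against closed-form enumeration
($x = (1,2,3)$ vs $y = (4,5,6)$ gives exactly $p = 0.10$) and against an
independent $10^5$-permutation Monte-Carlo oracle on tie-free instances,
where exact and permutation p-values estimate the same quantity; with
heavy ties the normal approximation is only asymptotically calibrated,
which the type-I-error test measures directly on discrete null data.

**Overlap statistics**: subpopulation co-positivity percentages use the
union of cells positive for either gene as denominator (the only reading
under which the three compartments sum to 100 %); DEG-list overlap
likewise reports $100\,|A \cap B| / |A \cup B|$ over unique genes. The
hypergeometric over-representation test is the one-sided upper tail with
BH-FDR across sets; its universe is an explicit argument, conventionally
all genes surviving QC.

## The synthetic-data model

`synthetic_design()` defines the generative model the test suite and the
acceptance script run against. Counts are negative binomial with mean
$\mu_{gtc} = \mathrm{program}(g, t) \times \mathrm{factor}(g, t, c)
\times s_i$: a per-type expected program, per-condition multiplicative
effects on named genes in named types, and gamma per-cell size factors
(shape = rate = 10, mean 1). The NB size (inverse dispersion) defaults
to 2, a typical droplet-data overdispersion at desk scale. Mitochondrial
content is emulated by giving each cell a fraction drawn uniformly from
(0.01, 0.08) and allocating that share of its expected depth to the
`mt-` genes, which exercises the 6 % rule without modelling organelle
biology. Defaults: 2,000 genes, five clusters (`neuron_htr1d`, `PC0`,
`PC2`, `oligo`, `immune`) with 250 cells per condition, four conditions
(`control`, `ab42`, `il4`, `5ht`), ~3,000 expected UMIs per cell, 10
exclusive markers per type at 8-fold elevation. Ligand/receptor genes
are "on" at mean 3 (detection fraction ≈ 0.8 at size 2) or "off" at
0.02 (≈ 0.01) — far on either side of the 0.1 edge rule, so planted
edge states are unambiguous. The default wiring mirrors the
serotonin/neurotrophin cast: `bdnf` in the neuronal cluster silenced
under `5ht`; `il4` switched on in immune cells under `il4`/`ab42`; a
40-gene DEG block (4-fold up/down) in the neuronal cluster under `5ht`,
three of whose genes reverse direction under `il4`/`ab42` to exercise
reciprocal-change detection.

The ground truth is derived analytically, not by sampling: a cluster's
expected detection fraction is $1 - (1 + \mu/\theta)^{-\theta}$, and the
same expression rule that the pipeline applies to realized data is
applied to these expectations. `plant_differential_interactions()`
rewires a design so that requested edges are gained or lost in a named
comparison and verifies against this analytic truth that the request is
realizable, refusing contradictions (the same edge gained and lost).

What the simulator does *not* emulate: ambient RNA, doublets, batch
effects beyond per-cell size factors, gene-gene correlation, or
continuous differentiation trajectories. Passing tests therefore
demonstrate correctness of the pipeline's logic and calibration of its
statistics under a clean generative model — not robustness to the
artefacts of real droplet data, where the expression-rule constants in
particular deserve a sensitivity sweep.

## Numerical and engineering choices

* Sparse `dgCMatrix` is the count container end to end; normalization
  rewrites only the nonzero slots, and iteration never densifies beyond
  the (small) gene subsets under test.
* All randomness flows from explicit integer seeds; generation,
  training and planting are bit-reproducible given the seed.
* Tie-breaks everywhere are deterministic (documented orderings), so
  outputs are invariant to cell and row order.
* Degenerate inputs fail loudly: empty groups, absent genes, unlabeled
  cells, all-zero cells at normalization, single-cluster marker
  requests, thresholds violating their own invariants. Readers reject
  malformed numeric fields rather than coercing them. The one silent-ish
  coercion — duplicate gene symbols made unique on read — warns, and
  follows the dominant upstream convention.
* Published supplementary DEG tables are read from delimited text
  directly; `.xlsx` input is converted through the system Python's
  `openpyxl` when one is present. Column roles (gene, fold change, p,
  FDR) are auto-detected from header heuristics and always echoed,
  since published tables rarely standardize headers. Re-filtered counts
  (p < 0.05, and jointly with |logFC| ≥ 0.25) are reported next to raw
  unique-gene counts so the filter behind a printed number can be
  identified empirically.

## Problem sizes

The shipped tests and the acceptance script run at desk scale by design:
the default fixture is 2,000 genes × 5,000 cells; label transfer uses a
600-gene, three-type reference/query pair (1,200 cells each); type-I
calibration uses 1,130 null genes over 100 + 100 cells; the permutation
oracle runs $10^5$ permutations on 50 small instances. These sizes give
stable recovery statistics (edge recovery is exact, DEG recall ≥ 95 %,
transfer accuracy ≥ 95 %) while keeping a full verification run within
minutes on one CPU core. The pipeline itself has no intrinsic scale
limit beyond sparse-matrix memory.

## Known limitations

* Edge calls carry no significance statement; a permutation-based
  communication test (CellPhoneDB-style) is explicitly out of scope.
* The Wilcoxon normal approximation on heavily zero-inflated genes is
  conservative; genes below `min_pct` are not tested at all.
* Label transfer presumes the query's types are a subset of the
  reference's; novel query populations are assigned to the nearest
  reference class (with low confidence) rather than flagged as novel.
* The ligand-receptor pair table is an input; the shipped demo table
  covers only the three documented axes and is not a curated resource.
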