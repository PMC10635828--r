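---
title: "Mapping single cells to spatial spots by balanced assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping single cells to spatial spots by balanced assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotalign)
```

## The problem and the model

Spot-based spatial transcriptomics pools the RNA of several cells per capture
spot; scRNA-seq resolves cells but not positions. `spotalign` reverses the
pooling: given a raw scRNA-seq count matrix with cell-type annotations, a raw
ST count matrix, and global cell-type fractions for the ST sample (from any
external deconvolution tool — deconvolution is deliberately *not* part of
this package), it assigns one single-cell transcriptome to every inferred
cell slot in the tissue.

The assignment model is a balanced linear program. After CPM + log2
normalization and restriction to the shared gene set, each spot `s` is
replicated into `n_s` sub-spots (`L = Σ n_s` in total) and the reference is
resampled into a pool of exactly `K = L` cells whose type census matches the
fractions applied to `L`. With dissimilarity `d_kl` between pool cell `k` and
sub-spot `l`, the program

$$\min_x \sum_{k}\sum_{l} d_{kl}\,x_{kl},\qquad
\sum_l x_{kl} = 1,\;\; \sum_k x_{kl} = 1,\;\; x_{kl}\ge 0$$

always has an integral optimum (the constraint matrix is totally
unimodular), i.e. an optimal *bijection* between cells and sub-spots. The
solver works on the dual: potentials $u_k, v_l$ with reduced costs
$r_{kl} = d_{kl} - u_k - v_l \ge 0$ are maintained while shortest
augmenting paths are grown from unassigned rows, in $O(L^3)$ overall. At
termination the package returns the permutation *and* the duals, so
optimality can be verified directly: all reduced costs nonnegative, zero on
matched edges, and $\sum u + \sum v$ equal to the objective (strong
duality). The test suite checks this certificate on every solved instance
and also cross-checks the optimum against exhaustive enumeration for
$K \le 7$.

Assumptions worth keeping in mind: the fractions are trusted as global
(per-spot composition is not constrained); every mapped cell type must exist
in the reference; and the cost is a per-pair profile similarity, so strongly
correlated cell types compete for the same sub-spots and are disambiguated
only by the capacity constraints.

## Tunable parameters

* `mean_cells` (default 5): the assumed mean cells per spot anchoring the
  UMI-based estimate. 5 suits ~55 µm Visium spots; 20 suits legacy ST arrays
  with larger spots; ~10 is sensible for tissues with small, dense cells.
  Units are cells per spot. Supplying segmentation counts via
  `cells_per_spot` bypasses the estimate entirely.
* `metric` (default `neg_pearson`): negated Pearson correlation. Spearman
  (Pearson on average-tie ranks) and Euclidean distance are provided for
  robustness checks; Pearson is the default for speed and because the cost
  only needs relative profile shape.
* `mode`: `duplication` (default) keeps every mapped profile a measured
  cell — the right choice on real data. `generation` synthesizes shortfall
  cells gene-by-gene from the type's empirical per-gene distribution and is
  used in benchmarking so duplicates cannot inflate precision; generated
  cells carry no ground truth and are excluded from precision scoring.
* `solver`: `exact`, or `integer` which rounds costs to multiples of
  `1/scale` (`scale = 1e6` by default) and solves that problem exactly. The
  default scale keeps scaled correlation costs well inside exact-integer
  range while altering assignments only where costs differ by under 1e-6.
* `bin_size` (default 10000, `map_cells_binned`): single-cell-resolution ST
  datasets are partitioned into random disjoint bins of at most this many
  cells, each mapped independently with a freshly resampled query pool. This
  bounds the cubic solve while retaining cellular diversity per bin.
* Confidence scoring: 50 training spots per class (resampled with
  replacement when fewer exist), 5–50 markers per type, removal threshold
  0.10 on the probability scale.

## The synthetic-data generator

`generate_atlas()` draws negative-binomial counts (dispersion 2) around
log-normal gene means, log-normal library-size factors (sd 0.3), and gives
each type a marker program: 10% of genes with means multiplied by 8. These
defaults produce type separability comparable to well-annotated tissue
atlases — markers are clear but transcriptomes overlap heavily.
`lay_out_and_pool()` places cells in the unit square (contiguous type
territories, a smooth gradient, or uniformly at random), overlays a grid
sized so nonempty spots average the requested occupancy (5, 15 or 30 cells
per spot emulate common resolutions), and sums raw counts per spot as exact
integer pseudo-bulk. Query noise multiplies a fraction `p` of each cell's
genes by independent $2^{N(0,1)}$ draws — median factor 1, mostly within
four-fold; `permute_within_type()` makes duplicated profiles distinct by
giving each cell 20% of its genes from a same-type donor.

What the generator does *not* emulate: platform capture biases, spot-edge
cells split across spots, segmentation errors, ambient RNA, batch effects
between the two modalities, and continuous cell states within a type.
Passing tests therefore demonstrate the correctness of the optimization,
estimators and scoring under controlled conditions, not field performance on
any particular tissue.

The input-perturbation models used for robustness studies are implemented
exactly as specified by their noise laws: fractions are scaled by
$2^{z}$ with $z = \mathrm{clamp}(y, -2, 2)$,
$y \sim N(0, (2x^{1/3})^{-2})$, then renormalized (hard four-fold range,
rarer types noisier); counts become
$\max(1, \min(n\cdot\mathrm{round}(2^{y}), \lceil 1.1M\rceil))$ with
$y \sim N(0, (p/n^{1/3})^2)$, where `p = 1.4` is the calibration used for
5-cells-per-spot designs and larger occupancies use larger `p` (up to 3.7).

## Numerical choices

* **log2 pseudocount**: the log transform is `log2(x + 1)` so zeros map to
  zero; the CPM scale makes the +1 negligible for expressed genes.
* **UMI predictor**: the cells-per-spot predictor is
  `u_s = log2(1 + total UMI of spot s)`. A per-spot CPM rescale leaves its
  own column total constant by construction, so the log total of the raw
  counts is the meaningful per-spot summary; the +1 guards empty spots.
  Fitted values are rounded to the nearest integer and clamped at 1; if all
  spots have identical totals, each gets `round(mean_cells)`.
* **Apportionment**: fractions are converted to integer targets by largest
  remainder (Hamilton), which minimizes total deviation from `f·L`;
  remainder ties go to the larger fraction, then the lexicographically
  smaller type name. Zero-fraction types are never mapped.
* **Degenerate correlations**: a zero-variance profile would make the cost
  undefined; such entries are set to 0 (neutral) so the solver never sees a
  non-finite value.
* **Determinism**: gene order is sorted at intersection, pool columns are
  ordered by type then source id, each cell type draws from its own RNG
  stream derived from the master seed (so adding a type never perturbs
  another type's draws), and the solver's scan order is fixed — a fixed seed
  reproduces a mapping bit-for-bit. Under exact cost ties the solver returns
  one optimal permutation deterministically; only the objective value (not
  the tied permutation choice) is asserted against the enumeration oracle.
* **Integer solver**: the integer-approximate route solves the rounded-cost
  problem exactly with the same augmenting-path core and reports its
  objective on the original real costs, making the two solvers directly
  comparable; agreement is measured as the percentage of cells assigned to
  identical sub-spots.
* **Median split ties** in the near/far partition go to `close`; cells
  inside an annotated tumor region can be forced to distance 0.
* **Pseudo-bulk conventions**: simulation pools *sum* raw counts (exact
  integer conservation); confidence scoring *averages* normalized-and-scaled
  profiles. Scaling before averaging is per-gene z-scoring, the common
  practice for classifier features when the reference does not prescribe a
  specific scaling.

## Design decisions that were genuinely open

* The package reads 10x-style MatrixMarket triplets and plain TSV matrices
  only; the on-disk format of upstream pre-processed matrices is not
  standardized, and these two cover public datasets without pulling in
  HDF5-stack dependencies.
* Whether generation mode also changes the surplus branch
  (`num_sc ≥ num_ST`) is unspecified; both modes downsample surplus types
  identically, since synthesis is only ever needed to fill a shortfall.
* The exponentiated-Gaussian noise is applied multiplicatively — the
  standard reading of a $2^{N(0,1)}$ noise factor, and the only one that
  preserves nonnegativity of counts without truncation.
* TPM normalization for full-gene-body platforms is out of scope (gene
  lengths are not an input); only CPM is implemented.
* In the binned single-cell mode a single bin reduces exactly to the
  unbinned pipeline, including the RNG stream, so the two entry points agree
  on small data.

## Problem sizes in the tests

The simulation-based checks run at 200 cells, 5 types, 200 genes and ~5
cells per spot (L ≈ 200), with 10 replicate tissues per noise level; solver
oracle checks use 500+ random instances at K = 2..7 plus 100 Gaussian
instances at K = 50; the confidence-score experiment uses 240 cells over 4
territories with 10% planted swaps. These sizes keep the whole suite in the
tens of seconds while leaving every quantity well away from its decision
threshold.

## Known limitations

* Global fractions only; per-spot composition constraints are a possible
  extension of the LP but are not implemented.
* The cubic solve makes single runs above ~20k sub-spots expensive; use the
  binned mode (single-cell ST) or the integer solver for large inputs.
* Confidence scores are post-hoc and classifier-based, not a posterior over
  assignments; a type mapped to every spot (or none) cannot be scored.
* Generated cells are placeholders for capacity, not biologically meaningful
  profiles; downstream per-cell analyses should use `provenance ==
  "original"` cells.
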