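---
title: "Methods: quantifying and aligning intra-tumoral transcriptomic heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and aligning intra-tumoral transcriptomic heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its models, estimators and the
design choices behind them. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The notion of heterogeneity

`scheter` defines a collection of tumors as *heterogeneous* when cells within
tumors are as dissimilar as (or more dissimilar than) cells between tumors.
This is a relational definition over multiple tumors; it deliberately differs
from composition-based diversity measures (Simpson's index, effective number
of species), which require a prior demarcation of cell subtypes and describe
one tumor at a time. The inputs are normalized (RPKM/FPKM-like) gene × cell
matrices with a dropout mask and a cell → tumor map (`expression_matrix()`).

### Preprocessing

Genes with **more than** a configurable fraction (default 70%) of missing
entries are removed; a gene at exactly the threshold is kept, reading the
filter strictly. Missing entries are encoded in delimited text as empty
fields, `NA` or `NaN`; zeros are observed values, not dropouts (in
Matrix-Market input, absent triplets are the dropouts, which is the natural
sparse encoding but cannot represent an "observed zero" distinctly — use the
delimited form when that distinction matters). Dropouts are imputed by the
per-gene mean over observed entries (default) or by zeros. Bulk matrices for
validation are transformed gene-wise to empirical CDF values, rank/n with
average ties, so values lie in (0, 1] and any strictly monotone per-gene
distortion of the input is irrelevant.

### Cell normalization and the silhouette index

Each cell vector is centered and scaled to **unit norm** over the selected
genes. Under this convention the squared Euclidean distance between two cells
is exactly `2 − 2ρ` with `ρ` the Pearson correlation of the raw vectors;
scaling to unit sample variance instead would multiply all distances by a
common constant and break the exact identity, which is why unit norm is the
default and only convention. Distances are `sqrt(2 − 2ρ)`.

The silhouette of cell *i* is `s(i) = (b(i) − a(i)) / max(a(i), b(i))` with
`a(i)` the average distance to its own tumor's cells and `b(i)` the minimum
over other tumors of the average distance to that tumor's cells. The
own-tumor average **includes the zero self-distance** by default (the
denominator is the tumor size, not size − 1): that is the literal reading of
the defining formula, and on the benchmark simulation it reproduces the
published gap scores while the conventional exclude-self variant does not
(it drives the case-3 NSV to 1.0 rather than ≈ 0.7). `include_self = FALSE`
is available for the conventional silhouette. The **NSV fraction** counts
strictly negative silhouettes per tumor; the headline index is the unweighted
mean over tumors.

### The p_diff score

For the distributions of intra-tumoral (X) and inter-tumoral (Y) pairwise
cell correlations,

```
p_diff = P(X > Y + ε) − P(X < Y − ε),  ε = 0.05 by default.
```

Classical two-sample tests are useless here: hundreds of cells give 10^4–10^6
correlation pairs and any microscopic shift becomes "significant". `p_diff`
is a size-insensitive effect measure in [−1, 1].

Estimation: each sample's density is estimated by a Gaussian KDE with
Silverman's bandwidth, evaluated on a 1001-point grid over [−1, 1] (the
domain of correlations); `n_samples` draws (default 10^5) are taken from each
density by rejection sampling (uniform proposal on the domain, acceptance
probability `p(x)/p_max`), and the two probabilities are the fractions of
matched sample pairs satisfying each inequality. Rejection sampling from the
truncated density needs no renormalization because acceptance only depends on
the density up to a constant. Raw (not z-scored) expression feeds the
correlations; Pearson correlation is invariant to per-cell affine transforms,
so this choice only matters in that it defines the correlation on the
original gene scale. The Monte-Carlo standard error at the default budget is
about 0.002; the estimator is checked against the closed form for Gaussian
X and Y in the test suite and must agree within three standard errors.

For distributions that are not correlations (per-gene Cox coefficients), the
same estimator runs on the pooled data range padded by 5% per side, since
those values are unbounded.

### The entropy baseline

Within each tumor, each gene's marginal density is estimated by the same
Gaussian KDE and its differential entropy computed by numerical integration
of −p log p; genes are treated as independent, so the tumor's entropy is the
sum over genes, and the dataset value is the unweighted mean over tumors.
Entropy is reported in **bits** (base 2): with per-tumor Silverman bandwidths
and the integral estimator, base 2 reproduces the published case-3 minus
case-1 gap scores of the benchmark simulation (≈ 8.0 at noise 0.05 and ≈ 1.8
at noise 0.5), whereas natural-log values do not. Zero-variance genes within
a tumor are skipped with a warning (their KDE is degenerate).

Known limitation: differential entropy under KDE is estimator-dependent. At
the lowest noise level of the benchmark (σ = 0.05), the Silverman bandwidth
over-smooths the 10%-minority modes of the case-2 mixtures and pushes the
case-2 entropy marginally (≈ 0.45 bits on values of ≈ −14) above case 3, so
the entropy baseline does not reliably order the two most similar
compositions even though it clearly separates the extremes. The NSV and
p_diff indices order all three compositions correctly at every noise level —
which is the point of preferring them over entropy.

## The benchmark simulation

`simulate_mixture()` draws 10 genes × 500 cells from five populations (100
cells each). Population *i*'s centroid has `1/sqrt(2)` in genes `2i−1, 2i`
and zero elsewhere (unit norm); each cell is its centroid plus i.i.d.
Gaussian noise of standard deviation σ ∈ {0.05, …, 0.5}. Tumors are
compositions of populations: case 1 — one population per tumor; case 2 — 60
cells from one population and 10 from each other; case 3 — 20 cells from
every population. Cells of each population are dealt to tumors in a fixed
order, so a seed makes the data bit-reproducible. These sizes and noise
levels are the study conditions; the acceptance script regenerates them from
the given seed.

## Gene-cluster hierarchies

### Consensus k-means

`consensus_kmeans()` subsamples 80% of the genes 100 times (both defaults
configurable), runs k-means on each subsample with k-means++ initialization
and Euclidean distance over cells **after per-gene z-scoring** (so highly
expressed genes do not dominate the metric; this mirrors the cell-side
normalization), computes the consensus value of a gene pair as the fraction
of runs containing both genes in which they co-clustered, and prunes an
average-linkage tree on `1 − consensus` distances to k groups. No additional
stability filtering is applied on top of the pruned consensus partition.

### The hierarchy DAG

One clustering per level k = 1..12 (default); a level-(k+1) cluster inherits
a level-k cluster when their overlap is at least 15% of the finer cluster's
size, so a cluster may have several parents (joined from multiple coarser
clusters) and several children (split into multiple finer ones). The k = 1
all-genes root is included by default (`include_root = FALSE` drops it), and
edge weights are `|intersection| / |finer cluster|`.

Edges are stored from the coarser to the finer cluster — roots at k = 1,
leaves at k_max — so that "root-to-leaf paths", "top nodes", "downstream" and
"bottom of a chain" in the reduction, unique-enrichment and alignment
procedures read in their plain graph sense. The inheritance relation itself
(finer inherits coarser) is unaffected by the storage direction.

### Stump reduction

A *stump* is a maximal chain of clusters that stay essentially unchanged over
a range of k. `reduce_hierarchy()` finds the linear nodes (at most one parent
and at most one child), groups them into maximal chains along edges, appends
to the bottom of each chain its unique child when that child has exactly one
parent and multiple or no children, collapses each appended chain to a single
reduced node, maps every other node to its own reduced node, and adds a
reduced edge for every original edge whose endpoints map to different reduced
nodes. Requiring the appended child to have exactly one parent is a
deliberate guard: appending a multi-parent node would fuse independent
lineages into one stump. Reduction is idempotent and conserves gene content;
the reduced node's representative gene set is the **deepest** (largest-k)
cluster of its stump by default — downstream analyses treat reduced clusters
as single gene sets, and the deepest member is the most refined one — with
the union available as an option.

Per-cluster annotations are the cluster's own `p_diff` and NSV (computed on
its gene subset over all cells) and its *density*, the fraction of observed
entries in the cluster's submatrix of the pre-imputation mask. Homogeneity
ranks (`rank_pdiff()`) are descending in `p_diff` with average ties.

## Unique enrichment

Enrichment of a cluster in a gene set is the upper-tail hypergeometric
probability of the observed overlap; the enrichment universe defaults to the
genes that survived preprocessing in the dataset (overridable). FDR
adjustment is Benjamini–Hochberg **within each cluster** by default — each
cluster's tests across the collection form one family, matching per-cluster
reporting — with a global scope available.

A gene set is *uniquely enriched* in the most downstream cluster whose
enrichment cannot be attributed to a substructure. The algorithm sorts
clusters by the −log10 adjusted p-value (ties broken toward the smaller
cluster id), grows a top-ranking list L while restricting the root-to-leaf
paths to those containing all of L, and stops when the next sorted cluster
(1) leaves every candidate path, or (2) scores below both half the last
member's score and the reporting threshold 5.0, or (3) completes a candidate
path. Rule (2) is checked before rule (3): a low scorer never joins L even
when it would complete a path — otherwise a negligible leaf could "complete"
a path and veto an otherwise clean report, contradicting the intended
behavior in which traversal stops at a weak cluster and the path is spanned
by the strong members accepted so far. The maximal path is then the candidate
path itself if L completed one; otherwise the subpath spanned by L on a
hole-free candidate path (a *hole* is an on-path cluster outside L scoring
strictly below L's minimum), or the longest contiguous run of L members when
every path has holes. Before extraction, the last member of L is discarded
when the next sorted cluster is its sibling with a comparably high score
(greater than half of it and above 5.0) — the enrichment then splits between
siblings and neither is uniquely supported. The path may finally be extended
through a parent/child when exactly one qualifies (sort rank within 5 of the
path's maximum rank, score ≥ 5.0). The bottom node is reported only when its
transformed score is at least 5.0. The rank window (5) and the score
threshold (5.0) are distinct parameters that happen to share a numeral; both
are configurable. Path lists are processed in lexicographic node-id order so
tie-breaks are deterministic.

## Aligning hierarchies across datasets

### Cluster overlap and path matching

Two clusters from two datasets *overlap* when their Jaccard index exceeds
0.2, or lies in [0.1, 0.2] while each cluster ranks within the other
dataset's top ten partners by that ratio. Paths are matched between datasets:
a pair of contiguous subpaths (of root-to-leaf paths) is *matched* when more
than 90% of their cross cluster pairs overlap, and *maximally matched* when
no matched pair of containing subpaths exists. Two implementation decisions
matter here:

* **Minimum path length 2.** A single cluster carries no lineage (edge)
  information — the downstream factorization operates on edges — yet a coarse
  single cluster can pair with almost any foreign path through the top-ten
  fallback, and the trimming rule below has no "downstream portion" to test
  on it. Subpaths therefore need at least two nodes per side.
* **Exact prefilter.** A subpath containing `d` clusters that overlap nothing
  in the partner dataset fails at least `d/length` of its pair tests, so any
  subpath with `d/length ≥ 0.1` is discarded before enumeration. This is a
  pure speed-up (no false negatives); it keeps the pairwise enumeration
  tractable when unstable background clusters make the DAG path-rich.

### Trimming and mergeable groups

A matched path's top node is trimmed when its *complementary paths*
(root-to-leaf paths of the same hierarchy through that top whose below-top
portions are node-disjoint from the path's) and the path's matched partners
are poorly overlapped below the tops — more than half of those cluster pairs
fail the overlap rule. The canonical case is the all-genes root joining
unrelated branches. The rule is iterated to a fixed point, because trimming
one side exposes the other side's top, and trimmed pairs are re-verified
against the 90% bar and dropped when they no longer match: without this,
diamond motifs (a node with two parents sharing a grandparent) block the
complementary-path test and let roots leak through.

Two maximal paths of one dataset are *mergeable* when their tops coincide
and, in at least one common partner dataset, a matched path of each pair
overlaps in more than 90% of cluster pairs. Maximal cliques of the mergeable
relation (exact enumeration via igraph; instances are tens of paths) become
path groups, each spanning a subgraph — the union of its paths' nodes and
consecutive edges.

### Factorization and meta clusters

Per dataset, subgraphs form a binary subgraph × edge membership matrix A.
For each K in 2..10, A ≈ WH is computed by multiplicative-update NMF
(Frobenius objective, uniform random initialization, 500 iterations); each
row of H is quantized by keeping entries at least 10% of the row maximum, and
the unique quantized components with more than one edge that form a single
connected subgraph are pooled over K. Components are then merged across (and
within) datasets: two components are mergeable when, in both directions, at
least 75% of the clusters incident to one's edges overlap a cluster incident
to the other's, using the same two-tier overlap rule (within a dataset a
cluster always overlaps itself, so same-dataset matching subsumes shared
edges). Computing the 75% rule on incident clusters rather than raw edge sets
is deliberate: edge sets from different datasets can never intersect
literally — cross-dataset meta clusters would be impossible — and on the
package's worked four-subgraph example the two components {e1,e2,e4} and
{e1,e2,e3} share exactly 3 of 4 incident clusters, making the merge
consistent with the 75% rule, whereas their edge-set overlap (2/3) is not.
Maximal cliques of mergeable components are combined into meta clusters; a
reduced cluster belongs to a meta cluster when it is an endpoint of one of
its edges, so one cluster may belong to several meta clusters, and clusters
incident to no component are *orphans*.

The whole factorize-and-merge stage is repeated over randomized trials
(default 100); each trial yields a binary cluster co-occurrence matrix, and
the consensus is the medoid trial under Hamming distance (ties to the
earliest trial). Combining meta clusters beyond that point is a curation
step: it is exposed as a user-supplied merge map and never automated.

### Characterizing meta clusters

Per meta cluster, dataset and gene set, the enrichment score is the geometric
mean of the −log10 FDR-adjusted p-values over the nodes of all maximal paths
(≥ 3 nodes) within the meta cluster's subgraph whose members all pass the
adjusted p ≤ 10⁻³ cutoff; absent when no path qualifies. Disconnected member
sets are repaired with minimal connecting paths, and connector nodes claimed
by other meta clusters are subtracted again. Gene sets are reported when
enriched in at least two datasets for at least one meta cluster; because
p_diff scales differ across datasets, intra-tumoral homogeneity of a meta
cluster is summarized as the mean of its members' within-dataset p_diff
ranks, not of the raw scores. The grouping of reported sets into display
groups is parameterized by two user-chosen focal meta clusters (counts of
supporting datasets decide group 1/2/3) rather than hard-coding any
particular pair.

## Bulk validation

Expression coherence of a cluster in bulk data is the p_diff deviation of its
member genes' pairwise correlations from the pairwise correlations of 8000
randomly selected background genes (all genes when fewer exist; the selection
is made once per dataset under the caller's seed). Survival association fits
one univariate Cox proportional-hazards model per gene (Breslow ties;
non-converging fits are skipped and counted) — conventionally on
CDF-transformed expression — and compares the member genes' coefficient
distribution with all genes' via p_diff; a positive deviation means
expression is negatively associated with survival time. For each meta
cluster, members' enrichment among the top-ranked clusters (sorted by either
metric) is a random walk that increments at members; normalized by its
terminal value it is compared with the straight null line through a one-sided
Kolmogorov–Smirnov p-value `exp(−2 n D⁺²)` computed on the n-cluster curves,
treating the null line as the theoretical uniform CDF. The one-sided form is
fixed to "members above the line" (enrichment at the top); no two-sided
variant is offered.

## Subtype prediction

`extend_panel()` splits a marker panel (e.g. PAM50) into three groups by the
same consensus k-means machinery (fixed k for determinism), ranks every
non-panel gene by its maximum group-level average correlation with the panel
in each of two bulk datasets separately, and keeps the genes in both top-200
lists. `predict_cell_subtype()` correlates each cell with every labeled
reference sample over the panel (pairwise-complete Pearson on raw values, so
dropouts are simply skipped; per-cell affine transforms cannot change the
calls), averages within each subtype and calls the maximum; the full average
vector is kept so cells can be filtered by a minimum correlation (raising the
threshold never admits more cells). Patients are called by plurality over
their classified cells, with ties broken toward the subtype whose cells
correlate better and flagged as ambiguous.

## Simulated fixtures: what they do and do not show

`simulate_hierarchy_suite()` plants co-expression blocks as two-level latent
factor structures — a block factor (with a tumor-level shift) plus two
sub-block factors whose gene split is drawn independently per dataset. The
dataset-specific splits are essential: with identical clean splits everywhere,
sibling sub-clusters are disjoint between datasets, and the trimming rule
(correctly) reduces every match to its bottom two nodes, leaving no edges for
the factorization; partially overlapping substructure is exactly the regime
the alignment is designed for. Shared blocks reuse gene identifiers across
datasets; private blocks and background noise genes are dataset-specific.
`simulate_bulk_survival()` plants a coherent block through a single latent
factor with loading `sqrt(ρ)` (pairwise correlation ≈ ρ) and exponential
survival times with log-hazard proportional to that factor, censored at a
fixed quantile.

None of the simulators attempt realistic scRNA-seq count noise: no
dropout-rate curves, no library-size effects, no overdispersed counts —
expression is Gaussian around structured means, matching the benchmark
design. Passing tests therefore demonstrate correctness of the estimators and
algorithms under their stated models, not robustness to the full error
structure of real single-cell data. Gene identifiers are matched exactly
across datasets; no alias resolution is attempted.

## Numerical choices and problem sizes

Randomness is governed by explicit `seed` arguments throughout; reports
record the seed used. KDE bandwidths are Silverman's rule everywhere (the
entropy comparison and the p_diff estimator deliberately share the
convention). The rejection sampler draws in batches of `2 n` proposals until
filled. NMF retries are unnecessary in practice because multiplicative
updates cannot diverge from a uniform random start; degenerate all-zero rows
in quantization are skipped. The test suite runs the benchmark at its
published size (500 cells) with 10 seeds for the gap scores and 2 × 10⁴
rejection samples per p_diff, the alignment recovery at 3 datasets × 84
genes × 120 cells with 15 consensus trials, and the survival validation at
250 samples × 140 genes; these sizes were chosen as the smallest at which the
planted effects are unambiguous, and the acceptance script uses the same
ones.

## Known limitations

* The entropy baseline's case-2/case-3 ordering at very low noise is
  estimator-dependent (see above); NSV and p_diff are the indices of record.
* `p_diff` inherits KDE boundary bias near ±1; correlations piling up at the
  boundary (near-duplicate cells) are slightly smoothed inward, which shrinks
  extreme scores by a few hundredths.
* Path matching enumerates contiguous subpaths of root-to-leaf paths; in
  pathological DAGs with many diamond motifs the enumeration can still grow
  quickly despite the prefilter. Reduced hierarchies of the intended size
  (tens of nodes) are unproblematic.
* The uniqueness algorithm's tie-breaks (sort order, path order) are
  deterministic but arbitrary where the underlying scores are exactly tied.
* Hierarchy alignment assumes shared gene identifiers across datasets.
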