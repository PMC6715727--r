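---
title: "From mesoscale constraints to stochastic micro-connectomes"
author: "corticonn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From mesoscale constraints to stochastic micro-connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corticonn)
```

## The modeling problem

Tracer experiments constrain cortical long-range connectivity at the
mesoscale: region-to-region projection strengths, laminar synapse
profiles, the topographic organization of projections, and — from
whole-brain single-axon reconstructions — statistics of which *sets* of
regions individual axons innervate. None of this pins down a unique
neuron-to-neuron connectome. `corticonn` treats the micro-connectome as
a random draw from the space of wiring diagrams consistent with the
mesoscale constraints, provides fitting code for each constraint, a
stochastic instantiation algorithm, and analyses of the micro-structure
that the constraints induce.

All stages are exercised on synthetic fixtures with planted ground
truth. This vignette explains the model behind each stage, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the fixture-scale tests do and do not show.

## Synapse-density budgeting

The wild-type ipsi/contra strength pair (`projection_matrix`) is scaled
by the factor $\sigma$ solving

$$\sigma \sum_{a,b} (M_i + M_c)[a,b] \; V[b] \; C_t[a,b] = B,$$

with $V$ the region volumes, $C_t$ the target-coverage fractions
(all ones by default; coverage data can be supplied), and $B$ the
long-range synapse budget. The budget is an explicit argument with
default $68.74\times 10^9$. A total cortical budget can be derived from
the measured mean density of 0.72 synapses/μm³ times an isocortex volume
of 123.2 mm³ (`total_synapse_budget()`, ≈ 88.7 billion), from which
local (within-region) synapses are subtracted; because the two published
figures for that subtraction differ, the budget here is configuration,
not computation, and the default follows the scaling equation's
right-hand side.

`split_by_class()` produces the five class matrices by scaling
module-to-module blocks of the wild type with per-class weights,
normalized per block cell. Exact conservation
($\sum_{\text{classes}} = $ wild type, to the last bit) is achieved by
assigning one class the residual rather than trusting floating-point
normalization to sum to 1. Regions lacking layer 4 get a zero L4 row;
their L4 weight share is redistributed over the remaining classes so
conservation still holds exactly.

`apply_strength_cutoff()` removes the weakest projections: the cutoff is
the largest value in the multiset of projection densities such that the
synapses removed (density × target volume × coverage) stay strictly
below the configured loss bound (default 5%). Maximality is brute-force
checkable: raising the cutoff to the next distinct density violates the
bound. The cutoff is evaluated after class splitting, on the per-class
projection list, which matches reading the loss bound as a bound on
projection synapses.

`mirror_contralateral()` expands the single-hemisphere data onto both
hemispheres assuming mirror symmetry, producing one full matrix per
class with $D[r\to t] = D[\text{mirror}(r)\to\text{mirror}(t)]$ exactly
and zero diagonal (within-region connectivity is local and out of
scope).

## Layer profiles

Each projection is assigned one of six prototype laminar profiles
(relative density per layer, thickness-weighted mean 1). The profiles
themselves are inputs; the synthetic library uses six profiles peaking
in different depth bands. The assignment algorithm:

1. expected profile frequencies for a source module = projection-count
   weighted average of the per-class frequency vectors;
2. adjustment factors = observed module frequencies / expected, with
   0/0 defined as 1 and positive/0 an error;
3. feedforward/feedback from hierarchy scores (feedforward iff
   source score ≤ target score — ties count as feedforward, an explicit
   tie-break);
4. halve the *adjustment factors* of the opposite-type prototypes
   (feedback prototypes 2, 4, 6 for feedforward projections and vice
   versa) — the halving is applied to the factors, and since the final
   step multiplies factors by the class frequency vector, halving the
   factors or the frequencies changes the argmax identically here;
5. pick the argmax, ties toward the lowest profile id.

The assignment is a pure function; determinism is tested.
`profile_zscores()` implements the validation operation (prediction
minus mean of raw replicate profiles over their SD, requiring at least
five replicates).

## Topographic mapping

A projection's spatial structure is encoded by barycentric coordinate
systems. Source anchors are the three mask pixels maximizing the sum of
pairwise distances — the search is restricted to convex-hull vertices,
which is sufficient because the objective is convex in each point —
then moved 25% toward the mask centroid (the centroid of the whole
mask, not of the three points; the choice matters only by a few
pixels). Each source voxel is colored by its clamped barycentric
coordinates; the projection image accumulates color × strength per
target pixel, ignoring source voxels with HSV saturation below 0.5;
the lightness scale makes the brightest pixel's channel sum 1.
Normalization divides each pixel by its channel sum floored at
$\sigma_{tgt}$, 25% of the maximum, so weakly innervated pixels fade to
black instead of being amplified.

Target anchors are fitted by derivative-free (Nelder–Mead) multi-start
optimization of

$$J = \underbrace{\text{mean}_{\text{reliable pixels}} \lVert
  \text{color}_{\text{anchors}} - N \rVert_1}_{\text{color match}}
  + \lambda \cdot \text{fraction of source mapped outside target},$$

with $\lambda = 1$ by default. Two numerical choices deserve note.
First, the color term is evaluated on *reliable* pixels only (those
whose raw channel sum reached the normalization floor): faded pixels
carry no usable hue because the saturation filter removes the central
source voxels, and including them biases the fit measurably even on
noise-free fixtures. Second, the eight restarts start from the eight
canonical orthogonal placements (four rotations × optional reflection)
of the source triangle in the target mask, which makes the label
recovery over all eight planted transforms robust.

The Gaussian kernel width — projections map points to areas, not
points — is chosen on a log grid by minimizing the Kolmogorov–Smirnov
distance between saturation distributions of the convolved anchor
coloring and the data image. A final polish step refines anchors and
width jointly against the pipeline-level relative error (the printed
formula: sum of absolute differences over the two images' average and
the pixel count), computed between the data image and the image the
fitted mapping itself generates when pushed through the same
render-and-normalize pipeline. That comparison has its minimum at a
perfect fit, which is what makes the planted-recovery tolerance
(anchors within one pixel, error below 2%) attainable; comparing crisp
anchor colors against a blurred data image would bottom out near 10%
even at the true anchors. Nelder–Mead is restarted once at its own
optimum to escape simplex collapse.

`characterize_transform()` reports a reflection iff the signed area of
the anchor triangle flips, and the rotation as the nearest multiple of
90° of the rotation component after factoring the reflection out as a
first-axis flip.

## The projection-type tree

Single axons innervate subsets of regions ("p-types"); with 27 targets
there are $2^{27}$ possible subsets, so the model must be generative,
not tabulated. The tree model places regions at the leaves of a
directed tree; an axon percolates outward from its source leaf,
crossing each directed edge it reaches independently with the edge's
probability, never revisiting a refused edge. With edge length
$-\log_{10} p$:

* first-order probability: $P(S\to T) = 10^{-L(S,T)}$ (path length is
  additive);
* conditional increase:
  $I(S; T_1, T_2) = 10^{L(S \to \mathrm{lca}(T_1,T_2))} \ge 1$, where
  the lowest common ancestor is taken **in the tree rooted at the
  source leaf** — equivalently the node where the paths from $S$ to the
  two targets diverge. (With the lca taken at the global root the
  formula fails exactly when the source sits inside the subtree under
  that lca; exhaustive enumeration of all percolation outcomes on small
  trees confirms the rooted-at-source reading, and the tests assert
  agreement to 1e−12.)

Class-specific first-order predictions use
$P = k_c \sqrt{\mathrm{nps}}$ with $k = 0.5$ (L2/3, L6), $0.33$
(L4, L5PT), $0.22$ (L5IT), clipped at 1, where nps is projection
strength over source volume.

**Topology.** A Louvain resolution sweep on the symmetrized normalized
connection density matrix, from γ = 6 (every region its own community)
down to 0 (one community, the root) in steps of 0.05 (the endpoints are
given; the step is a package choice — results are insensitive to it on
fixtures because merges are driven by the community structure, not the
step). Two communities merge when a detected community contains more
than half of each; simultaneous multi-way merges are binarized in
lexicographic region order, so the skeleton is binary and reproducible
under a fixed seed.

**Edge probabilities.** A leaf-to-root pass over sibling motifs
$(T_1, T_2, R)$ solves, in least squares, the up-length difference
(mean row difference of the working distance matrix over all reference
nodes outside both subtrees), the down-length difference (mean column
difference), and the two cross-sibling distances through the parent.
The reference set is every active node outside the motif; where data
are missing (absent projections) the length is floored at
$-\log_{10}\varepsilon$, $\varepsilon = 10^{-6}$. After each motif the
parent inherits the averaged child distances.

The four motif equations are structurally rank-3: shifting both child
up-lengths by $+t$ and both down-lengths by $-t$, compensated on the
parent's own edge, changes no leaf-to-leaf path length. The minimum-norm
solution can therefore assign negative lengths even on perfectly
additive inputs, and clamping them locally destroys additivity. The
package instead resolves the gauge globally: the non-negativity (and
$\le -\log_{10}\varepsilon$) constraints on all edges form a
difference-constraint system over one shift per internal node, which on
a tree is solved exactly by an interval dynamic program (bottom-up
feasible intervals, top-down midpoint assignment). On additive inputs
recovery is then exact to machine precision (tested at 1e−6 over 50
random trees, observed ~1e−15); genuinely inconsistent inputs may still
require clamping, which is flagged on the returned tree.

**Statistics.** Pairwise co-innervation is tested against the
hypergeometric null (two-tailed, rejection at p < 0.05);
profile-similarity structure is compared via pairwise Hamming-distance
distributions and a two-sample KS test, with a naive
independent-Bernoulli control.

## Instantiation

* **Allocation**: each projection gets a random `round(f·N)` subset of
  the source population; specified pairwise interactions enforce
  overlaps of `round(f_a·f_b·increase·N)` by swap-in resampling;
  unspecified pairs default to independence. Infeasible demands error
  with the offending pair.
* **Counts**: expected synapses = density × targeted volume,
  distributed over layers ∝ profile × thickness and uniformly over a
  layer's voxels. Fractional expectations are realized by stochastic
  rounding (floor plus Bernoulli of the remainder), a package choice
  that preserves the expectation exactly.
* **Placement**: within each voxel, segments are sampled with
  replacement ∝ length; offsets are uniform in [0, 1]. A voxel with no
  segments hands its count to the nearest voxel that has some (logged).
* **Source assignment**: allocated source somata are mapped through the
  barycentric pair into target flat space; per synapse the k = 100
  nearest mapped positions (exhaustive exact-k search, ties at the k-th
  distance broken by neuron id) are weighted by an isotropic Gaussian
  of the fitted kernel width; width 0 degrades to a uniform draw over
  the tied nearest.
* **Classes**: L2/3, L4, L6 pyramidal cells join their layer's class;
  slender-tufted and untufted L5 cells are L5IT; thick-tufted L5 cells
  are L5PT with probability one half (the rest corticothalamic, outside
  the cortical model); interneurons none.
* **Output**: a TSV edge table with SONATA edge-group column names plus
  a JSON sidecar, and one MatrixMarket sparse connection matrix per
  target region; the round trip is lossless and the matrix marginals
  equal per-neuron synapse counts.

Participation fractions from clipped probabilities
($\min(1, k\sqrt{\mathrm{nps}})$) are left unnormalized; the clip is
visible in validation output rather than silently renormalized.

## Micro-structure analyses

`reciprocal_overexpression()` samples a disc in region B around a
random neuron, maps its center into region A through the fitted
mapping, optionally shifts it by an offset in a seeded random
direction, and pools unidirectional and reciprocal connection counts
over samples; the ratio is observed over the independence expectation.
On fixtures with mapping-driven connectivity the ratio exceeds 1 and
grows with the offset; with independent connectivity it stays near 1.

`triplet_motif_counts()` samples one neuron per region per triplet and
tabulates the 64 directed states of the six ordered pairs against the
product expectation from empirical pairwise edge probabilities, with
per-motif z-scores.

`module_edge_density_analysis()` detects within-region modules
(seeded Louvain on the symmetrized intra-region graph; the clustering
method is a configurable package choice recorded in the result), forms
the module-to-module edge-density matrix, and compares the width of its
distribution at half the modal height (Gaussian KDE, default `nrd0`
bandwidth; width = distance between the outermost half-height
crossings) against degree-preserving edge-swap controls (≥10 swaps per
edge; degree conservation is exact and tested).

## Synthetic fixtures: what they do and do not show

The generator plants known ground truth in every input: region/layer
geometry with exact volume bookkeeping and mirror symmetry, projection
tensors whose expected strengths follow a planted barycentric mapping
with Gaussian spread plus optional half-normal noise, Poisson neuron
counts with at least one dendritic segment per neuron, and axon tables
drawn from a known tree. Default fixture conditions: a
10×10×12-voxel atlas at 100 μm (two regions per hemisphere, six
layers), planted kernel width 60 μm, noise 0 for recovery tests,
10,000 sampled axons for Monte-Carlo checks, a ~10⁴-neuron fixture
(20×20×12 voxels at 2 neurons/voxel) for instantiation statistics —
sizes chosen so every distributional check operates at 3-standard-error
resolution.

Passing these tests shows the estimators are *correct*: they recover
what was planted, conserve what must be conserved, and converge at the
Monte-Carlo rate. It does not show that real tracer data satisfy the
model's assumptions — linear continuous mappings, module-block class
scaling, tree-generated co-innervation — nor reproduce any published
full-scale figures, which require the original atlas-scale inputs and
ten-million-neuron instances.

## Reproducibility

Every stochastic operation takes an explicit seed and runs under a
locally set RNG state; pipeline stages derive independent sub-stream
seeds from one root seed (`derive_seed`), so stages can be re-run in
isolation and a recipe rebuilt from the same seed is byte-identical.
`scripts/acceptance.R --seed N --out file.json` recomputes the headline
quantities from scratch under any seed.
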