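# corticonn

Stochastic generation and analysis of long-range cortical
micro-connectomes in R.

Mesoscale tracing experiments constrain cortical long-range connectivity
only at the region-to-region level: how strongly region *A* projects to
region *B*, in which layers the synapses land, and how the projection is
topographically organized. A neuron-level (micro-) connectome consistent
with those constraints is not unique — it is a random draw from the space
of wiring diagrams they admit. `corticonn` implements a pipeline that
turns mesoscale constraints into concrete stochastic connectome
instances, and the micro-structure analyses that quantify what the
constraints imply at neuron resolution. It is aimed at computational
neuroanatomists building or evaluating large-scale cortical network
models.

The pipeline has four fitting stages and two consumer stages:

1. **Synapse densities** (`compute_scaling_factor`, `split_by_class`,
   `apply_strength_cutoff`, `mirror_contralateral`). Raw projection
   strengths *M<sub>i</sub>*, *M<sub>c</sub>* are scaled by a factor σ
   chosen so that
   σ · Σ<sub>a,b</sub> (M<sub>i</sub> + M<sub>c</sub>)[a,b] · V[b] ·
   C<sub>t</sub>[a,b] equals the long-range synapse budget (default
   68.74 × 10⁹ synapses, derived from a mean density of 0.72 μm⁻³ over
   123.2 mm³ of isocortex minus local synapses). The scaled matrix is
   split into the five projection classes (L2/3, L4, L5IT, L5PT, L6) by
   module-block weights, weak projections are cut off so that less than
   5% of synapses are lost, and densities are mirrored onto both
   hemispheres.
2. **Layer profiles** (`assign_profiles`). Each projection gets one of
   six prototype laminar profiles via expected frequencies, observed /
   expected adjustment factors, and a feedforward/feedback halving rule.
3. **Topographic mapping** (`fit_topographic_mapping`). Each projection's
   spatial organization is a pair of barycentric coordinate systems: the
   normalized projection image
   N[a,b] = I<sup>raw</sup>[a,b] / max(ΣRGB, σ<sub>tgt</sub>) is fitted by
   three target anchor points plus a Gaussian kernel width, and the fit is
   characterized by its reflection/rotation and a relative error.
4. **Projection types** (`fit_ptype_tree`, `sample_innervation_profiles`).
   Which region *subsets* single axons innervate follows a generative
   tree model: regions are leaves, each directed edge carries a crossing
   probability, and an axon percolates outward from its source leaf.
   First-order probabilities are P(S→T) = 10<sup>−L(S,T)</sup> with L the
   additive path length (−log₁₀ p per edge), and the conditional
   co-innervation increase is 10<sup>L(S→lca(T1,T2))</sup> (lca taken in
   the tree rooted at the source). Topology comes from a Louvain
   resolution sweep (γ from 6 to 0); edge probabilities from local
   least-squares on sibling motifs with a global gauge repair.
5. **Instantiation** (`allocate_source_neurons`,
   `projection_synapse_counts`, `sample_synapse_positions`,
   `assign_presynaptic_neurons`). Densities become per-voxel synapse
   counts (layer-profile × thickness weighted), synapses land on
   dendritic segments sampled ∝ length, and each synapse is assigned a
   presynaptic neuron among the 100 nearest mapped source positions with
   Gaussian kernel weights.
6. **Micro-structure** (`reciprocal_overexpression`,
   `triplet_motif_counts`, `module_edge_density_analysis`). Reciprocal
   connectivity against the independence expectation, 64-state triplet
   motif counts, and module-to-module edge-density distributions against
   degree-preserving edge-swap controls.

Every input the pipeline needs — voxel atlas, flat map, projection
tensors with a planted topographic mapping, neuron/segment tables,
single-axon innervation matrices — can be generated synthetically with
known ground truth (`build_synthetic_atlas`, `demo_fixture`,
`synth_neurons_and_segments`, `synth_axon_table`), so the whole pipeline
is testable at desk scale.

## Worked example

```r
library(corticonn)

ab <- build_synthetic_atlas()          # 4 regions, 6 layers, 10x10x12 voxels
fx <- demo_fixture(ab, seed = 3)       # planted wild-type matrix, profiles,
                                       # and a tensor with a planted mapping
rec <- build_recipe(ab$atlas, ab$flatmap, fx$wt, fx$class_module_weights,
                    fx$tables, fx$library, fx$tensors, seed = 3)
rec
#> Long-range connectivity recipe
#>    36 projections over 4 regions; cutoff 5.912 um^-3 (loss 3.21%)
#>    20 p-type blocks; 1 fitted mappings
```

The cutoff line says the weakest projections were removed at a density
threshold of 5.9 μm⁻³ (large because the fixture is tiny), losing 3.21%
of projection synapses — below the 5% bound. Each of the 20 p-type
blocks lists, for one (class, source region), the first-order innervation
fraction per target and the pairwise conditional increases from the
fitted tree. The fitted mapping for the planted tensor can be inspected:

```r
rec$mappings[["1->2"]]
#> Topographic mapping; kernel width 59.98 um; relative fit error 0.000381
#>   transform: reflection no | rotation 0 deg
```

The planted kernel width was 60 μm and the planted transform was the
identity; both are recovered. `validate_recipe(rec, ab$atlas)` returns a
zero-row violation table, and `write_recipe()` serializes the recipe to
YAML for the instantiation stage.

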