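# spatialCCI

Cell–cell interaction (CCI) network reconstruction from single-cell
expression and spatial coordinates, with multi-slice 3D alignment.

Spatial transcriptomics measures where cells sit and what they express,
but the interaction network connecting them is never observed directly:
measured neighbourhood graphs are noisy, incomplete (edges missing
because of dropped cells or sectioning artifacts), and confined to one
2D section at a time. `spatialCCI` is for analysts who want to

* reconstruct a cell-level interaction network from a partial spatial
  graph plus expression, recovering edges that were never observed;
* build gene-level communication networks from curated ligand–receptor
  (L-R) pair databases;
* align consecutive tissue sections into a common 3D frame and find
  interactions that cross tissue layers.

## The model

Cells are nodes of a graph. The observed adjacency `A` is the
symmetrized k-nearest-neighbour graph of the spatial coordinates
(Euclidean distances; each cell connected to its `n` nearest
neighbours), or — at gene level — the symmetric graph of L-R pairs found
in a curated database. Expression `X` (cells × genes, z-scored per gene)
provides the node features.

A variational graph autoencoder is trained to reproduce `A`:

* **Encoder** — three graph-convolution layers
  `H⁽ˡ⁾ = ReLU(Â H⁽ˡ⁻¹⁾ W⁽ˡ⁻¹⁾)` with
  `Â = D̃^{-1/2}(A + I)D̃^{-1/2}`, followed by two linear
  graph-convolution heads giving per-cell Gaussian parameters `μ` and
  `log σ`.
* **Latent** — `z = μ + σ ⊙ ε`, `ε ~ N(0, I)` (reparameterization), with
  a two-layer adversarial discriminator pushing the latent distribution
  toward the `N(0, I)` prior.
* **Decoder** — inner products through the logistic function:
  `A′ᵢⱼ = sigmoid(zᵢ · zⱼ)`.
* **Loss** — `L = L_recon + β·L_KL` (+ adversarial generator term),
  where `L_recon` is class-weighted binary cross-entropy on the
  off-diagonal entries and
  `L_KL = ½ Σⱼ (μⱼ² + σⱼ² − 1 − log σⱼ²)` per cell.

Edges with high reconstructed probability that were absent from the
input are the recovered (imputed) interactions.

For 3D work, consecutive slices are matched with entropic
Gromov–Wasserstein optimal transport on their intra-slice distance
matrices (`GW(C,P) = Σ (D_X(i,j) − D_Y(k,l))² P(i,k) P(j,l)`, solved by
annealed Sinkhorn–Knopp scaling), registered with a closed-form weighted
Procrustes rotation + translation, refined by mutual-nearest-neighbour
iterations, and stacked with a fixed layer spacing.

## Worked example

Simulate a 200-cell tissue with 4 spatial communities, remove half of
the true edges, train, and score recovery of the held-out edges:

```r
library(spatialCCI)

tissue <- simulateTissue(nCells = 200, nGenes = 50, nCommunities = 4,
                         seed = 1)
tissue
#> TissueFixture: 200 cells, 50 genes, 4 communities
#>   edges: 773  (kNN, n = 6 )

X <- standardizeExpression(tissueExpression(tissue))
A <- tissueAdjacency(tissue)

edgeRemovalExperiment(X, A, fractions = 0.5, seeds = 0:4)
#> EvalReport: 5 rows, 1 condition averages
#>     condition   acc auroc    ap
#>  fraction=0.5 0.788 0.873 0.797
```

With 50% of edges hidden, the model calls held-out edges vs an
equal-size sample of non-edges with accuracy 0.79 (threshold 0.5) and
ranks them with AUROC 0.87, averaged over five seeds. A single fit
exposes the reconstructed network directly:

```r
fit <- trainVGAE(X, A, seed = 1)
fit
#> CCIFit: 200 nodes, latent dim 32
#>   trained 30 epochs; total loss 7.2498 -> 4.8138
head(rankedEdges(fit), 3)
#>    node_i  node_j probability
#> 1 cell133 cell135   0.6067254
#> 2 cell102 cell133   0.6059722
#> 3 cell133 cell140   0.6052186
```

`simulateMultislice()` + `alignSlices()` + `procrustesTransform()` +
`refineTransform()` + `stackSlices()` cover the 3D path, and
`runPipeline()` wires every stage from a YAML config (a thin CLI lives
in `inst/scripts/run_pipeline.R`).

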