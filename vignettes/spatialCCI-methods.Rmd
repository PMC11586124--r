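---
title: "spatialCCI: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spatialCCI: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the graph model and its assumptions, the parameters that
matter, what the synthetic generators emulate, and the numerical and
design decisions taken where the method left them open.

## The reconstruction model

A tissue is modelled as a graph whose nodes are cells. The observed
adjacency is built from spatial coordinates: each cell is linked to its
`nNeighbors` nearest cells by Euclidean distance and the directed result
is symmetrized by logical OR. The biological assumption is that in
solid tissue a cell physically touches a handful of immediate
neighbours and that interaction is dominantly local. `nNeighbors`
defaults to 6 (a cell in a 2D packing touches roughly six others);
because the kNN rule is applied per cell before symmetrization, actual
degrees are at least `nNeighbors` but can exceed it. Exact distance
ties (regular grids) are broken stably by node index so graphs are
reproducible. At gene level the same container holds a different graph:
genes are related iff some curated ligand–receptor pair connects them,
in either direction, with multi-subunit complexes expanded
subunit-by-subunit.

The generative model is a variational graph autoencoder. A three-layer
GCN encoder (`ReLU(Â H W)` with the self-loop-normalized propagation
operator `Â`) feeds two linear graph-convolution heads producing a
per-cell Gaussian posterior (`μ`, `log σ`). A latent sample
`z = μ + σ ⊙ ε` is decoded through inner products,
`p(edge i~j) = sigmoid(zᵢ·zⱼ)`, so edge probability grows with latent
similarity. The objective is class-weighted binary cross-entropy on the
off-diagonal adjacency entries (positive-class weight = non-edges /
edges, so sparse graphs do not collapse to "no edge") plus
`β · KL(q(z|x) ‖ N(0, I))` with the standard diagonal-Gaussian KL,
`½ Σⱼ (μⱼ² + σⱼ² − 1 − log σⱼ²)` summed over latent dimensions and
averaged over cells. Self-loops are excluded from the loss and from all
scoring. An adversarial regularizer — a two-layer MLP discriminator
trained to tell prior samples from encoder latents, one discriminator
step then one encoder step per epoch — additionally pushes the
aggregate latent distribution toward the prior, which stabilizes the
representation under input noise.

Evaluation decodes the posterior mean (`sigmoid(μμᵀ)`); sampling is a
training-time device for propagating gradients through the posterior,
and scoring a single stochastic draw would only add variance.

## Training numerics

Training is full-batch Adam for 30 epochs by default. Two numerical
choices matter and were made deliberately:

* **Regularizer warm-up.** The KL and adversarial weights ramp linearly
  from 0 to their targets across the run (`warmup = TRUE`). In a short
  full-batch budget the prior pull otherwise dominates before the
  reconstruction signal develops, shrinking all latent means toward
  zero and leaving edge probabilities compressed around 0.5. The final
  weights are the configured ones (`beta = 1` by default), so the
  objective at the end of training is the stated objective.
* **Adam first moment `β₁ = 0.5`.** The common convention for
  adversarial objectives; high momentum (0.9) oscillates in the
  discriminator game and measurably slows convergence over 30
  full-batch steps.

Defaults: hidden widths `[64, 64, 32]` (exactly three GCN layers),
latent dimension 32, learning rate 0.01, discriminator width 64,
adversarial weight 1. Weight initialization is Glorot-uniform; there
are no biases anywhere in the encoder, matching the propagation rules
above. One run seed controls weight initialization and all ε draws; the
adversarial module draws from an independent stream derived from the
same seed, so disabling it (`advWeight = 0`, which skips the module)
leaves the rest of the trajectory untouched. A NaN loss aborts with the
epoch named. Probabilities are clamped to `[1e-12, 1 − 1e-12]` inside
cross-entropies.

## Slice alignment

Consecutive sections are matched by entropic Gromov–Wasserstein
transport between their intra-slice Euclidean distance matrices, which
is invariant to rotation, translation and reflection of either slice —
exactly the nuisance transforms separating physically adjacent
sections. Marginals are uniform (no prior cell importance). The solver
linearizes the quartic objective at the current plan (cost
`const − 2 D_X P D_Y`) and projects with log-domain Sinkhorn–Knopp
scalings.

Numerical choices:

* **Annealing.** The entropic temperature is annealed geometrically
  (factor 4) from 5% down to 0.01% of the mean squared distance,
  warm-starting the potentials at each level. A single small ε from a
  cold start is prohibitively slow, and a single large ε returns a
  blurred plan whose cost is orders of magnitude above the sharp
  optimum.
* **Level termination.** Each level stops when the objective stalls
  (relative change `< 1e-8` twice in a row); plan-change criteria stall
  long before the objective stops improving.
* **Exact marginals.** After the final Sinkhorn projection a rounding
  step (scale rows and columns down, repair the deficit with a rank-one
  correction) makes both marginals exact to machine precision, so the
  `tol = 1e-8` marginal contract always holds.
* **Restarts.** The GW objective is non-convex and near-symmetric point
  clouds have spurious branches; `nRestarts = 2` reruns the annealed
  solve from a seeded perturbed initialization and keeps the
  lowest-cost plan.

The rigid transform is then estimated in closed form by weighted
Procrustes (SVD of the plan-weighted cross-covariance), reflections
excluded by default (`det R = +1`; tissue sections should not mirror),
translation from the weighted barycenters, optional isotropic scale off
by default — where the method narrative mentions scaling, the stated
minimization is over rotation and translation, and the formula wins.
Because a soft plan under cell dropout carries a small systematic
translation bias, `refineTransform()` then alternates
mutual-nearest-neighbour hard correspondences with Procrustes re-fits
(ICP-style) until the transform stabilizes. Stacking assigns
`z = (slice − 1) × layerSpacing` and a 3D kNN graph annotates every
edge as intra- or inter-layer.

A fused cost mixing expression distances into the matching is
deliberately not implemented: the alignment equations are purely
spatial, and the spatial-only solver already recovers planted
transforms to a fraction of a degree on the package's fixtures.

## Data processing conventions

* Standardization is per **gene** (column), population variance
  convention, because node features enter the GCN gene-wise; the
  alternative (per cell) would erase relative expression levels across
  genes. Zero-variance genes map to zero columns instead of raising, so
  noise-free synthetic data survive.
* All-zero cells and genes are dropped before standardization; an input
  that filters to nothing is a hard error.
* Noise-robustness experiments add i.i.d. Gaussian noise **after**
  standardization: a noise sd swept up to 7 is only meaningful on a
  unit-variance scale. A flag on `addGaussianNoise()` callers can apply
  it beforehand instead.
* The canonical ligand–receptor dedup key is: species, upper-cased
  trimmed symbols, complex subunits sorted within each side,
  ligand→receptor direction preserved. Direction is kept because
  signaling is directional even though the derived gene adjacency is
  symmetrized. Complexes expand subunit-by-subunit into the gene
  adjacency since the matrix is per-gene while pairs may be
  per-complex.
* Held-out scoring uses balanced seeded negative samples from the
  original graph's non-edges, disjoint from all positives; accuracy
  uses threshold 0.5 on reconstructed probabilities. Both the negative
  universe and the threshold are configurable, since neither is
  canonically fixed for this task.

## What the synthetic generators emulate

`simulateTissue()` produces what the model needs to be *able* to work:
spatially clustered cell communities (Gaussian blobs) whose membership
drives a low-rank expression signal (community mean profiles drawn
`N(0, signalStrength²)` per gene, plus `N(0, noiseSd²)` noise), with
the ground-truth graph defined as the kNN graph of the coordinates.
Blob centres are placed irregularly (golden-angle spacing, varying
radius): rotationally symmetric layouts make distance-matrix matching
genuinely ill-posed, and real tissue is not symmetric. The default
benchmark fixture is 200 cells, 50 genes, 4 communities, `nNeighbors`
6, noise sd 0.3 — small enough that the full test suite and acceptance
script run in minutes on one CPU.

`simulateMultislice()` emulates consecutive sections: cumulative
planted rotations (15° steps) and translations, coordinate jitter
(sd 0.01), and 5% random cell dropout per slice, with the planted
transforms and surviving counterpart map returned as ground truth.
`simulateLRDatabase()` draws unique random L-R pairs with optional
two-subunit complexes. `simulateSCTDB()` writes a **synthetic**
stand-in for the curated merged L-R reference tables — same published
unique-pair counts (5786 human, 4806 mouse), synthetic gene universe,
with duplicated rows, case variants and reordered complex subunits
injected so the merge + dedup pipeline is genuinely exercised when the
counts are recomputed.

What passing tests on these fixtures show: the implementation trains,
ranks and recovers planted structure under the stated noise, dropout
and masking regimes, and the alignment recovers planted rigid
transforms. What they do not show: performance on real platform data —
the generators produce Gaussian expression, not counts (no negative
binomial dispersion, no dropout curves, no batch effects), communities
are balanced and well separated, and slices differ only by rigid
transforms plus jitter, not by real inter-section biology.

## Known limitations

* Dense full-batch linear algebra bounds practical graph sizes to a
  few thousand cells; there is no minibatch or neighbour-sampling path.
* Entropic GW with restarts is a local method; heavily symmetric or
  near-degenerate geometries can still defeat it, and only pairwise
  (not barycentric multi-way) alignment is provided.
* Reconstructed probabilities are not calibrated beyond the balanced
  class weighting; the 0.5 accuracy threshold is a convention.
* Cross-species gene-symbol resolution and curation of new L-R
  evidence are out of scope for the database module.
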