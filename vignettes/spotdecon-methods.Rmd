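---
title: "Models and methods behind spotdecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spotdecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

spotdecon estimates the cell-type composition of capture spots in spatial
barcoding transcriptomics (ST) data — Visium-style arrays where every spot
averages the transcriptomes of a handful of cells — using a reference
scRNA-seq dataset from the same tissue type. This vignette is the package's
own account of the models it implements, the parameters that matter, and the
choices made where the design was genuinely open. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The two-step model

### Step 1: platform-effect removal with a conditional VAE

scRNA-seq and ST measure expression with systematically different
efficiencies ("platform effects"), which break the linear mixing assumption
that deconvolution relies on. spotdecon treats the two platforms as the two
values of the condition variable of a conditional variational autoencoder:

* encoder `q_phi(z | x, c)` and decoder `p_omega(x | z, c)` are
  single-hidden-layer feed-forward maps (tanh activations). The condition
  `c` is a single scalar input feature appended to both encoder and decoder
  inputs, `c = 0` for scRNA-seq-side data and `c = 10` for ST data. (Any
  other pair of distinct codes gives the same model after rescaling one
  input weight column, so only the contrast matters.)
* the latent width is `3K` for `K` cell types; the hidden width is the floor
  of the geometric mean of the gene-panel size and the latent width.
* the loss is the negative evidence lower bound with a standard-normal prior
  and a unit-variance Gaussian decoder, i.e. `KL(q || N(0, I))` plus mean
  squared reconstruction error. A Gaussian decoder is the simplest
  likelihood compatible with the min-max-scaled inputs; a negative binomial
  decoder would model counts more directly but needs raw-count inputs and a
  dispersion model, and is deliberately out of scope.
* optimization is minibatch Adam (initial learning rate 0.003). The rate is
  halved after 5 epochs without validation improvement and training stops
  after 10 without improvement, reverting to the best weights. These decay
  and patience constants are package defaults: the stopping signal
  (validation loss) is principled, the exact patience numbers are not
  critical and are exposed in `cvae_config()`.

Because the reference contains only pure cells while spots are mixtures, the
scRNA-seq condition is augmented with *pseudo-spots*: averages of
`cells_min`–`cells_max` randomly drawn reference cells (uniform cell count,
sampling without replacement within a pseudo-spot), `min(100 N K, 500000)`
of them by default, 80% for training and 20% for validation. The cell-count
range should match the cell density of the ST tissue; the package default
(5–20) matches roughly 10 cells per spot. Pseudo-spot compositions are
recorded as cell-count fractions, matching the ground-truth convention of
the simulator.

Every gene is min-max scaled to [0, 10] separately per condition before
training. Degenerate genes (constant within a condition) scale to 0 and
inverse-scale to their constant. After training, ST spots are encoded with
`c = 10` (posterior mean, for determinism) and decoded with `c = 0`,
clipped to the [0, 10] training range, inverse-scaled with the
*scRNA-seq-side* factors, multiplied by 10,000 and rounded — a non-negative
integer count matrix in the reference space. The reference itself is
encoded and decoded at `c = 0` (denoising) and stays continuous, since it is
only averaged into signatures afterwards.

### Step 2: penalized Poisson regression

For (transformed) spot counts `Y_ij`, spot depth `N_i` and cell-type
signatures `mu_kj` (mean library-normalized expression of marker gene `j` in
type `k`):

    Y_ij | lambda_ij ~ Poisson(N_i lambda_ij)
    log lambda_ij = alpha_i + log(sum_k theta_ik mu_kj) + eps_ij

with `theta_i` on the probability simplex and `alpha_i` a free per-spot
intercept. The error `eps_ij` has a heavy-tailed density: Gaussian with
scale `sigma` inside `|eps| <= 3 sigma` and a `1/|eps|` tail beyond,
approximating a Cauchy–Gaussian mixture so that a few badly modelled genes
cannot dominate the fit. Two numerical points:

* the tail is truncated at `8 sigma` because a `1/|eps|` tail is not
  normalizable on an unbounded range; the normalizing constant has a closed
  form over the truncated support and the tests verify the density
  integrates to 1 against `integrate()` to 1e-6.
* the printed form of the tail denominator is read with `|eps|`, which keeps
  it positive on the whole tail branch (it would change sign just above
  `3 sigma` otherwise).

The random effect is marginalized on a fixed quadrature grid (25 nodes over
`±5 sigma` plus 8 tail nodes to `8 sigma`); trapezoid weights under the
density are renormalized to sum to one, so the marginal likelihood is an
exact finite mixture and the `sigma -> 0` limit recovers the plain Poisson
likelihood. `sigma` is profiled on the fixed grid
{0.05, 0.1, 0.15, 0.25, 0.35, 0.5, 0.75, 1} at the maximum-likelihood stage
and held fixed afterwards.

Two penalties complete the objective

    F = sum_i [ l_i(theta_i, alpha_i) + lambda_r sum_k q_ik |theta_ik| ]
        + lambda_l tr(theta' L theta)

* **adaptive LASSO** — weights `q_ik` are reciprocals of the unpenalized
  per-spot maximum-likelihood estimates (floored at 1e-4 before inversion so
  absent types get a large finite weight), encoding that only a few of the
  K tissue types are present in any one spot.
* **graph Laplacian** — `L = D - A` over the unweighted spot adjacency
  (neighbours iff centre distance ≤ 1.2 × the minimal nonzero spacing,
  which captures square 4-neighbourhoods and hexagonal 6-neighbourhoods);
  `tr(theta' L theta)` is half the sum of squared composition differences
  across neighbouring spots.

### Optimization

The objective is minimized in two ADMM stages, both consensus splittings
between a smooth block and a per-row simplex projection:

1. **selection** — per spot, likelihood + adaptive LASSO; cell type `k` is
   called present iff the estimate is ≥ 0.001.
2. **smoothing** — jointly over spots, likelihood + Laplacian penalty with
   `theta` fixed to zero outside each spot's selected support.

On the feasible set the weighted L1 penalty is linear, so it lives in the
smooth block (solved by warm-started L-BFGS-B with a zero lower bound) and
the projection step needs no prox shift; exact zeros come from the simplex
projection. The penalty parameter starts at `rho = 1` with standard
residual-balancing (double/halve when one residual exceeds ten times the
other) and over-relaxation 1.6. Iterations stop when primal and dual
residuals fall below `sqrt(n) * 1e-5` plus a 1e-3 relative term — the usual
scaled criterion, so the tolerance does not tighten with problem size — or
at 200 iterations with a warning. ADMM is not a strict descent method: the
objective trace oscillates mildly near the optimum, so every iteration's
feasible point is scored and the best one seen is returned; the sequence of
accepted (best-so-far) objectives is non-increasing by construction and the
property tests additionally check that the returned iterate attains the
trace minimum and improves on the initial value.

`lambda_r` and `lambda_l` are chosen by gene-wise 5-fold cross-validation:
marker genes are split into seeded equal folds, the full two-stage fit is
re-run on each training fold for every candidate pair, and the base-model
log-likelihood of the held-out genes (at the fitted `theta`, `alpha`) is
averaged; the largest mean wins, ties going to the lexicographically
smallest pair (weaker regularization). Defaults are 7-point logarithmic
grids over [0.1, 100]; CV refits run a reduced ADMM budget (30 iterations,
1e-4 tolerance) because only the score ranking matters there.

### Gene panels

The CVAE trains on the union of the top highly variable genes (normalized
dispersion of log1p counts-per-10k, z-scored within 20 abundance bins — one
fixed, deterministic definition) and cell-type markers. Markers come from
all ordered pairs of cell types: per-gene two-sided Wilcoxon rank-sum tests
on library-normalized expression with Benjamini–Hochberg correction within
each comparison, kept when FDR < 0.05, fold change ≥ 1.2 (ratio of means
with a 1e-9 pseudo-count; the scale of the ratio is a package choice),
fraction of expressing cells ≥ 0.3 in the foreground and ≤ 0.1 in the
background type ("expressing" = raw count > 0), sorted by fold change, top
20 per comparison, unioned. The same criteria are applied twice: to the raw
reference for the CVAE panel and to the transformed reference for the
regression, with a fallback to the raw-reference markers if the transformed
pass returns fewer than `max(5, K)` genes. One adjustment is needed on the
transformed pass: reconstructed expression is continuous, so "expressing"
cannot mean "> 0" (almost everything unclipped is); a cell counts as
expressing when its transformed expression exceeds 1e-4 on the unit library
scale — one count per 10,000, the continuous analogue of a single UMI.

## Imputation at enhanced resolution

Estimated compositions are interpolated to a finer grid by a one-step
random walk. Edge spots are found by rasterizing spot occupancy onto its
lattice and flood-filling the background from the raster border: background
connected to the border is outside the tissue, the rest are holes, and
occupied sites 8-adjacent to either are edge spots. (This lattice flood
fill replaces an image-library contour call; it needs no raster resolution
choice beyond the spot spacing itself and is exactly testable.) The
bounding rectangle is gridded at side `d < D`; a new centre is kept iff it
is within `D` of an inner spot or within `(D - d)/2` of an edge spot. Each
kept centre starts from the average composition of its nearest original
spot(s) (ties within 1e-9 averaged), and one multiplication with the
row-stochastic matrix `M = D^-1 W` of the truncated Gaussian kernel
`W = exp(-r^2 / 2 tau^2) 1[r <= phi]` (isolated centres get self-weight 1)
yields the imputed compositions — still on the simplex, since `M` is
row-stochastic. Expression is imputed as
`X_imputed = theta_imputed theta^+ X` with `theta^+` the Moore–Penrose
inverse (normal-equations form, SVD fallback with a warning when
rank-deficient) and `X` depth-normalized observed expression over all
original spots. `phi` and `tau` are tuned by coarse-graining a
single-cell-resolution dataset at a ladder of spot sizes, imputing from the
coarsest map to each finer one, and minimizing the mean RMSE against the
finer maps' exact ground truth; search ranges default to 1–200 length
units.

## The simulation framework

Ground truth comes from coarse-graining single-cell-resolution spatial
data: the tissue is gridded into half-open squares anchored at
(min x, min y), each non-empty square becomes a spot whose composition is
the exact cell-count fraction per type and whose expression is
`ceil(mean(U_ij / sum_j U_ij) * 1000)` — the ceiling guarantees no observed
gene is zeroed. Cells on square boundaries belong to the lower-index
square; separately loaded experiments can be offset by ten tissue widths so
they never become spatial neighbours. Profile replacement
(`sequencing_replace`), density scaling (`densify`, preserving ground-truth
compositions exactly), rare-type down-sampling and reference-mismatch
editing reproduce the standard robustness scenarios.

### The synthetic fixture and what it does (not) show

`make_fixture()` generates the study conditions used throughout the tests
and the acceptance script: K = 5 cell types, 2,000 cells, 200 genes,
layered geometry (horizontal bands with 80% layer purity, emulating
cortical layers), log-normal base expression with 10 marker genes per type
over-expressed 8-fold, damped 2,000-fold in the non-adjacent types (markers
that satisfy the field's pct-based criteria are essentially silent
off-type) but expressed at baseline in the adjacent layer's type — real
markers are enriched, not exclusive, and without some sharing any per-gene
platform distortion would be absorbable by the regression's per-gene random
effect, leaving nothing for a platform correction to recover. Per-cell
depths are 800–1,500 with Poisson counts. Coarse-graining at a 70-unit
spot side gives roughly 200 spots with ~10 cells each, a Visium-like
density. These sizes are the package's chosen study scale; they keep a
full three-arm evaluation within minutes on one core.

The paired "external" reference redraws cells from the same type means
under a platform distortion. A purely per-gene multiplicative factor would
be absorbed by the model's own per-gene random effect — the regression arm
is provably robust to it, and measurement confirmed it — so the distortion
perturbs both a per-gene scale (log-normal, sd 0.5) and each gene's
response exponent (`log mu' = log f_j + gamma_j log mu`,
`gamma_j ~ N(1, 0.4)`, centred on each gene's geometric-mean level so
marker selection on the reference stays intact): gene- and
expression-level-dependent, the
"complicated" platform-effect structure that motivates learning a
correction instead of modelling a random effect.

What passing on this fixture shows: the estimator recovers compositions
when its assumptions hold, the platform correction recovers accuracy lost
to a nonlinear cross-platform distortion, and every pipeline contract
(simplex, sparsity, smoothing, determinism) holds end-to-end. What it does
not show: robustness to segmentation error, spatial gradients within a cell
type, dropout structure beyond Poisson sampling, or real-platform noise —
conclusions about real tissues still require real references.

## Numerical choices and degenerate inputs

* zero-total-count samples are dropped with a warning naming them; genes
  with zero counts across all spots are dropped before fitting; signatures
  are floored at 1e-8 so predicted rates stay positive on restricted
  supports.
* the simplex constraint is enforced by softmax reparameterization at the
  MLE stage and by Euclidean projection inside ADMM; ties in the dominant
  cell type are broken by the first type index and counted in a message.
* undefined per-spot Pearson correlations (constant vectors) are reported
  as missing and excluded from medians, with the count recorded.
* all stochastic steps (pseudo-spots, CVAE initialization and shuffling,
  CV folds, the generators) take a seed and restore the caller's RNG state.

## Known limitations

* the CVAE is a compact dense network trained by straightforward Adam; very
  large gene panels (thousands of genes) will train slowly compared to
  GPU-backed implementations, though the regression scales linearly in
  spots and genes with the compiled likelihood kernel.
* `sigma` is profiled once at the MLE stage and held fixed, so severe
  misspecification of the error scale propagates to both stages.
* CV refits use a reduced ADMM budget; with very flat score surfaces the
  tie-break (weakest regularization) decides.
* the imputation random walk is isotropic and single-step by design;
  anisotropic tissue structure is smoothed isotropically.
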