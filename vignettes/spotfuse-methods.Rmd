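---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `spotfuse`, its
assumptions, the tunable parameters, and every place where the design was
genuinely open and a choice had to be made. It states no empirical result
that the test suite does not itself compute.

## The model

The working hypothesis is that an ST spot's expression distribution is a
mixture of the distributions of the cells it contains: if a spot is
dominated by one population, its expression vector over the common genes
resembles a single cell of that population. `spotfuse` therefore scores
every (cell, spot) pair with three metrics capturing complementary aspects
of that resemblance.

**Gaussian mutual information.** For a bivariate Gaussian, the mutual
information has the closed form

$$MI(U, V) = \tfrac12 \ln \frac{\mathrm{var}(U)\,\mathrm{var}(V)}
{\det \Sigma} = -\tfrac12 \ln (1 - \rho^2),$$

where $\Sigma$ is the 2×2 sample covariance of the paired gene values and
$\rho$ the Pearson correlation. The discrete joint-pmf definition of MI is
*not* implemented: estimating a joint pmf from one gene-vector pair is
ill-posed, and the closed form is the operative definition here. Units are
nats (natural log); the choice of base only rescales MI, which is min-max
normalized before any fusion, so nothing downstream depends on it.
$\rho^2$ is clamped at $1 - 10^{-12}$, bounding MI at
$-\tfrac12\ln 10^{-12} \approx 13.8$ nats — duplicated rows (which occur in
real data) would otherwise diverge.

**R².** $1 - \sum_i (u_i - v_i)^2 / \sum_i (u_i - \bar U)^2$ treats the
spot vector as a direct prediction of the cell vector. It is deliberately
asymmetric and may be negative; both facts are covered by tests.

**Degenerate-input conventions.** A constant vector (all-zero cell or
spot after filtering is the common case) yields MI = 0, PCC = 0, and — when
the R² denominator vanishes — R² = 0, so degenerate observations read as
*neutral* similarity rather than propagating NaN. These conventions are
flagged via messages, not errors.

## Preprocessing

Genes expressed (strictly positive value) in fewer than 5% of cells or 1%
of spots are removed, and both matrices are restricted to the common
surviving genes in identical order. "Expressed" means `> 0` because no
count threshold is specified anywhere for this filter; a gene at exactly
the threshold prevalence survives (the removal condition is "fewer than").
Filters run on the raw values — counts or normalized data both pass
through unchanged, since all downstream metrics are either scale-aware or
explicitly normalized, and imposing a normalization here would silently
change user data.

## Pseudo-images

The raster construction is unspecified territory, so the conventions are
explicit and serialized with every run: x maps linearly to columns, y to
rows with the vertical axis flipped (image convention), indices rounded
half-up. The default raster is 64×64, but coordinate grids that are
equally spaced with few distinct values — e.g. pseudo-spot tile centers —
use their own grid dimensions, which makes the map injective and keeps the
LIME cost (which scales with pixel count) down. Channel values are min-max
scaled to [0, 1] with *global per-metric bounds across all cells*:
per-image scaling would erase the between-cell intensity differences the
classifier must learn. Colliding spots average their scaled values;
background pixels are exactly 0.

## Classifier

The reference configuration is a ResNet50-style trunk — 7×7 stride-2 stem,
3×3 stride-2 max pool, bottleneck groups of 3/4/6/3 units, global average
pooling, softmax head — trained with SGD (momentum 0.8), L2 weight decay
0.0125, learning rate 0.00005, 100 epochs. No CNN framework exists in this
R environment, so all layers (convolution via im2col, batch normalization,
ReLU, max pooling, dense, residual units, He initialization) are
implemented in the package; training is deterministic on CPU given the
seed, which the tests assert by comparing weights across runs.

Two deliberate deviations:

* **"Parallel ResNet50"** is ambiguous (ensemble? multi-branch?); a single
  ResNet50-style trunk is implemented. For the two-label task (stage ×
  type) the trunk is shared and each label gets its own softmax head;
  joint accuracy is exact-match over heads.
* **The small-cnn profile** (2 conv–batchnorm–ReLU–pool blocks, flatten,
  dense softmax) is the desk-scale default for tests. The reference
  learning rate 5e-5 is tied to the large architecture and cannot move a
  freshly initialized small network in 30 epochs, so the profile resolves
  an unspecified learning rate to 0.01. A flatten+dense head (not global
  pooling) is used because cell types differ mainly in *where* the bright
  correlation region sits, and a translation-invariant head would discard
  exactly that signal.

Batch size defaults to 32 and no augmentation is applied (neither is
specified). Images enter at native raster size.

## Attribution (LIME)

Perturbations toggle superpixels of the spot layout. Segmentation is grid
tiling of the spot-pixel bounding box with empty tiles dropped and the
smallest segments merged into grid-adjacent neighbors until exactly `K`
(default 40) contiguous, near-equal segments remain. "Off" segments are
replaced by the per-channel mean over spot pixels (a neutral value in the
image's own intensity range). Samples are weighted by
$\exp(-d_{\cos}^2/\sigma^2)$ with $d_{\cos}$ the cosine distance between
the mask and the all-ones mask and $\sigma = 0.25$; `n_samples` defaults
to 500 and each segment is kept with probability 0.5. The surrogate is a
depth-≤3 weighted regression tree — the complexity penalty $\Omega$ is
realized as the fixed depth cap, which keeps the fit deterministic — and
the attribution of a segment is the tree's impurity-decrease importance of
its mask bit, normalized to sum to 1, divided uniformly over the segment's
pixels (so total attribution mass is conserved). Tree importances are
unsigned; that is accepted here because downstream use (type averaging,
top-quantile spot selection, ICC) only needs magnitudes.

The class explained is the cell's *true* label when building type maps
(the predicted label is the natural alternative; on a well-fit model they
rarely differ, and the true label keeps $\bar A_t$ interpretable as "where
type-t evidence lives").

Cell-type maps $\bar A_t$ are plain elementwise means of the member maps.
High-attribution spots are those at or above the $1 - $ `top_frac`
quantile (default top 20%), ties included.

## Deconvolution

The three layers are min-max normalized to [0, 1] before averaging
(`fuse = "minmax"`, the default): MI is unbounded and nonnegative, PCC
lives in [−1, 1], and averaging them raw would let MI's scale dominate.
The raw mode (`fuse = "raw"`) is provided because the source formulation
averages without comment; the choice is recorded in the proportions
object's provenance. After per-type averaging, negative fused values are
clipped at 0 before simplex normalization so proportions are
interpretable as (inferred) mRNA fractions; all-zero spots fall back to
uniform with a warning; argmax ties break lexicographically.

## Benchmark metrics

* SSIM and the RMSE z-scores use **population (1/n) moments**; the
  normalization is not pinned down by the formulas, the choice is covered
  by a dedicated scaling test (z-vector vs its negation has RMSE exactly
  2), and it is recorded here.
* JSD uses **base-2 logs** so its range is exactly [0, 1].
* Performance levels use **mean ranks for ties**, keeping APS stable when
  methods coincide; with no ties each PL column sums to $Q(Q+1)/2$.

## Communication statistics

ICC averages the same Gaussian MI (clamped), cosine similarity and
Pearson correlation over flattened attribution maps. Flattening uses
spot-bearing pixels only by default: the constant zero background would
otherwise inflate cosine and Pearson terms. The diagonal is finite only
because of the MI clamp (≈ (13.8 + 2)/3); it is reported as-is. MI is
*not* rescaled before averaging — the formula says raw — so ICC values
between strongly colocalized maps can exceed 1; users comparing against
bounded expectations should note this, and the clamp constant is exposed.
The hypergeometric tail is computed with exact log-binomial arithmetic
(`C = 0` returns exactly 1), and "expressed" for a ligand/receptor means
value > 0.

## Synthetic data

The generator states a world and keeps it fixed: 4 cell types, 100 genes
with 8 disjoint signature genes per type, negative-binomial counts
(signature mean 20, background mean 1, dispersion 0.5 — single-cell
overdispersion rather than Poisson), a log-normal per-cell size factor
(sd 0.1), 1500 cells of which half are held out as the single-cell
reference (mimicking a separate reference assay), and a 14×14 square grid
over a 100×100 domain whose tiles sum their member cells' expression into
pseudo-spots with exact compositional ground truth. Cells sit in one
Gaussian blob per type (sd 18) with a 50% uniformly mixed fraction; those
two spatial knobs were calibrated once so the default fixture lands near
the target construction of ~189 occupied spots with 1–18 cells each
(192 occupied, occupancy 1–11 at seed 0), before any downstream criterion
was evaluated.

What the generator does *not* emulate: platform artifacts (spot bleed,
segmentation error), batch effects between reference and spatial
modalities, continuous gradients between types, or realistic gene–gene
correlation structure. A green recovery test therefore establishes that
the pipeline's machinery is correct on its stated world — not that it
matches any particular tissue.

## Pipeline

`run_end_to_end()` executes all stages from one config, writes every
output with an md5 content hash into a JSON manifest, and derives all
stage seeds from explicit config fields (a missing seed fails validation
before any stage runs). Reruns with an identical config are hash-stable,
which the end-to-end test asserts. **Resuming a partial run from the last
valid stage hash is not implemented** — runs always recompute; at desk
scale every stage is cheap, and the bookkeeping would add state without
scientific content. This is the one orchestration amenity deliberately
dropped.

## Known limitations

* The scalar metric functions and the vectorized tensor builder agree to
  ~1e-12 (floating-point summation order), not bit-for-bit.
* Tree importances are unsigned; a signed (ridge-linear) surrogate is a
  natural extension but is not implemented.
* The ResNet50-style trunk is smoke-tested (forward + one training step)
  but not trained in the test suite; pure-R training of the full trunk is
  out of desk-scale budget.
* Multiple-testing correction across enrichment genes is left to the
  caller (raw p-values at the 0.05 threshold are reported).
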