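# spotfuse

Integration of paired single-cell and spatial transcriptomics data by
spot–cell correlation fusion — with pseudo-image CNN cell-type
classification, LIME-style attribution maps, per-spot cell-type
deconvolution, a deconvolution benchmark suite, and colocalization /
enrichment statistics for cell–cell communication analysis.

## Who this is for

Spatial transcriptomics (ST) spots typically mix mRNA from 10–20 cells.
Given a labeled single-cell (or single-nucleus) reference with expression
vectors `U_j` and an ST slide with spot vectors `V_k` over common genes,
`spotfuse` scores every (cell, spot) pair with three complementary
similarity metrics:

* **MI** — Gaussian mutual information, `MI(U, V) = -½ ln(1 − ρ²)` nats
  (with `ρ²` clamped below 1 so collinear pairs stay finite),
* **R²** — coefficient of determination,
  `1 − Σ(u_i − v_i)² / Σ(u_i − Ū)²`, treating the spot as a direct
  prediction of the cell,
* **PCC** — sample Pearson correlation.

The resulting `3 × n₁ × n₂` tensor drives everything downstream:

1. **Pseudo-images** — each cell's three correlation row-vectors are
   rasterized at the spot positions and stacked as RGB channels
   (MI → red, R² → green, PCC → blue), one image per cell.
2. **Classification** — a CNN (ResNet50-style trunk, or a fast small-cnn
   profile; SGD with momentum 0.8 and L2 weight decay 0.0125) predicts
   each cell's type (optionally a second label, e.g. stage) from its
   pseudo-image.
3. **Attribution** — LIME superpixel perturbations with a depth-limited
   weighted regression-tree surrogate yield per-cell attribution grids
   `A_j`, averaged into cell-type attribution maps `Ā_t`.
4. **Deconvolution** — the min-max-normalized layers are averaged,
   cell rows are averaged per type (`ŵ_t`), and each spot's values are
   normalized to the simplex: `p_k^(t) = ŵ_k^(t) / Σ_j ŵ_k^(j)`.
5. **Benchmarking** — per-type PCC, SSIM (α = 0.01, β = 0.03), RMSE of
   z-scores, base-2 JSD, and the aggregative performance score
   (APS = mean rank across the four metrics among Q methods), plus the
   adjusted Rand index for spatial-domain agreement.
6. **Communication** — the integrated correlation coefficient
   `ICC = (MI + cosine + PCC) / 3` between flattened attribution maps, and
   an exact hypergeometric test for enrichment of ligand/receptor-expressed
   spots among the top-20% attribution spots.

A synthetic generator (`simulate_paired()`) emulates the
single-cell-resolution benchmark construction — cells gridded into square
pseudo-spots (default 14×14, ≈190 occupied, 1–18 cells each) with
expression summed per tile — so the whole workflow runs offline with known
ground truth.

## Worked example

```r
library(spotfuse)

sim    <- simulate_paired(synthetic_config(seed = 0))   # q = 4 types
paired <- filter_and_align(sim$sc, sim$st)              # <5% cells / <1% spots gene filter
tensor <- build_tensor(paired$sc, paired$st)
#> CorrelationTensor: 3 metrics (MI, R2, PCC) x 750 cells x 192 spots

props <- deconvolve(tensor, setNames(paired$sc$labels$cell_type,
                                     paired$sc$cell_ids))
round(head(props$values, 3), 3)
#>       type1 type2 type3 type4
#> spot0 0.291 0.270 0.194 0.245
#> spot1 0.210 0.291 0.297 0.202
#> spot2 0.287 0.206 0.211 0.296

evaluate_deconvolution(props, sim$truth$values)
#>    type   PCC  SSIM  RMSE   JSD
#> 1 type1 0.957 0.492 0.293 0.243
#> 2 type2 0.962 0.518 0.277 0.238
#> 3 type3 0.969 0.543 0.249 0.235
#> 4 type4 0.966 0.568 0.261 0.178
```

Each proportion row lies on the simplex; per-type PCC ≈ 0.96 means the
estimated spatial composition tracks the planted ground truth closely.
Comparing the predominant type per spot with the ground-truth predominant
type gives `ari(...) = 0.583` on this fixture.

The full workflow — training the classifier, building attribution maps,
ICC and the manifest — runs from one config:

```r
m <- run_end_to_end(run_config("out", sim = synthetic_config(seed = 0), seed = 0))
m$summary$accuracy       # 1.0 on the separable synthetic fixture
m$summary$per_type_pcc   # all >= 0.7
```

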