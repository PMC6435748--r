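# myelinquant

High-throughput quantification of oligodendrocyte ensheathment on aligned
nanofiber cultures, from multi-channel fluorescence well images.

Oligodendrocytes cultured on electrospun 2 µm nanofibers wrap fiber
segments in O4/MBP-positive membrane ("sheaths"), a reduced in-vitro model
of myelination. The biological readouts are per-cell: the number of
sheaths a cell forms, their lengths (log-normal, analysed as log10 µm),
the mean sheath length per cell (mSLC), and the count of ensheathing
cells per well. Quantifying these by hand is slow (hours per well) and
rater-dependent; `myelinquant` automates it for anyone running nanofiber
myelination assays — screening labs, glial-biology groups — and ships a
synthetic-phantom oracle so every algorithmic stage is testable without
imaging data.

## What is inside

Two segmentation engines over a common tabular output (a tibble of
per-sheath records):

* **Heuristic two-stream engine** — `run_heuristic()`. After CLAHE
  contrast enhancement, stream 1 extracts elongated sheath segments with
  a Hessian ridge filter: with eigenvalues of the scale-normalized
  Hessian ordered |λ₁| ≤ |λ₂|, a pixel scores
  `|λ₂|·(1 − |λ₁|/|λ₂|)` where λ₂ < 0, and the top `sensitivity`
  quantile is kept. Stream 2 estimates cell bodies by watershed of the
  distance transform with suppressed shallow maxima, keeping only bodies
  that colocalize with a Hoechst nucleus. Bodies are subtracted from the
  ridge mask and the remaining segments are associated to the nearest
  body within a continuity gap (2 µm), one cell per segment.
* **Masked-nucleus UNet** — `build_unet()`, `unet_train()`,
  `infer_well()`. A compact encoder-decoder (5×5 kernels, stride 2,
  filters 10→50 down and 50→10 up with skip concatenations; 338,572
  parameters; implemented in RcppArmadillo with full backpropagation)
  takes a 3-channel crop whose middle channel is the binary mask of one
  nucleus of interest, and learns to segment only that cell's sheaths.
  Training minimizes per-pixel categorical cross-entropy with class
  weighting (×10 on sheath pixels) and spatial edge weighting
  `w = exp(1 − D/f + b)`, `D` the Chebyshev distance to the nearest
  ground-truth pixel.

Shared machinery: post-processing (`resolve_overlaps()` unfair
distribution, `remove_sticky()` skeleton-based bridge removal,
`filter_by_length()` two-pass 12 µm / 3×-strict filter), morphometrics
and evaluation (`summarize_well()`, `per_cell_ji()`, `global_ji()`,
`compare_groups()`), the power calculator
(`min_detectable_difference()`, which scales the minimum detectable
log-length difference as `δ_ref·√(n_ref/n)`), and the seeded phantom
generator (`generate_phantom()`) that renders fibers, somata, nuclei and
log-normal-length sheath bars with exact per-cell ground truth.

## Worked example

Generate a synthetic well and quantify it with the heuristic engine:

```r
library(myelinquant)

ph  <- generate_phantom(phantom_spec(n_cells = 20, seed = 11))
ph$image
#> <well_image 'phantom-seed11'> 1024 x 1024 px @ 0.5 um/px; channels: nuclei, membrane, brightfield

rec <- run_heuristic(ph$image)
rec
#> <sheath_records> 54 sheaths / 15 cells on 1024 x 1024 px raster
#> # A tibble: 54 x 5
#>    cell_id px            sheath_id length_um area_px
#>  *   <int> <list>            <int>     <dbl>   <int>
#>  1       1 <int [370]>           1      30.7     370
#>  2       1 <int [442]>           3      36.8     442
#>  3       1 <int [1,430]>         4     119.     1430
#>  ...

glance(rec)   # well-level morphometrics
#>   n_candidates n_ensheathing_cells sheaths_per_cell_mean sheaths_per_cell_sem
#> 1           20                  15                   3.6                0.412
#>   mslc_mean mslc_sem log10_length_mean log10_length_sem n_sheaths
#> 1      54.4     3.38              1.68           0.0346        54
```

Twenty cells were placed, 15 of them ensheathing; all 15 are recovered,
forming on average 3.6 sheaths of mSLC 54 µm. The pooled mean log10
length (1.68) sits close to the generating distribution's truncated mean
(1.71); the small deficit and the sheath undercount are the documented
subtraction/threshold biases of the two-stream design (see the methods
vignette), which cancel in group comparisons. `tidy(rec)` gives the
per-cell morphology table, `autoplot(rec)` a per-cell overlay, and

```r
min_detectable_difference(300)
#> 0.06582806
```

reproduces the power argument for large samples: 300 sheaths resolve only
~0.07 log-length units, versus 0.01 at the 13,000-sheath reference scale.

To train the UNet at demonstration scale and compare weighted against
unweighted losses (this is the long-running part, ~10 min on one CPU):

```r
cmp <- unet_learning_comparison(seeds = 1:3)
```

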