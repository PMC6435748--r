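---
title: "Quantifying oligodendrocyte ensheathment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying oligodendrocyte ensheathment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Oligodendrocytes cultured on aligned electrospun nanofibers (2 µm
poly-L-lactic-acid fibers, axon mimics) wrap fiber segments in
MBP/O4-positive membrane. The quantities of biological interest are
per-cell: how many sheaths a cell forms, how long they are (the sheath
length distribution is log-normal, so lengths are analysed as log10 µm),
the mean sheath length per cell (mSLC), and the number of ensheathing
cells per well. The unit of analysis is a multi-channel whole-well raster
(Hoechst nuclei, O4/MBP membrane, optional brightfield) at 0.5 µm/px.

Manual classification follows four criteria: (1) an identifiable cell
body and nucleus; (2) ensheathing processes parallel to the fibers with
length > 12 µm and thickness > 2 µm; (3) continuity of the cell body with
its ensheathments; (4) each ensheathed fiber segment belongs to exactly
one nucleus. Everything in this package is an operationalization of those
four rules.

`myelinquant` provides two segmentation engines plus shared
post-processing and morphometrics:

* a **heuristic two-stream engine** (`run_heuristic()`): CLAHE contrast
  enhancement, a Hessian ridge filter for the elongated sheath segments,
  watershed cell-body estimation on the distance transform, subtraction
  of bodies from the ridge mask, and continuity-based association of the
  remaining segments with nuclei;
* a **masked-nucleus UNet** (`build_unet()`, `unet_train()`,
  `infer_well()`): a compact encoder-decoder trained on 3-channel crops
  whose middle channel is the binary mask of one nucleus of interest,
  prompting the network to segment only that cell's sheaths and thereby
  solving criteria 3-4 *inside* the model rather than by geometric
  approximation.

Because the original culture images are not distributable, the package
ships a seeded phantom generator (`generate_phantom()`) that renders the
culture geometry with exact per-cell ground truth; every stage of the
pipeline is validated against it.

## The phantom: what it emulates and what it does not

`phantom_spec()` encodes the study conditions: 0.5 µm pixels, parallel
vertical fibers every 8 µm, sheath bars 2 µm thick centered on fibers,
sheath lengths log-normal on the log10 µm scale truncated below at the
12 µm manual floor, and ensheathing cells drawing
`1 + Poisson(mean - 1)` sheaths (mean 5 by default, the per-cell count
reported for the reference wells). Each sheath's near end lies inside its
cell's soma disc, so continuity with the cell body is true by
construction. Non-ensheathing cells are rendered unstained (nucleus
only), which is exactly the population the candidate filter is meant to
exclude.

Two defaults deserve justification:

* `log10_length_sd = 0.29`. The dispersion of log sheath lengths is never
  printed directly, but the published power analysis states that 13,000
  sheaths detect a difference of 0.01 log units at 80% power.
  Inverting the two-sample minimum-detectable-difference relation
  `delta = (z[0.975] + z[0.8]) * sigma * sqrt(2/n)` gives
  `sigma = 0.288` (`derive_log_length_sd(0.01, 13000)`), which we round
  to 0.29.
* `log10_length_mean = 1.7` (~50 µm). No mean is printed; 50 µm is a
  typical nanofiber sheath length and, importantly, keeps the 12 µm
  truncation in the far tail (z = -2.1), so the rendered distribution is
  only mildly truncated. `phantom_log_length_moments()` returns the exact
  truncated-normal moments; parameter-recovery checks compare against
  those, not the untruncated parameters, because the truncation shifts
  the mean by ~+0.02 log units — larger than the standard error at the
  sample sizes used.

The soma disc (default radius 20 µm) stands for the soma *plus* the
proximal arbor that reaches the fibers a cell ensheathes; sheath counts
are capped by the number of reachable fiber slots (two directions per
fiber under the disc), which depresses the realized mean count by ~1.5%
relative to the nominal Poisson mean — well inside the tolerances used in
the tests. Placement is rejection-sampled so that with `crowding = 0`
all structures are disjoint; with `crowding > 0` the generator
deliberately constructs sheath-tip overlaps between designated pairs and
records each overlap with its rightful owner (the claimant with larger
total sheath area), giving the unfair-distribution operator a known
answer key. Sheath lengths are drawn once per placement round, not per
collision retry — re-drawing on every collision would select against long
sheaths and visibly narrow the length distribution (we measured a ~10%
sd shrinkage before fixing this).

The phantom is a geometric oracle, not a photorealistic one: noise is
additive Gaussian on a flat background, intensity is uniform along a
sheath, there are no staining gradients, no out-of-focus light, no
curved fibers, and no debris. Passing phantom tests therefore
demonstrates that the algorithms implement their stated geometry
correctly at realistic SNR; it does not certify performance on real
micrographs, which vary in ways the phantom does not model.

## The heuristic engine

All intensity processing happens on the CLAHE-enhanced membrane channel
(`clahe_enhance()`; tiles 64 px, clip 0.01 — standard values, the source
method states none).

**Ridge filter.** The Hessian at Gaussian scale `sigma` is computed by
convolution with second-derivative Gaussian kernels
(gamma-normalized). With eigenvalues ordered `|l1| <= |l2|`, a bright
ridge requires `l2 < 0`, and the ridge-likeness score is
`|l2| * (1 - |l1|/|l2|)` — large for elongated structures, zero for
isotropic blobs. This particular combination is this package's choice
(only "eigenvalues of the Hessian" is prescribed by the method it
implements); it is isolated in `ridge_score()` and swappable. The
user-facing `sensitivity` maps to the `1 - sensitivity` quantile of the
score map rather than an absolute threshold, making it robust to
intensity scale; `ridge_sigma_px` defaults to the 2 µm sheath thickness
in pixels (4 px), and sensitivity defaults to 0.05 (about the sheath
pixel fraction of a moderately dense well).

**Cell bodies.** The membrane image is Otsu-binarized and opened with a
disc of the sheath thickness (`body_open_radius_um = 2`), which removes
sheath-width structures and leaves soma-scale blobs; this opening is our
interpretation of "cell bodies" as soma-scale objects — without it the
watershed regions would include the sheaths themselves and the
subtraction step would erase everything. The distance transform is then
watershed-split with shallow maxima suppressed (`hmax_depth = 2` px),
separating touching somata, and only regions colocalizing with a detected
nucleus survive; regions holding several nuclei are split between them by
geodesic propagation, so there is exactly one body per nucleus.

**Association.** Segments (8-connected components of ridge minus bodies)
are assigned to the nearest body within `association_gap_um = 2` µm (one
sheath thickness; the continuity criterion states no tolerance, so we
chose the smallest physically meaningful one). Nearest wins; beyond the
gap the segment is dropped; no segment is ever given to two cells.

Known, accepted biases (quantified on phantoms): sheath pixels under the
cell body are removed by the subtraction step and short sheaths that dip
below 12 µm after subtraction are filtered, which shortens pooled
log-lengths by ~0.04 log units and lowers sheath counts by ~0.2/cell.
These are properties of the two-stream design itself — the very
limitation that motivates the single-cell network — and they cancel in
between-group comparisons, which is what the group-recovery check
demonstrates.

## The masked-nucleus UNet

Inputs are `crop_size_px` x `crop_size_px` x 3 arrays: membrane, the
binary mask of the nucleus of interest, and the full nuclear channel
(other nuclei stay visible in channel 3; only channel 2 is masked).
Candidates come from watershed nucleus detection followed by the
membrane-blob filter (binarize, close, open; keep nuclei whose centroid
falls in a blob) that discards clearly unstained cells. The default crop
of 256 px (128 µm) comfortably contains one cell's arbor; training-scale
experiments use 128 px crops. Borders are zero-padded so padding can
never spawn signal.

The architecture is deliberately small: five stride-2 5x5 convolutions
with 10/20/30/40/50 filters down, five fractional-stride (transposed)
5x5 convolutions with 50/40/30/20/10 filters up, a skip concatenation at
every matching resolution, and a final 1x1 softmax giving two mutually
exclusive classes. That is 338,572 trainable parameters (the test suite
checks this against a layer-wise closed form), small enough to train and
run on a CPU. The backend is implemented in RcppArmadillo as
im2col/col2im + GEMM with full backpropagation; analytic gradients are
verified against central finite differences to ~1e-7 relative error.
"One training step" means one minibatch update throughout.

The loss is per-pixel categorical cross-entropy with two weightings:

* **class weighting** — sheath-pixel loss multiplied by 10, balancing the
  rare foreground class (~4% of pixels in phantom crops);
* **spatial weighting** — `w = exp(1 - D/f + b)` with `D` the Chebyshev
  distance to the nearest truth pixel (computed by an exact two-pass
  chamfer transform), concentrating the loss near object margins. The
  printed formula places `b` in the exponent, which is the default
  (`spatial_mode = "exponent"`); because the stated purpose of `b` is to
  keep weights from reaching zero, an additive floor
  `exp(1 - D/f) + b` is also provided (`spatial_mode =
  "additive_floor"`). `f = 6` px and `b = 0` are package defaults; no
  values are prescribed anywhere, so both are explicit configuration.

Training uses Adam (default lr 1e-4, batch 4 — conventional values, none
are prescribed), records validation loss and mean per-example JI at
threshold 0.5 every `val_every` steps, optionally rotates each drawn
example by a uniform random angle (`rotate_augment = "random_angle"`),
aborts on NaN loss, and returns the best-validation-JI checkpoint.
Determinism: all randomness (init, batch order, angles) flows from R's
seeded RNG; compiled code is single-threaded apart from BLAS GEMM.

**Scaled-down learning demonstration.** Full-scale training (hundreds of
thousands of steps on GPU) is out of reach by design; the package instead
demonstrates the *learning dynamics* at small scale:
`unet_learning_comparison()` trains on 240 phantom masked-nucleus crops
(128 px, 15 cells per phantom, all ensheathing) against 60 validation
crops, 120 steps at lr 1e-3, batch 4, checkpointing every 20 steps,
paired weighted/unweighted runs over 3 seeds. These sizes were chosen as
the smallest at which the qualitative result is stable across seeds:
the weighted configuration typically crosses validation JI 0.3 by step
40 while the unweighted one needs 80-100 (it spends its first ~60 steps
predicting all-background), and the weighted run ends near JI 0.8. The
comparison reproduces the *trend* — weighting produces an earlier,
steeper JI rise — not any figure-level value; at this scale the
unweighted run eventually overtakes on final JI because the phantom task
is easy and class weighting trades calibration for early recall.

## Post-processing

Applied in fixed order by `postprocess_records()`:

1. **Unfair distribution** (`resolve_overlaps()`): a connected component
   claimed by several cells goes wholly to the claimant with the larger
   total sheath area ("larger cell" is measured in sheath pixels, not
   soma size, matching the rationale that a multi-ensheathing cell is the
   likelier owner); exact ties go to the lower cell id, making the
   operation order-invariant.
2. **Sticky removal** (`remove_sticky()`, per cell): Zhang-Suen
   skeletonization; junction pixels found by the Rutovitz crossing
   number (a plain neighbour count misfires on the staircase skeletons
   of oblique bars) together with their skeletal 8-neighbourhood
   (removing only the junction pixel leaves its arms diagonally
   connected); branches whose extent across the fiber axis exceeds their
   extent along it (45 degree dividing line — no angle is prescribed) are
   deleted; junction clusters touching two or more retained branches are
   re-inserted, restoring along-fiber connectivity; finally every mask
   pixel maps to its nearest skeleton pixel (Euclidean, ties keep) and
   pixels nearer a deleted branch are dropped.
3. **Two-pass length filter** (`filter_by_length()`): drop sheaths below
   12 µm; then re-count, and cells left with one or two sheaths must
   clear `strict_multiplier x 12` µm (default multiplier 3, the lenient
   end of the prescribed 3-4 range). The pass ordering — filter, re-count,
   strict rule — is this package's resolution of an ambiguous order, and
   is pinned by a worked example in the tests (sheaths of 10/15/40 µm
   leave only the 40 µm sheath at multiplier 3). The filter is idempotent.

**Length convention.** `measure_length()` returns
`sqrt(12) * sigma_major * pixel_size`, the major axis of the
second-moment-equivalent *rectangle* (with a 1/12 px² variance term so a
single pixel has unit extent). For a straight bar this equals the
end-to-end length exactly, which is what the phantom's truth lengths and
the recovery tests require; the classical regionprops *ellipse*
convention (`4 * sigma`) is available via `convention = "ellipse"` and is
a constant factor `2/sqrt(3)` larger. The choice matters only as a
consistent convention on both sides of any comparison.

## Evaluation and power

`jaccard()` is plain intersection-over-union with both-empty defined as
1 (perfect agreement on absence). `per_cell_ji()` pairs cells by nucleus
centroid, greedily, closest first, one-to-one, within 10 µm (the
pairing rule is unspecified in the source method; spatial matching is
the only option that works across independent segmenters), and
`global_ji()` compares the unions. `summarize_well()` aggregates sheaths
per cell and mSLC with SEMs over cells and pooled log10 lengths with SEM
over sheaths; `compare_groups()` reports difference of group means with
`sqrt(sem_a^2 + sem_b^2)` and delegates p-values to `wilcox.test` /
`t.test` (standard tests are consumed, never reimplemented).

`min_detectable_difference(n, n_ref, delta_ref)` implements the
`1/sqrt(n)` scaling of the two-sample minimum detectable difference at
fixed power: with the 13,000-sheath reference design resolving 0.01 log
units, 300 sheaths resolve only `0.01 * sqrt(13000/300) = 0.0658` — the
reason the high-throughput pipeline can see effects manual counting
cannot.

## Numerical choices and degenerate inputs

* Coordinates are 0-based `(y, x)` with origin top-left in all exported
  values; matrices are indexed `[row, col]` internally.
* Polygon rasterization: even-odd rule at pixel centers
  (`(col - 0.5, row - 0.5)` in 0-based coordinates); centers exactly on
  an edge are included.
* Label masks are 16-bit; more than 65,535 objects per well is an error
  (real wells carry ~2,000 candidates).
* Empty inputs: empty ROI sets, empty masks, candidate lists and record
  tables all propagate as empty results, not errors; an empty truth mask
  gives a valid (uniformly tiny) spatial weight map.
* Nucleus-sheath pairing in ROI files uses a `cell<K>-` name prefix
  (`cell3-nucleus`, `cell3-ens1`); the original files' convention is
  unknown, so ours is documented and enforced by the reader.
* The Chebyshev transform is an exact two-pass chamfer; the skeleton
  test suite pins H-, X- and bar-shaped oracles.
* Ties: unfair distribution → lower cell id; nearest-skeleton
  reconstruction → pixel kept if equidistant; association → nearest body.

## Problem sizes used by the validation battery

Heuristic recovery runs 10 phantoms of 1024 px / 20 cells at low noise;
group recovery uses 4 wells per condition with a +1 sheaths-per-cell
injection; moment checks pool ~500 cells across 34 phantoms; the UNet
demonstration uses the 240/60-example configuration above. These sizes
are the package's validation design: large enough that the 3-standard
-error recovery bands and median-over-seeds comparisons are stable, small
enough to run routinely.

## Known limitations

* The heuristic engine's subtraction bias (above) means absolute lengths
  are slightly conservative; use the UNet path or group contrasts when
  absolute calibration matters.
* The phantom does not model crossing or curved fibers; the sticky
  removal and association rules assume a dominant fiber axis.
* Transfer of a phantom-trained UNet to real micrographs is untested
  here and would require real training data; the package validates the
  training machinery, not a shippable model.
* Rotation augmentation slows early learning markedly (as expected when
  the orientation prior is removed); it is off by default.
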