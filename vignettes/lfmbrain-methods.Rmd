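---
title: "Methods: whole-brain light field imaging analysis with lfmbrain"
author: "lfmbrain authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-brain light field imaging analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfmbrain)
```

# Scope and model

`lfmbrain` implements an analysis pipeline for fast, near-whole-brain
fluorescence imaging of behaving adult *Drosophila* with light field
microscopy: volumetric reconstruction of raw sensor frames, preprocessing of
the 4D movie, blind source separation of spatially distinct activity
sources, anatomical annotation against a region atlas, and voxelwise
condition/stimulus statistics. Every stage can be exercised against seeded
synthetic ground truth, so the package is verifiable end to end without any
recordings.

The signal model underlying both the generator and the analysis is

$$ F(v, t) \;=\; b(t)\,\Big[ B(v) + \sum_s M_s(v)\, a_s(t) \Big] \;+\;
\varepsilon(v, t), $$

where $B$ is a static anatomical baseline, $M_s \ge 0$ are compact source
weight fields, $a_s$ are source fluorescence time courses (a driver signal
convolved with the indicator impulse response), $b(t) \in (0,1]$ is a
non-increasing photobleaching factor, and $\varepsilon$ is Gaussian read
noise with optional scaled-Poisson shot noise. Rigid motion enters as a
per-frame translation of the whole volume.

# The synthetic-data generator

`makeAtlas()` partitions an ellipsoidal brain mask into connected regions by
Voronoi tessellation around k-means centers; landmarks sit at region
centroids plus the mask poles, so at least four non-coplanar named points
always exist for affine registration. `makeGroundTruth()` places one
Gaussian blob per source strictly inside its region (support truncated at 5%
of the peak), and builds traces by convolving a driver with the indicator
kernel:

* independent Poisson event trains (default rate 0.3 Hz; every event-driven
  source fires at least twice per recording — a source with no events is
  indistinguishable from background, and a deliberately silent source is
  available via coupling `"silent"`);
* behavior-state indicators (walk/groom), one-sided ball optic flow
  (left/right), or stimulus onset trains;
* a delayed copy of another source's trace, used to probe cross-correlation
  lag recovery.

Defaults that stand in for the study conditions: fractional photobleaching
loss of 13% over 30 s for GCaMP6 (20% for ArcLight), implemented as an
exponential decay; indicator rise-to-peak of 0.15 s (GCaMP6f), 0.10 s
(ArcLight) and 0.55 s (GCaMP6s); peak source amplitude 30 a.u. over a
baseline of 100 a.u. (peak $\Delta F/F \approx 0.3$); Gaussian read noise SD
2 a.u.; behavior bouts from a semi-Markov process with mean durations 5 s
(walk), 8 s (rest) and 3 s (groom). Indicator decay constants are free
parameters (0.6 s GCaMP6f, 0.3 s ArcLight, 1.8 s GCaMP6s): recovery tests
are parameter-recovery tests and are insensitive to the exact value. Raw
per-voxel SNR figures are not available for this kind of recording, so the
noise defaults were chosen once for testability, not fidelity.

The rendered baseline is deliberately *structured* (`makeBaseline()`:
per-region intensity variation plus smooth texture). Real recordings carry
anatomical contrast in the baseline, and that contrast is what rigid
registration locks onto; a flat synthetic baseline would make motion
correction an ill-posed problem the real data never poses.

What the generator does **not** emulate: optical scattering, nonrigid tissue
deformation, aliasing stripes from reconstruction, correlated (shared)
noise across voxels, and sources with overlapping support. Passing tests
therefore demonstrate algorithmic correctness on well-posed phantoms, not
performance on real recordings.

# Light field forward model and deconvolution

The wave-optics light field PSF is out of scope; the package uses a
geometric-optics stand-in that preserves the structure of the inverse
problem. Each reconstruction depth $d$ blurs with a normalized lateral
Gaussian of width $\sigma(d) = \sigma_0 (1 + w\,|d|)$ (defaults
$\sigma_0 = 1.49\,\mu m$, $w = 0.02/\mu m$, reproducing a lateral FWHM
growing from about 3.5 to 12 µm across the default 40-layer, 6-µm stack) and
projects to the sensor as a subaperture pair: the blurred layer is rolled by
$\pm$ a depth-proportional parallax offset (nearest pixel, spanning half the
lenslet pitch across the stack) with unequal view weights 0.6/0.4. The
offset *separation* encodes $|d|$ and the weight asymmetry its sign; with
equal weights, depths $\pm d$ would be exactly indistinguishable for a point
source. All convolutions and rolls are circular, which makes the adjoint
exact — the property Richardson–Lucy deconvolution actually requires.

`deconvolve()` is textbook RL: multiplicative updates with the forward
operator and its adjoint, predicted intensities floored at $10^{-12}$ so no
division by zero can occur, every iterate nonnegative. The iteration count
is a free parameter (default 30); no stopping rule is claimed. Lateral
sampling can be coarsened from 3 to 6 µm by integer binning of the sensor
frames. `measurePsfFwhm()` reproduces the bead-based resolution measurement:
1D profiles through each bead center, half-maximum crossings located by
linear interpolation, lateral FWHM the mean of x and y, axial from z;
profiles that never fall below half maximum are flagged rather than
truncated.

# Preprocessing

* **Motion correction** (`motionCorrect()`): rigid translation per frame by
  FFT cross-correlation against the first frame (or temporal mean), integer
  search within ±5 voxels, then per-axis quadratic (three-point) subvoxel
  refinement. Rotation is not estimated by default; translation suffices on
  the synthetic tests and matches the rigid contract.
* **Detrending** (`detrend()`): subtraction of a centered running box
  average (15–30 s) removes background and the bleaching decay. Whether the
  original procedure used a centered or causal box is not documentable;
  centered is chosen and stated. Edges use shrinking windows — no data are
  fabricated beyond the recording. Even window lengths use the standard
  centered even-order moving average (half weights on the two end frames),
  so a 100 ms window at 200 Hz is exactly 20 frames *and* a linear ramp is
  removed exactly at interior frames.
* **Sign flip** (`invertSign()`): ArcLight reports depolarization as
  dimming, so voltage movies are negated; guarded against accidental use on
  calcium data.
* **Denoising** (`kalmanDenoise()`): the steady-state scalar form
  $\hat x_t = (1-g)\hat x_{t-1} + g\,y_t$ with $\hat x_1 = y_1$ and default
  gain 0.5. Only the gain is specified by the source procedure; the
  recursion above is this package's stated contract.
* **SVD movement subtraction** (`svdMotionRemoval()`): removes selected
  rank-1 terms; the auto mode flags components whose map energy concentrates
  (fraction > 0.5) on top-quartile-gradient voxels of the mean volume —
  movement maps look like shadows hugging intensity edges. The auto rule is
  a package heuristic; the qualitative selection it replaces cannot be
  formalized further.
* **Behavior alignment** (`alignBehavior()`): the behavior clock is
  stretched linearly by the measured drift (default 30 ms per minute) and
  the behavior is resampled onto the fluorescence grid — nearest neighbor
  for the categorical state, linear for optic flow, with one-sided turns
  preserved across interpolation boundaries.
* **z-slab reduction** (`zslabReduce()`): contiguous z-slabs whose thickness
  tracks the axial PSF height at each depth (greedy, outward from the depth
  of minimal PSF height), each slab replaced by its mean.

# Source extraction

The chain is: variance normalization → SVD → shoulder detection → component
count → spatial ICA → sign convention.

1. `varianceNormalize()` removes the top-k SVD terms (default 2), measures
   the per-voxel temporal variance of the residual without spatial
   filtering, and divides the movie by its square root (floored at
   $10^{-8}$ of the maximum). This equalizes the noise floor so PCA is not
   dominated by bright voxels.
2. `pcaVolumes()` is a thin SVD of the voxels × time matrix, computed by
   exact LAPACK SVD for small movies and via the smaller Gram matrix for
   large ones.
3. `detectShoulder()` finds the bend of the singular spectrum at the point
   with a 45° tangent. Axis scaling is otherwise ill-defined, so the
   package's convention — stated prominently because it changes the answer —
   is to normalize both axes to $[0,1]$ (index and $\log\sigma$) and return
   the first index where the centered finite-difference slope crosses −1.
   Whether the original procedure used raw or normalized indices is
   unknowable; this convention is frozen and oracle-tested.
4. `chooseNComponents()` doubles the shoulder index (clamped to the rank):
   components just past the shoulder still carry activity, twice the
   shoulder keeps them while discarding noise.
5. `runIca()` applies fixed-point ICA (logcosh contrast, symmetric
   decorrelation, tolerance $10^{-4}$, at most 500 iterations, mandatory
   seed) to the top-n *spatial* SVD modes — spatial ICA, because
   independence is sought between maps. The spatial modes are mean-free by
   construction, so no extra centering is applied; whitening is then exact
   and the unmixed maps span the same subspace, which makes
   maps × (scale × traces) reconstruct the rank-n truncation of the
   variance-normalized movie to machine precision. Component traces are the
   least-squares projection of that truncation onto the unmixed maps
   (closed form $V^{-1/2} W D_n V_n^\top$), variance-normalized with the
   scale retained. Non-convergence raises a warning and is recorded in the
   component metadata, never silent.
6. `fixSigns()` flips each (map, trace) pair so the mean of the positive
   side of the map dominates the absolute mean of the negative side.

ROI masks (`zscoreThresholdMask()`) zero all voxels below $k$ (default 3)
standard deviations; the SD is computed **about zero**, not about the map
mean, because ICA maps are mean-free by construction (configurable). Only
the positive side of a map defines the ROI — the meaning of negative map
regions is an open question, so masks do not use them. ROI time series are
weight-normalized averages of the ΔF/F movie.

# Atlas annotation and artifact rules

`landmarkAffine()` solves the least-squares affine from ≥ 4 shared,
non-coplanar named landmarks; `applyTransform()` resamples by pull-back
(trilinear for continuous fields, nearest neighbor for labels; out-of-grid
samples map to background). Components are sorted to the region with the
highest mean of the positive map part (`sortByRegion()`), ties broken by
overlap count, then lowest label.

A region counts as *present* in a map when more than 0.5% of its voxels
exceed the map's 3σ threshold — the presence criterion itself is this
package's convention, and both numbers are configurable. Automatic artifact
flagging (`classifyArtifacts()`) marks components present in more than 5
regions (flagged as movement) and/or fragmenting into more than 200
connected objects under 26-connectivity (flagged as noise). Both an "or"
and an "and" combination rule are implemented; "or" is the default because
genuine artifact classes typically violate one criterion strongly, while
the literal reading of the source procedure is the conjunction. Manual
flags are never overridden. Object counting uses a voxel-adjacency graph
(6/18/26-connectivity) and graph components.

# Map statistics

Condition maps are voxelwise mean differences between frame sets
(antisymmetric under swapping; positive displayed green, negative magenta,
configurable). Stimulus maps pool the 1-s post-onset windows minus the 1-s
pre-onset windows; onsets without a full window are dropped and reported.
The indicator kernel is the peak-normalized double exponential
$(1 - e^{-t/\tau_r})\,e^{-t/\tau_d}$ with $\tau_r$ solved so the peak sits
at the probe's rise-to-peak time; turn regressors are the causal
convolution of ball optic flow with this kernel. Cross-correlation lags are
located on a normalized cross-correlation with parabolic sub-frame
refinement (positive lag = second series follows the first).

`mapPermutationTest()` offers a seeded circular-shift permutation test for
condition maps (off by default; the maps themselves are raw differences).
Shifts shorter than the indicator impulse response are excluded from the
null (default margin 5 s): a shift of a few hundred milliseconds leaves the
labels aligned with the *lagged* fluorescence — sometimes better aligned
than the truth, because the kernel delays the response — and is not a valid
draw from the null hypothesis.

# Numerical choices and degenerate inputs

* Box averages: cumulative-sum implementation, shrinking windows at edges.
* RL: $10^{-12}$ floor on predicted intensities; nonnegativity clamped each
  iterate.
* Motion correction on an all-constant frame: zero shift with a warning.
* ΔF/F: baselines floored at $10^{-6}$ of the maximum; voxels failing the
  floor are masked to zero and counted.
* Shoulder detection drops trailing numerical-rank zeros
  ($\le 10^{-12}\,\sigma_1$) before taking logs; a flat spectrum raises a
  "no shoulder" error and the pipeline driver falls back to a configured
  count.
* All generator and analysis randomness flows through explicit integer
  seeds; generation restores the caller's RNG state.
* 0-based voxel convention, x fastest; physical coordinate of voxel $i$ is
  $(i-1)\cdot\text{pitch}$; NIfTI pixdim carries voxel size and frame
  period.

# Benchmarking convention

End-to-end recovery is scored by Hungarian assignment of ground-truth
sources to components, on map cosine similarity and trace Pearson
correlation. Because the chain detrends the movie before extraction,
extracted traces can only carry the filtered signal; ground-truth traces
are therefore passed through the same box filter before correlating
(`matchSources(..., detrendWindowS = )`). Comparing against raw traces
would penalize the detrending choice, not the extraction.

The test and acceptance problem sizes were chosen as the smallest grids on
which each property is meaningfully testable: the full-size recovery run
uses a 64 × 32 × 16 volume with 2000 frames at 100 Hz and 8 sources; the
behavior-coupling and map phantoms use quarter-size grids. The
walk-versus-rest exactness check renders its phantom noise- and bleach-free:
off-support voxels are then constant, so "significant exactly on the
coupled voxels" is well defined, which no finite noisy sample can achieve
(a p < 0.01 test has a ~1% false-positive rate off support by
construction); a noisy variant asserting full sensitivity is kept
alongside.

# Known limitations

* The light field model is geometric, not wave-optical: quantitative
  agreement with a physical-optics PSF library is not claimed, only a
  self-consistent forward/adjoint pair with depth recoverability.
* Registration is affine from landmarks only; it degrades in areas without
  clear landmarks and makes no attempt at nonrigid correction.
* Motion is rigid translation; rotation and local deformation are not
  modeled or corrected.
* The ICA component count depends on the shoulder convention; other axis
  scalings move the shoulder and hence the count.
* Artifact classification implements only the two automatic rules; the
  manual curation step of real analyses has no formal counterpart.

# A minimal worked run

```{r, eval = FALSE}
cfg <- pipelineConfig(
  seed = 1,
  simulate = list(shape = c(32L, 16L, 8L), n_regions = 4L, n_sources = 4L,
                  duration_s = 20, frame_rate_hz = 100),
  preprocess = list(discard_initial_s = 0, motion_correct = FALSE)
)
res <- runPipeline(cfg, "pipeline_out")
res$components
```
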