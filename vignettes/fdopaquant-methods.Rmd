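---
title: "Methods: semi-automated F-DOPA PET quantification of pediatric gliomas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automated F-DOPA PET quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdopaquant)
```

## The problem

[18F]F-DOPA PET of brain gliomas is read through semi-quantitative indices:
the ratio of the tumor's maximum uptake to the maximum in the corpus
striatum (T/S) and to a normal-tissue reference (T/N), and — when a dynamic
acquisition exists — the shape of the tumor's time-activity curve (TAC):
its time-to-peak, its late slope, and the slope normalized to the striatum's
(DSR). Manual extraction requires an operator to delineate the tumor on
every study (and, for dynamic scans, on a late frame that must then be
back-projected), which is slow and poorly reproducible. This package
automates the chain from BIDS inputs to a CSV of indices, with a
deliberately small amount of manual input: a FLAIR-drawn lesion mask and a
brain mask, both produced upstream with standard interactive tools.

## Pipeline model and assumptions

**Reference region.** The reference is the *entire white matter of the
hemisphere contralateral* to the lesion (left hemisphere for subtentorial
tumors), taken from a Desikan–Killiany-style parcellation and binary-eroded
to suppress spillover from adjacent hot structures. Using a large reference
makes its maximum stable; using the contralateral side keeps it clear of
tumor infiltration, and the pipeline *verifies* that the tumor mask does not
intersect the eroded reference, refusing contaminated configurations rather
than silently producing a biased N.

**Segmentation.** The brain-masked PET is normalized voxelwise to
`N = max(reference uptake)`; voxels with SUVr strictly above 1 form the raw
candidate. A raw global threshold also selects physiologic high-uptake
anatomy (striatum, venous sinuses), so the candidate is restricted to its
connected components that intersect the FLAIR lesion dilated by a small
radius (default 2 voxels). The automatic volume is adopted only when T/S
and T/N are strictly greater than 1 for *both* the automatic and the
FLAIR-drawn candidate; on any failure the FLAIR-drawn VOI is used. Gating on
all four ratios is the conservative reading of an ambiguous rule ("all
parameters greater than 1"); when the two candidates disagree the event is
written to the log. If the gate fails and the FLAIR VOI is empty, the study
is reported as a negative scan with null metrics.

**Sinus refinement.** Static volumes reconstructed from dynamic scans often
retain superior-sagittal-sinus blood-pool signal adjacent to the tumor. Two
per-voxel features are computed inside the unrefined mask: (i) a sinus
pseudo-probability — the weighted sum of the first two dynamic frames
(defaults w1 = w2 = 0.5; venous signal is maximal early and decays later)
normalized to its maximum; and (ii) a lesion-distance probability — the
small-component-filtered automatic mask OR-combined with the FLAIR lesion,
smoothed with a Gaussian of FWHM 5 mm and renormalized. A 2-means
clustering splits the voxels; the cluster whose centroid is higher on the
sinus feature is labeled sinus; a linear-kernel SVM fitted on those labels
relabels the voxels and the tumor-labeled set is kept. The step runs only
for gated-in lesions with dynamic data. Two guards keep it safe: if the
clusters fail to separate by at least 0.2 on the sinus-probability axis the
mask is considered sinus-free and returned unchanged (genuine blood pool
sits near the top of the [0, 1] scale while tumor early uptake is far
below), and a degenerate single-cluster outcome likewise returns the input
with a warning.

**Quantification.** All ratios are ratios of in-mask maxima. TACs are
per-frame means with population standard deviations, timed at frame
midpoints from the BIDS sidecar (`FrameTimesStart`, `FrameDuration`).
Slopes are OLS fits of mean uptake against time over frames whose midpoint
is at or after 120 s, reported per minute; time-to-peak is the midpoint of
the earliest maximal frame. Intra-tumor sub-regions split the tumor voxels
at `mean ± 2 sd` of in-mask uptake with strict inequalities, exactly as the
defining intervals are written; voxels equal to a boundary (and voxels at or
below `mean − 2 sd`) belong to no sub-region. This leaves a measure-zero
gap by construction, which we keep for fidelity; on a constant tumor the
partition is empty and a warning is raised. Sub-region masks are computed on
raw uptake — SUVr would give identical masks since it is a positive
rescaling.

## Tunable parameters

| key | default | unit | meaning |
|---|---|---|---|
| `preprocess.closing_radius_vox` | 1 | voxels | closing ball for the FLAIR lesion mask |
| `preprocess.erosion_iterations` | 1 | passes | reference white-matter erosion |
| `preprocess.connectivity` | 6 | — | neighborhood for components/growing |
| `segment.flair_dilate_vox` | 2 | voxels | lesion neighborhood for candidate restriction |
| `refine.w1`, `refine.w2` | 0.5, 0.5 | — | early-frame weights (equal weights: the neutral choice, the weighting itself being otherwise unconstrained) |
| `refine.fwhm_mm` | 5 | mm | lesion-distance Gaussian FWHM (metric, matching mm voxel geometry) |
| `refine.min_component_vox` | 10 | voxels | "small component" threshold |
| `refine.seed` | 17 | — | K-means initialization seed |
| `quantify.slope_window_start_s` | 120 | s | slope window start ("second minute", operationalized as frame midpoint ≥ 120 s) |

`init_config()` writes the full default set; unknown keys are rejected at
load so misspelled options cannot silently revert to defaults.

## Coregistration choices

MRI-to-PET alignment is a rigid 6-DOF transform (same subject, same head),
estimated by maximizing 32-bin histogram mutual information — a
cross-modality metric — with centroid initialization and two rounds of
Nelder–Mead refinement on a stride-2 voxel subset, after light Gaussian
pre-smoothing. The contract is tested by known-perturbation recovery, not
internals: a 6/−4/2 mm translation plus 5° rotation on the phantom is
recovered to ≈0.1 mm / ≈0.1°. Template-to-subject alignment is exposed
behind the same transform interface as a low-DOF global similarity model
(rigid + isotropic scale); the transform type is pluggable, so a deformable
backend can be substituted without touching the callers, and transforms
compose (template→MRI ∘ MRI→PET) so labels are resampled exactly once, with
nearest-neighbor interpolation that provably never invents labels. When the
FLAIR and PET grids already coincide the pipeline uses the identity
transform and says so in the log, which keeps noiseless recoveries exact.

## The phantom: what it emulates, and what it does not

The generator produces a 64×64×64, 2 mm isotropic brain: hemispheric
white-matter blocks, caudate/putamen/pallidum and thalamus per hemisphere, a
pons, an ellipsoidal tumor (left, right, or pontine), and a thin superior
midline sinus structure that touches — but never overlaps — the tumor.
Static uptake is piecewise constant per region (defaults: tumor 10,
striatum 6, white matter 2, sinus 8, in arbitrary Bq/ml-scale units) with
optional additive Gaussian noise; an optional radial gradient makes the
tumor core hotter than its rim for sub-region studies. Dynamic uptake
follows one of four per-region trajectory models: accumulation
(`baseline + slope·t` beyond two minutes; tumor default 2 + 0.05 t),
plateau (rise then constant), downward (rise then linear decline), and an
exponentially decaying sinus (amp 30, τ = 25 s) that is bright only in the
first frames. The default frame schedule is 12×10 s followed by 14×60 s —
a wash-in phase finer than the two-minute boundary plus a long tail for
slope fitting; real schedules always come from the sidecar. All noise is
seeded; identical seeds give byte-identical NIfTI output.

Ground truth (`phantom_ground_truth()`) is computed analytically from the
spec, so noiseless runs must recover T/S, T/N, slopes, DSR and TTP exactly,
and they do — to float precision.

The phantom deliberately omits PET physics: no point-spread blurring,
attenuation, scatter, Poisson counting statistics, motion, or anatomical
realism, and its FLAIR shares the PET grid, so the coregistration stage is
exercised by synthetic perturbation rather than true cross-modality
misalignment. Passing tests therefore demonstrate the correctness of the
*computational chain* — segmentation logic, gating, refinement, curve
fitting — not clinical performance on scanner data.

## Numerical choices

* Maxima, means and standard deviations are taken over mask voxels;
  standard deviations are population (divisor n) throughout.
* The SUVr threshold and the gate use strict `>`, as the defining
  inequalities are strict; a lesion whose T/S is exactly 1 falls back to
  the FLAIR VOI.
* Morphology is defined set-arithmetically (dilation = union of shifted
  copies; erosion keeps voxels whose whole structuring element lies inside
  the mask, with outside-the-grid counting as background) and is tested
  against exhaustive per-voxel oracles on small grids. Closing is forced
  extensive (output ⊇ input) to avoid border clipping. Structuring elements
  are digital balls; radius 1 is the 6-connected cross. Erosion that would
  empty the reference falls back to the uneroded mask with a warning.
* Region growing measures distance in world millimetres, not voxels, so
  anisotropic acquisitions grow isotropically in space.
* Gaussian smoothing is separable with kernels truncated at 4σ and
  zero-padded borders; the resulting maps are renormalized to maximum 1,
  so the truncation does not affect their probabilistic use.
* K-means uses 5 seeded restarts; the SVM relabels the same voxels it was
  fitted on (the labels being K-means output, the SVM acts as a
  regularized, margin-based redraw of the boundary). If it degenerates to
  one class the K-means labels stand.
* Slope fits use `lm`; the reported standard error is the usual OLS slope
  SE. With a striatum slope of magnitude below 1e−12 per minute the DSR is
  undefined and emitted as missing with a warning.

## Known limitations

**Extreme-value bias of max-based ratios under noise.** T/S and T/N are
ratios of in-mask *maxima* — that is the clinical definition — and the
maximum over n voxels of a region at level L with additive N(0, σ²) noise
concentrates near `L + σ√(2 ln n)`, not L. The inflation is relatively
larger for the lower-level region (σ/L is larger), so noisy T/S is biased
*low*: at σ = 5% of the tumor level on the default phantom (739-voxel tumor,
1764-voxel striatum) the bias is ≈ −9.5%. Averaging replicates does not
remove it; it is a property of the statistic, and readers comparing
noisy-phantom recoveries against level ratios should expect it. A
peak-SUV-style statistic (mean over a small neighborhood of the maximum)
would trade this bias for a resolution dependence; we keep the field's
definition.

**Single-voxel sensitivity of the late slope.** The TAC of a ~700-voxel
mask averages noise down so far that the OLS slope SE is ~0.001/min; a
single non-tumor voxel that joins the threshold component by chance (a
3.8σ white-matter excursion happens about once per noisy study at σ = 5%)
shifts the slope by several SE. The slope estimate itself remains accurate
to well under 1%, but SE-relative acceptance bands at this problem size are
brittle by construction.

**Other limitations.** The deformable template stage is a global similarity
stand-in behind the registration contract; bilateral or multifocal lesions
are unsupported (the hemisphere rule assumes one side); TAC pattern
*classification* (accumulation vs plateau vs downward) is intentionally not
implemented — the curves are emitted for the reader — and no kinetic
modelling or partial-volume correction is attempted.

## Problem sizes used in the test suite

Unit tests run on 8³–24³ grids against brute-force oracles (100 seeded
random masks for the morphology equivalences, 1000 random tumors for the
sub-region partition); pipeline and recovery tests use the full 64³ phantom,
with 20 seeded replicates for the noisy-recovery study. These sizes make
every oracle exhaustive while keeping a full suite run in a few minutes on
one core.
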