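---
title: "Simulating nodule-bearing chest radiographs and scoring their detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating nodule-bearing chest radiographs and scoring their detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxrsim)
```

## The problem

Evaluating nodule-detection performance on chest radiographs — whether of
human readers or CAD systems — requires lesion-level ground truth: where
every nodule is, and its exact projected extent. Manual annotation is
expensive and itself error-prone. `cxrsim` takes the virtual-clinical-trial
route: real (or phantom) chest CT volumes supply the anatomy, synthetic 3D
nodules supply the lesions, and a parallel-beam forward projection turns
both into a posteroanterior radiograph. Because the nodules are projected
separately from the anatomy, the ground truth is perfect by construction.

This vignette documents the model, its parameters and defaults, the
numerical choices, and what the synthetic phantoms do and do not
demonstrate.

## Physical model

**HU to attenuation.** CT voxels are converted to linear attenuation with
the monochromatic affine model
$$\mu_x = \mu_{water} + (\mu_{water} - \mu_{air})\cdot \frac{HU_x}{S}$$
with defaults $\mu_{water} = 0.2059\ \mathrm{cm}^{-1}$, $\mu_{air} = 0$
(air attenuation is three orders of magnitude below water at diagnostic
energies) and $S = 1000$ (the common DICOM scale; 1024 is accepted for
vendors that use it). The model is monochromatic by construction — no
polychromatic spectrum or beam hardening. Attenuation is clamped at zero so
out-of-range padding values (e.g. −1024 under $S = 1000$) cannot produce
negative attenuation.

**Projection.** The projector is parallel-beam: a pixel of the raw
radiograph is $\sum_i \mu_i \, \Delta s$ along the ray, with $\Delta s$ the
voxel size along the ray direction converted to cm — a dimensionless
optical depth. The posteroanterior view projects along the
anterior–posterior axis. Cone-beam geometry, scatter, noise and detector
blur are deliberately out of scope. The display image is
$1 - \exp(-\text{optical depth})$, min–max normalised per image; the raw
optical depths are always retained alongside, and exports offer 16-bit PNG
(display) or full-precision CSV (raw).

## Preprocessing

The patient table does not appear in real radiographs, so it is removed
first: voxels above −300 HU are grouped by 26-connected 3D components and
the second-largest component is replaced with air. Ranking is by voxel
count, ties broken by the earlier first voxel in canonical scan order, so
the operation is deterministic. The lung is then segmented: the body mask
(voxels above the −400 HU tissue threshold) is hole-filled per axial slice,
and the low-density voxels inside the filled body are kept, discarding
components below 1 cm³ (airway and noise fragments). All three thresholds
are exposed as arguments; they are package choices, not physical constants,
and were fixed before any study generation.

## Nodules and augmentation

Shapes come from a fixed pool. The default pool holds 19 synthetic shapes —
the size of a realistic library of segmented patient lesions — drawn as
lumpy quasi-spheres: a sphere whose radius is modulated along each
direction by a smooth random angular field (a six-wave random cosine sum,
normalised so the relative amplitude is bounded by the `irregularity`
parameter, default 0.3). The support is star-shaped, hence connected.
User-supplied masks (MetaImage/NIfTI) can replace the pool; they are
normalised to $[0, 1]$ with maximum 1.

Each inserted nodule is augmented: rotated in the coronal plane by an angle
uniform on $[0, 360)$ degrees, and rescaled. In *training mode* the three
axis extents are drawn independently and uniformly from 8–20 mm, with 1–6
nodules per image (uniform) drawn from the pool with equal probability. In
*study mode* each lesion gets a single isotropic diameter from the
configured size list — the reading consistent with reporting one "size" per
study lesion. Both modes are available because the phrase "scaled to values
between 8 and 20 mm along all three axes" supports either reading.

Positions are sampled uniformly from the exact admissible set — the voxels
at which the nodule's bounding box lies entirely inside the lung mask,
computed by a box-sum erosion — and pairwise 3D bounding-box overlap is
rejected with a bounded retry budget. Projected 2D overlap may still occur,
as it does in real radiographs.

## Numerical choices

* **Interpolation.** Rotation and rescaling use (tri)linear interpolation.
  Rasterisation onto the CT grid uses supersampled linear interpolation — a
  box average inside each coarse voxel — because point sampling a
  near-binary occupancy under coarsening does not conserve the occupancy
  integral; with supersampling the projected mass is conserved to better
  than 1%.
* **Extent control.** Interpolating a near-binary field contracts its
  half-occupancy surface slightly, so the scaling step measures the
  achieved tight box (voxels ≥ 0.5) and applies up to two corrective
  passes; output grids are kept odd-sized so a sample lands on the
  symmetry plane. The result matches the target extent within one voxel.
* **Resizing to 512×512.** Images are padded to square with zero optical
  depth (centred) and resized bilinearly; masks are resized by exact
  area-overlap interpolation and thresholded at 0.5; lesion centres of
  mass are recomputed on the resized masks. Ground truth is binarised at
  optical depth > 0 — the full projected support.
* **Determinism.** Every stochastic step runs under a locally seeded RNG;
  a study set is a pure function of (volumes, config, pool, seed) and
  regenerates byte-identical manifests.

## The reader-study composition

The default `study_config()` reproduces the benchmark geometry: 201
radiographs from 21 nodule-free volumes — 20 with no nodule (at most one
healthy image per source volume, to avoid duplicates), 53 with one, 67 with
two, 61 with three — and 370 lesions sized 8/10/15/20 mm in counts
32/111/120/107. The size multiset is assigned to lesion slots as a seeded
random permutation; how the original study distributed sizes over slots is
not documented, and a permutation is the least-structured consistent
choice. The composition is validated (slots vs sizes) before any generation
starts.

## Evaluation

A mark localises a lesion when the Euclidean distance to the lesion's
centre of mass is *strictly below* 30 pixels (the boundary comparison is an
argument, since detector-count conventions sometimes differ) and its score
passes ζ with ≥ (strict > available for detector conventions). Candidate
pairs are matched greedily one-to-one by descending score, ties by smaller
distance then lesion id — the matching rule is not standardised in the
field, and the greedy rule is deterministic and matches common FROC
tooling.

FROC: $LLF(\zeta)$ = localised lesions / total lesions; $NLF(\zeta)$ =
false-positive marks / all cases. wAFROC: per-case equal lesion weights
$W_{kl} = 1/L_k$; $FPF$ over nodule-free cases only, using the highest
false-positive score per case. The figure of merit is defined as the
weighted two-sample Wilcoxon statistic with kernel
$\psi(a,b) = 1_{b>a} + \tfrac12 1_{b=a}$, treating unmarked lesions and
mark-free normal cases as $-\infty$ (two "no mark" values tie at ½). This
definition is total under ties and unmarked cases; the trapezoidal area
under the empirical curve extended to (1, 1) is computed independently and
agrees to machine precision, a property the test suite asserts on
randomised instances. `wllf_at()` interpolates the curve at an operating
point (0.2 is the conventional report); at a vertical jump the observed
point's upper wLLF is returned.

Interchange with observer-performance tooling uses the three-table
Truth/NL/LL layout (CSV directory or xlsx workbook).

## What the phantoms show — and what they do not

The thorax phantom (elliptical body cylinder, two lung ellipsoids,
mediastinal slab, optional table, seeded geometry jitter; region HU values
−1000/+20/+40/−800 chosen *inside* the segmentation thresholds so the
defaults are exercised, not trivially satisfied) exists so that every stage
is testable without patient data. Passing tests on phantoms demonstrate the
*mechanics*: exact table removal, lung segmentation with Dice ≥ 0.95 under
20 HU noise, containment of placements, projection identities, ground-truth
bookkeeping and evaluation arithmetic. They do not demonstrate radiographic
realism: phantoms have no ribs, vasculature, scapulae or texture, and a
detector trained on phantom projections will not transfer to clinical
images. For realism the intended inputs are real CT volumes (e.g. public
chest-CT collections in MetaImage format).

Problem sizes used by the shipped tests and the acceptance script — 128³
voxels at 2.5 mm for full-study generation, 64³–96³ for unit tests — are
the package's chosen desk-scale defaults; a 512-capable phantom option
exists for higher-resolution work.

## Known limitations

* Monochromatic attenuation and parallel-beam geometry only; no scatter,
  noise or detector model on the projection side.
* Nodules are additive attenuation; they do not displace lung tissue.
* Anisotropic in-plane spacing is padded in pixel space, which can distort
  aspect slightly for strongly anisotropic volumes.
* Axis-aligned orientations only (no general direction cosines); no DICOM
  series reading.
* No significance testing or FOM confidence intervals — the package
  computes operating points and figures of merit; inference belongs to
  dedicated observer-performance software.
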