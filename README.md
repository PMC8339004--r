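# cxrsim

Synthetic posteroanterior chest radiographs with *perfect* lesion ground
truth, plus the lesion-localization analysis needed to score readers and
CAD systems on them.

Detecting lung nodules on chest radiographs is hard to study rigorously
because pixel-accurate annotations are expensive and imperfect. `cxrsim`
sidesteps annotation entirely: augmented 3D nodules are inserted at random
positions inside the segmented lung of a real (or phantom) chest CT volume,
and the volume is forward-projected with a parallel-beam projector into a
digitally reconstructed radiograph. Because the nodules are projected
separately, every lesion's exact 2D support and centre of mass are known.
The same package then scores mark lists (from human readers or detectors)
against that ground truth with FROC and weighted-AFROC analysis.

## What it computes

**Simulation.** CT voxels in Hounsfield units are converted to linear
attenuation with the monochromatic model

&nbsp;&nbsp;&nbsp;&nbsp;μ_x = μ_water + (μ_water − μ_air) · HU_x / S,

with μ_water = 0.2059 cm⁻¹ and S the vendor scale (1000 or 1024). The
patient table is removed (thresholding + 3D connected components, dropping
the second-largest object), the lung is segmented (tissue threshold,
slice-wise hole filling), and nodules — synthetic lumpy quasi-spheres or
user-supplied segmented masks — are augmented by coronal-plane rotation
(uniform 0–360°) and rescaling to 8–20 mm, placed without overlap inside
the lung, and forward-projected. The diseased radiograph is the sum of the
clean and nodule-only projections; image and per-lesion masks are resized
to 512×512.

**Evaluation.** A mark localises a lesion when its distance to the lesion's
centre of mass is below 30 pixels and its score passes the threshold ζ.
With per-case lesion weights W_kl = 1/L_k (summing to unity per patient),

&nbsp;&nbsp;&nbsp;&nbsp;wLLF(ζ) = (1/K_N) Σ_k Σ_l W_kl · I(z_kl ≥ ζ),
&nbsp;&nbsp;&nbsp;&nbsp;FPF(ζ) = (1/K_F) Σ_k I(FP_k ≥ ζ),

and the wAFROC figure of merit is the weighted Wilcoxon statistic
FOM = (1/K_N K_F) Σ_{k'} Σ_{k,l} W_kl ψ(FP_{k'}, z_kl), which equals the
trapezoidal area under the empirical wAFROC curve extended to (1, 1).
FROC (LLF vs NLF) curves, TP/FP/FN counts, box–segmentation fusion and
Truth/NL/LL rating-table import/export are included.

A thorax phantom generator (body, lungs, mediastinum, patient table, with
known truth masks) makes the whole pipeline testable without any patient
data.

## Worked example

```r
library(cxrsim)

# two phantom "patients", a 3-shape nodule pool, a 7-image mini study
vols <- lapply(1:3, function(i)
  generate_thorax_phantom(thorax_phantom_spec(seed = i))$volume)
names(vols) <- paste0("v", 1:3)
cfg <- study_config(n_per_count = c("0" = 2, "1" = 2, "2" = 2, "3" = 1),
                    size_counts = c("8" = 1, "10" = 3, "15" = 3, "20" = 2),
                    out_size = 256)
st <- generate_study(vols, cfg, nodule_pool(3, seed = 2), seed = 11)
st
#> <study_set> 7 radiographs, 9 lesions (seed 11)
#>   lesion-count classes: 0:2 1:2 2:2 3:1
#>   size histogram (mm): 8:1 10:3 15:3 20:2

# a perfect observer: one mark on every ground-truth centre of mass
marks <- transform(st$manifest$lesions[, c("case_id", "com_x", "com_y")],
                   score = 90)
names(marks)[2:3] <- c("x", "y")
wa <- compute_wafroc(match_marks(marks, st, radius_px = 30))
wa
#> <wafroc_result> FOM = 1.0000 (K_N = 5, K_F = 2, 9 lesions)
wllf_at(wa, 0.2)
#> [1] 1
```

The study set is a pure function of (volumes, config, pool, seed): re-running
reproduces manifests and pixel data byte for byte. `autoplot()` draws the
FROC and wAFROC curves; `tidy()`/`glance()` return them as tibbles. A shell
front end is installed as `exec/cxrsim`
(`cxrsim study --out DIR --seed 1`, `cxrsim evaluate --manifest DIR
--marks marks.csv --out report/`).

For comparison against human and CNN operating points,
`reader_study_benchmark()` ships the detection counts (TP/FP/FN over 370
lesions) and wAFROC figures of merit of nine radiologists and two CNN
detectors from a published 201-image synthetic-radiograph reader study.

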