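---
title: "Quantitative B-mode features for thyroid lesion subtyping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative B-mode features for thyroid lesion subtyping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyroquant)
```

## The problem

Papillary (PTC), follicular (FTC) and medullary (MTC) thyroid carcinoma differ
in prognosis and management, but their B-mode ultrasound appearance overlaps:
PTC tends to be hypoechoic with irregular, blurred margins and
microcalcifications; FTC is often near-isoechoic with smooth margins and
peripheral calcification; MTC is typically the most hypoechoic with fairly
regular margins. `thyroquant` implements a fully quantitative pipeline over
these contrasts: it extracts 21 formula-defined features from a grayscale
frame plus a binary lesion mask, screens them across subtypes
nonparametrically, removes collinear duplicates, and classifies the subtype
with a random forest whose feature relevance is measured by out-of-bag (OOB)
permutation importance.

Because clinical image sets of this kind are not generally redistributable,
the package ships a seeded phantom generator that emulates the relevant image
structure with known ground truth. Every stage of the pipeline is tested
against those phantoms; the generator is first-class, tested code.

## Data model

An `us_frame` is a matrix of intensities on [0, 1] with per-axis pixel
spacing in mm (rows = anteroposterior/depth, columns = transverse). Images
are rescaled by the container's nominal range (e.g. /255 for 8-bit), never
per-image min–max, so the absolute thresholds used below (0.85 for
calcification, 0.2 for anechoic tissue) are comparable across images. RGB
input is collapsed with Rec.601 luminance weights. Spacing is carried
per-axis everywhere; no feature ever uses an averaged spacing. PNG and TIFF
are read natively; DICOM is not (no reader available to this package) — a
DICOM export should be converted to PNG/TIFF and its `PixelSpacing` passed as
`spacing_override`.

## Segmentation refinement

Manual-style masks are refined in two stages. A morphological opening with a
disc of radius `opening_radius_mm` (default 0.2 mm, a deliberate, overridable
choice — the original procedure does not state one) removes satellite
specks. Then a morphological active contour runs for up to 200 iterations:
within a ±2 px band around the current contour, pixels are reassigned to the
side (lesion/background) whose local mean intensity they are closer to — the
external, data-attachment term, which pulls the contour onto intensity steps
— followed by a 3×3 binary median filter, whose fixed points are
curvature-minimizing contours (the internal smoothness term). Convergence is
declared when the mean boundary displacement per iteration drops below 0.05
px. Two guards keep the refinement conservative, which is what a
*semi-automatic correction* of an expert mask should be:

* the region step only acts when the inside/outside mean contrast exceeds
  half the intensity SD in the band — on a near-isoechoic lesion there is no
  edge evidence and only the smoothing term runs;
* the result is reduced to its largest connected component with holes
  filled, so the output is always one region.

The Dice coefficient reported by `refine_mask()` is `modification_dice`: the
overlap between the initial and refined mask, i.e. how much the algorithm
changed the input — deliberately not an accuracy against a reference
standard.

## The 21 features

**Morphology.** `aspect_ratio` = H/W of the axis-aligned bounding box in mm
(taller-than-wide > 1); the box is axis-aligned because H and W are the
clinical anteroposterior/transverse dimensions, not a rotated minimum
rectangle. `perimeter_to_area` (1/mm) uses area = pixel count × pixel area
and a perimeter estimator that is configurable and recorded: the default
`subpixel` estimator traces the marching-squares polygon of the mask after a
0.5 px Gaussian pre-smoothing (on a rasterized 5 mm disk it is within ~4% of
the analytic perimeter; raw marching squares on a binary mask overshoots by
~6% and pixel-edge counting by up to 27%); the alternative `pixel_edge`
estimator counts exposed pixel edges and is exact on axis-aligned rectangles.
PAR keeps units 1/mm rather than being made dimensionless.

**Echogenicity and echotexture.** Lesion pixels outside [0.2, 0.85] are
excluded (possible cystic/calcified tissue), then the mean and median are
divided by the mean of the reference parenchyma: `echo_mean`, `echo_median`.
The reference is an explicit mask when available, otherwise an automatic band
1–4 mm outside the lesion with the same extreme-intensity exclusion — a
reproducible operational proxy for "surrounding normal parenchyma".
`echo_std` is the population SD (denominator N) over the same surviving
pixels; the exclusions apply to the echogenicity statistics only, not to the
texture features, which use all lesion pixels (configurable). `entropy_mean`
and `entropy_std` summarize the per-pixel Shannon entropy (natural log) of a
64-level histogram in a 0.7 mm circular neighborhood (elliptical in pixels
when spacing is anisotropic, clipped at the image border). The four GLCM
descriptors use 32 gray levels, the four unit offsets (0°, 45°, 90°, 135°),
symmetric accumulation, pairs restricted to the mask, and averaging over
offsets; a constant region yields contrast 0, homogeneity 1, energy 1 and a
missing correlation. The level counts, offsets and the natural logarithm are
package choices recorded here because the defining formulas leave them open.

**Margin assessment.** All three margin features operate on the frame
normalized by the reference-parenchyma mean. `gradient_mean`/`gradient_std`
sample the mm-true central-difference gradient magnitude at uniformly
resampled contour points. `profile_mean`/`profile_std` summarize the local
contrast max I(s) − min I(s) of bilinear profiles along the outward normal,
s ∈ [−0.5, +0.5] mm in 0.1 mm steps; normals come from the gradient of the
σ = 1 px Gaussian-smoothed mask, which is stable on staircase contours. An
inventory note: the feature pair named "gradient" is mapped to the
contour-gradient statistics and the pair named "profile" to the
normal-profile local-contrast statistics; the alternative mapping is a
configuration away since the two approaches are close cousins.
`kl_divergence` is D(P‖Q) in nats between the intensity histogram P of the
margin band (all pixels within 0.5 mm of the contour on either side — total
width 1 mm, computed from an anisotropy-aware distance transform) and the
histogram Q of the reference parenchyma, on 64 shared bins over [0, max].
ε-smoothing of Q (ε = 1/(10 × reference pixel count), renormalized) is
applied only when some Q bin is empty where P has mass; this keeps exactly
representable cases exact while guaranteeing a finite divergence.

**Structure.** Calcification candidates are 8-connected components above
0.85 inside the lesion on the *raw* frame (the threshold is an absolute
normalized-grayscale cut); components under `min_area_mm2` (default 0.01
mm², roughly one pixel at 0.1 mm spacing) are discarded as artifacts. Each
component's maximum dimension (largest pairwise pixel-centre distance, mm)
classifies it as micro (≤ 1.5 mm) or macro (> 1.5 mm). The peripheral ring
is the lesion minus its erosion to depth 0.2 × equivalent radius √(A/π) — a
fraction rather than a fixed depth so the zoning is size-independent (a
fixed mm depth is available). A component is peripheral when at least half
its area lies in the ring (ties peripheral). Densities are counts per lesion
mm², `calcified_area_pct` and `cystic_area_pct` are area percentages;
anechoic regions are 8-connected components below 0.2 with the same
coherence filter. `peripheral_calc_count` is the component count in the
ring; a supra-threshold pixel-count variant is exported as an auxiliary
column because count-based and pixel-based readings of "peripheral
calcification" are both defensible.

## Statistics

Per feature: Shapiro–Wilk normality per subtype (report-only — comparisons
always proceed nonparametrically), the Kruskal–Wallis test (tie-corrected H,
χ² reference with k − 1 df), and, only when the global p < 0.05, Dunn's
pairwise z tests with tie-corrected pooled-rank variance, Šidák-adjusted
with m = 3 for the three subtype pairs. Non-significant features keep empty
post hoc cells. No cross-feature multiplicity correction is applied, and the
α = 0.05 gate is the only gate.

Collinearity pruning computes Pearson correlations over all feature pairs
and greedily retains features in priority order — screen-significant ones
first, then a declared clinical-interpretability ranking
(`default_interpretability_rank()`: direct morphological/echogenicity/
calcification measures before abstract texture descriptors) — dropping any
feature correlated above |r| = 0.9 with an already retained one and mapping
it to that partner. The retained set provably contains no pair above the
threshold.

## Classifier

A 100-tree random forest (Gini splits, bootstrap sampling, ⌈√p⌉ candidate
predictors per split, majority vote; vote ties go to the larger training
class, then lexicographic order) is trained on a stratified 70/30 split.
With the default 244-image cohort the split is 171/73 images. Image-level
splitting reproduces that arithmetic; lesion-level splitting (keeping the
two orthogonal views of a lesion together) is offered because paired views
across the split leak information — a caveat worth knowing when reading the
held-out numbers.

The ensemble fitting itself is delegated to a standard implementation, but
OOB bookkeeping is done in this package: per-tree bag counts give each
tree's OOB set; the OOB prediction of a sample is the majority vote over
trees that did not see it. Permutation importance is the mean over trees of
(error on the tree's OOB samples with the feature's column permuted) minus
(unpermuted OOB error) — a delta-error, not an impurity measure. One random
permutation of the whole column is drawn per feature; each tree then sees
its own OOB rows permuted. The reduced model retrains on the top-10 features
with the same split and a fresh seed, and both reports (per-class
precision/recall/F1 in %, row-normalized confusion matrix, OOB and held-out
accuracy) are returned side by side.

## The phantom generator

Each phantom is a speckle-textured frame with one star-convex lesion:

* boundary r(θ) = R(1 + a·h(θ)), h a seeded random sum of harmonics k = 2…m+1
  normalized to unit maximum, stretched along the AP axis by `aspect_stretch`;
  the ground-truth aspect ratio is computed from the continuous curve, not
  the raster;
* interior mean = `echogenicity_ratio` × parenchyma mean; the edge
  transition is a Gaussian blur of scale `margin_blur_mm`;
* speckle multiplies the scene with a unit-mean Rayleigh envelope low-pass
  filtered to a 0.3 mm correlation length — the standard fully-developed-
  speckle marginal; the low-pass acts on the envelope, so the point-wise
  contrast is mild, consistent with display-compressed B-mode texture (a
  full-contrast interference model would push ~8% of near-isoechoic tissue
  above the 0.85 threshold and make the fixed cuts meaningless);
* calcifications are discs at intensity 0.95 and anechoic inclusions discs
  at 0.05, placed by rejection sampling with a 2 px separation moat; the
  requested zone is verified with the *same* erosion-derived majority rule
  the detector uses, so recorded counts are consistent with extraction by
  construction. Geometrically infeasible requests error out; the cohort
  generator redraws such jittered parameter sets (bounded, seed-
  deterministic).

The three default templates encode the qualitative subtype contrasts (PTC:
hypoechoic, strongly irregular, blurred margin; FTC: near-isoechoic, smooth,
sharp margin, many peripheral calcifications; MTC: most hypoechoic, smooth,
occasional central macrocalcification) with uniform ±15% jitter. The source
cohort reports only effect directions and two medians, so the template
magnitudes are package choices made once to give well-separated classes; the
default cohort sizes (90/14/18 lesions, two views each) mirror the clinical
class imbalance. Consequently the pipeline's headline numbers on phantoms
(near-perfect held-out accuracy, all features significant at n = 244) are
*structural analogs* of the clinical results, not reproductions: passing
tests show the estimators, tests and classifier behave correctly, not that
real thyroid images are this separable.

## Numerical choices and edge cases

* Perimeter: see above; the estimator name is returned with the value.
* Recovery fixtures use sharp margins when checking that the extracted
  echogenicity ratio matches the generator's target within 2%: a blurred
  edge genuinely lowers the interior mean (partial-volume rim), which is
  physics rather than estimator error.
* KL smoothing is conditional (above); the divergence of a band and
  reference drawn from one texture is bounded by finite-sample bias ≈
  bins/(2 × effective sample count), which is visibly above zero for
  spatially correlated speckle.
* Entropy/GLCM quantization maps intensity 1.0 into the top level (no
  overflow bin); neighborhoods are clipped at the image border rather than
  padded.
* Degenerate inputs: all-equal groups give H = 0, p = 1 with a flag;
  constant regions give NA correlation; constant feature columns are
  excluded from pruning with a warning; a lesion whose pixels are almost all
  excluded raises a "predominantly calcified/cystic" error, which the cohort
  extractor converts to an all-NA row plus warning, and such rows are
  dropped (with a message) before classification.
* Problem sizes in the test suite — 122–244 phantom images at 128×128 px
  and 0.1 mm spacing, 2000-replicate null calibrations, 10-seed classifier
  checks — were chosen as the smallest sizes at which the studied effects
  are stable.

## Known limitations

* The margin-band KL divergence does **not** decrease monotonically with
  margin blur on noiseless phantoms — it increases. With a narrow (or
  degenerate) parenchyma histogram, blurring replaces pure-parenchyma band
  pixels with intermediate ramp intensities that fall outside the reference
  support, and the out-of-support mass dominates the divergence. A
  decreasing blur response would require a transport-aware dissimilarity
  (e.g. Wasserstein) or heavy-tailed reference texture. The KL feature is
  still a faithful lesion/background separability measure: it rises sharply
  with lesion/parenchyma contrast, which is the contrast the subtype screen
  exploits.
* Phantoms model no attenuation, shadowing, beam-profile or posterior
  features; calcifications cast no acoustic shadow.
* The active contour is conservative by design and will not recover from a
  grossly wrong initial mask; it refines, it does not segment de novo.
* Real cohort idiosyncrasies (vendor post-processing, operator gain, depth-
  dependent resolution) are outside the generator's scope; conclusions
  about real images require real images.
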