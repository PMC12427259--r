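# thyroquant

Quantitative B-mode ultrasound analysis of focal thyroid lesions for
differentiating the three major carcinoma subtypes — papillary (PTC),
follicular (FTC) and medullary (MTC). The package is aimed at quantitative-
imaging researchers who want transparent, formula-defined features rather
than black-box descriptors: every feature has a closed-form definition, a
unit, and a test against an independent oracle.

## What it computes

From a grayscale frame normalized to [0, 1] plus a binary lesion mask (and
an optional reference-parenchyma mask), `thyroquant` extracts 21 features in
four families:

* **Morphology** — aspect ratio AR = H/W of the axis-aligned bounding box
  (taller-than-wide > 1) and perimeter-to-area ratio PAR = P/A (1/mm), a
  margin-irregularity proxy.
* **Echogenicity / echotexture** — normalized echogenicity NE = μ_lesion /
  μ_parenchyma (mean and median, after excluding pixels outside
  [0.2, 0.85]), global SD σ, local Shannon entropy E = −Σ p_k log p_k in a
  0.7 mm neighborhood, and GLCM contrast / correlation / homogeneity /
  energy.
* **Margin assessment** — contour-gradient statistics, normal-profile local
  contrast C_local = max I(s) − min I(s) on s ∈ [−0.5, 0.5] mm, and the
  Kullback–Leibler divergence D_KL(P_band ‖ Q_parenchyma) between the 1 mm
  margin-band histogram and the parenchyma histogram.
* **Structure** — micro/macro calcification counts and densities (1.5 mm
  maximum-dimension cut), calcified area %, peripheral calcification count
  (erosion-derived peripheral ring, depth 0.2 × equivalent radius), and
  anechoic (cystic) area %.

Downstream, the per-image feature table is screened with Kruskal–Wallis
tests across subtypes and Dunn–Šidák post hoc pairs, pruned of collinear
features (|r| > 0.9, significant features retained preferentially), and fed
to a 100-tree random forest with out-of-bag permutation importance
(delta-error) and a reduced top-10-feature model. A semi-automatic mask
refinement (morphological opening + a conservative active contour) and the
Dice coefficient quantify how much an initial manual mask is corrected.

Because clinical cohorts of this kind are not redistributable, the package
includes a seeded phantom generator (speckled parenchyma, star-convex lesion
with controllable echogenicity ratio, boundary irregularity, margin blur,
calcifications by size and zone, anechoic inclusions) that emits ground
truth for every feature; the whole pipeline is developed and tested against
it. See `vignettes/thyroquant-methods.Rmd` for the full methods account.

## Worked example

```r
library(thyroquant)

spec <- phantom_spec(echogenicity_ratio = 0.6, lesion_radius_mm = 4,
                     irregularity_amplitude = 0.15, margin_blur_mm = 0.2,
                     calcifications = list(list(max_dim_mm = 1.0, zone = "peripheral"),
                                           list(max_dim_mm = 2.0, zone = "central")),
                     anechoic_fraction = 0.05, seed = 7)
ph <- generate_phantom(spec)
feats <- extract_features(ph$frame, ph$mask, ph$reference)
round(t(feats), 3)
```

```
aspect_ratio          0.919
perimeter_to_area     0.539
echo_mean             0.621
echo_median           0.611
echo_std              0.027
entropy_mean          1.456
entropy_std           0.599
glcm_contrast         7.133
glcm_correlation      0.902
glcm_homogeneity      0.895
glcm_energy           0.242
gradient_mean         0.787
gradient_std          0.224
profile_mean          0.431
profile_std           0.150
kl_divergence         3.677
micro_density         0.020
macro_density         0.020
calcified_area_pct    7.724
peripheral_calc_count 1.000
cystic_area_pct       4.944
```

Reading the numbers: the lesion is hypoechoic (`echo_mean` 0.62 against the
requested ratio 0.6; the small excess is the speckle/rim contribution), its
margin is moderately sharp (`profile_mean` 0.43 of a possible ~0.5 step),
and the structural counts recover the generator's ground truth exactly — 1
micro + 1 macro calcification (`micro_density` = `macro_density` = 0.02 per
mm² over ~50 mm²), one of them peripheral, and 4.9% cystic area against the
5% target.

The cohort-level analysis is organised as numbered drivers:

```sh
Rscript analysis/01_simulate.R          # 244-image cohort manifest + ground truth
Rscript analysis/02_extract_features.R  # results/features.csv (one row per image)
Rscript analysis/03_screen.R            # Kruskal-Wallis / Dunn-Sidak + pruning
Rscript analysis/04_classify.R          # RF reports + OOB permutation importance
```

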