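---
title: "Measuring upper-airway collapse from respiratory-phase CT"
author: "airwayCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring upper-airway collapse from respiratory-phase CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwayCT)
```

# The problem

Obstructive sleep apnea (OSA) is driven by a narrow, compliant pharynx that
collapses during sleep, and it is a common and consequential comorbidity of
heart failure. One way to quantify that collapsibility on imaging is to
scan the upper airway under several respiratory phases — calm breathing,
deep end-inspiration, deep end-expiration, and a Muller maneuver (forced
inspiration against closed nose and mouth) — and compare the airway's
cross-sectional caliber between phases. airwayCT implements that analysis
end to end: it segments the dark air column out of CT volumes with an
iterative single-threshold rule, partitions it into four anatomical
regions, measures per-region cross-sectional areas per phase, reduces them
to a per-region *collapse degree*, and compares case and control cohorts.
Because no imaging data are distributed with the package, every claim the
test suite makes is established on synthetic phantoms and cohorts whose
ground truth is known analytically.

# Segmentation model

## Iterative threshold selection

The volume is first quantized to $L = 256$ integer gray levels (see
*Quantization* below) and summarized by its histogram $H_F$,
$F \in \{0, \dots, L-1\}$. The global threshold is the fixed point of the
midpoint-of-class-means map. Starting from the midpoint of the support,

$$k_0 = \frac{F_{\max} + F_{\min}}{2},$$

each iterate splits the histogram at $\lfloor k_i \rfloor$, computes the
mean gray value of the lower class ($D_L$, levels $0..\lfloor k_i
\rfloor$) and the upper class ($D_R$, levels $\lfloor k_i \rfloor +
1..L-1$), and updates

$$k_{i+1} = \frac{D_L(k_i) + D_R(k_i)}{2},$$

stopping when $k_{i+1} = k_i$.

**Why exact equality is a safe stopping rule.** Both class means are
nondecreasing functions of the integer split level: moving the split up
adds larger values to the lower class and removes the smallest values from
the upper class. The induced map on split levels is therefore monotone, so
its orbit is monotone, settles on a fixed split level within at most $L$
steps, and from then on the iterate repeats bit-identically. No tolerance
or rounding is needed, and none is applied by default: a rounded or
tolerance-stopped threshold can land in a different histogram bin than the
true fixed point and change the binarization. The `tol` parameter remains
for callers who want earlier stopping, and `maxIter` (default 100) guards
against misuse; the suite verifies convergence and exact agreement with an
exhaustive fixed-point scan on a thousand random histograms.

Degenerate splits (one class empty, possible only for out-of-range
candidate thresholds) are clamped to the nearest split that keeps both
classes nonempty, which preserves the fixed-point semantics on skewed
histograms. A single-level histogram has no threshold to select and is
rejected with an error.

## Polarity, erosion and lumen extraction

Air is low-attenuation, so the airway lumen is the *dark* class: voxels
with quantized value $\le k$ are foreground by default (a `polarity` flag
inverts this for callers who want the tissue class).

Global thresholding leaves peripheral background structures attached to
the foreground. A single pass of binary erosion peels the foreground
boundary: a voxel survives iff every offset of the structuring element
lands on foreground. The default element is the in-plane 3×3 cross
(4-neighborhood plus origin), applied slice-wise, which removes exactly a
one-pixel rim from each axial cross-section — the minimal peel that
detaches thin bridges without eating the lumen. A 3×3 square and a 3-D
6-neighborhood cross are available, as is an iteration count.
Out-of-volume neighbors count as background, so masks touching the border
shrink there too; this is the conservative standard convention.

The lumen is then the single connected component kept by
`extractLumen()` — the largest by voxel count, or the one containing a
seed voxel. Components use 26-connectivity in 3-D by default because the
airway is a tube that may run obliquely through the slice stack; exact
size ties are broken by the component with the lexicographically smallest
$(x, y, z)$ coordinate, making segmentation fully deterministic.

## Quantization

Attenuation is mapped linearly from a configurable window onto
$\{0..L-1\}$ with `round()` and clipping. The default window is $[0, 255]$
— an identity for data already on an 8-bit-like scale, such as the
phantoms. Hounsfield-unit data should set the window explicitly (for an
air/soft-tissue problem, something like $[-1000, 400]$); all downstream
thresholds are in quantized gray-level units.

# Airway regions and the collapse statistic

Five axial landmarks — nasopharyngeal dome, hard-palate plane, lower soft
palate, upper epiglottis, upper hyoid — bound four contiguous regions:
nasopharyngeal, posterior palatal, retrolingual, laryngopharyngeal. Ranges
are half-open on 1-based slice indices (slice 1 most cranial), so the
partition is exact: disjoint and covering. Landmarks are an input
(phantoms carry ground-truth indices; real data supply a small CSV/JSON
file); automatic landmark detection is out of scope.

Each region's representative area is a summary of its per-slice area
profile (foreground pixel count × pixel area). The default summary is the
**minimum**: collapsibility is governed by the narrowest section of a
segment, and the bottleneck is what obstructs. A `mean` summary is
provided for users who prefer an averaged caliber.

The collapse degree of a region is

$$\text{collapse} = \frac{A_{\text{exp}} - A_{\text{insp}}}{A_{\text{exp}}},$$

with $A_{\text{exp}}$, $A_{\text{insp}}$ the representative areas at deep
end-expiration and deep end-inspiration. It is 0 for an unchanged airway,
at most 1, negative when the airway widens on inspiration, invariant to a
common rescaling of both areas, and undefined (an error) when the
expiratory area is zero. Calm-breathing and Muller volumes are segmented
and measured but do not enter the formula.

**Erosion bias.** The one-pixel erosion rim biases absolute areas downward
by roughly $\pi r^2 - \pi (r-p)^2$ for a lumen of radius $r$ at pixel size
$p$. The package reports eroded areas, faithful to the segmentation
pipeline, rather than compensating; the bias largely cancels in the
collapse *ratio* (at the default geometry the residual error at a true
collapse of 0.6 is about 0.03) and is covered by the recovery tolerances
below.

# The phantom: what it emulates and what it does not

`generatePhantom()` builds a dark tube (gray value 40) inside bright
tissue (gray value 200) with additive Gaussian noise, on a
$64 \times 64 \times 44$ grid at $0.5 \times 0.5 \times 2.5$ mm — the
axial step matching 5 mm slices reconstructed every 2.5 mm, and an axial
extent of about 11 cm covering dome to hyoid. The 160-gray-level contrast
with default noise SD 8 (5% of contrast) reflects the large air/soft-
tissue contrast of CT and makes the histogram bimodal, which is the
operating assumption of a single global threshold. Defaults place the
landmarks at slices 3, 12, 21, 30, 39 and give the regions expiratory
radii of 9 mm (nasopharyngeal) and 8 mm (the rest).

Three intentional design points:

* **Within-region waist.** Each region's radius profile carries a mild
  (10%) sinusoidal narrowing at its midpoint, so the narrowest
  cross-section sits in the region's interior. This encodes the anatomical
  premise behind the `min` summary — each segment has an interior
  bottleneck — and keeps the region's minimum from being dominated by the
  2-slice blend toward a narrower neighboring region at the boundary,
  which would mix two regions' calibers into one measurement.
* **Analytic collapse targets.** `generateSubject()` sets inspiratory
  radii as $r_{\text{insp}} = r_{\text{exp}}\sqrt{1 - \text{target}}$, so
  the target collapse holds exactly in analytic areas, waist and all. The
  phantom's metadata carries the analytic per-slice radii and areas for
  oracle comparisons.
* **Determinism.** Volumes are fully determined by the spec (including
  its seed) and phase; noise draws differ across phases.

The phantom deliberately omits partial-volume averaging, beam hardening,
anatomical curvature beyond a sinusoidal wobble, motion, and any
surrounding anatomy other than uniform tissue. Passing recovery tests
therefore demonstrate that the *algorithmic chain* — quantization,
threshold fixed point, erosion, component extraction, area summaries,
collapse arithmetic — is correct and stable under noise, not that the
pipeline meets clinical accuracy on real CT, where landmark placement and
partial-volume effects would dominate.

# The synthetic cohort

`cohortSpec()` describes a 30-vs-30 case/control cohort. Demographics
default to the matched baseline of a typical OSA/heart-failure comparison:
age 45.54 ± 10.15 vs 47.69 ± 11.12 years, height 1.66 ± 0.08 vs
1.65 ± 0.10 m, weight 67.52 ± 10.51 vs 66.85 ± 11.86 kg, and 24/6 vs 22/8
males/females — group differences that should *not* reach significance.
Cardiac dimensions are larger in the apnea group (LVESD 42 ± 6 vs 37 ± 5
mm, LVEDD 62 ± 7 vs 56 ± 6 mm) and FEV1/FVC mildly lower (72 ± 9 vs
76 ± 9 %).

Collapse degrees are drawn per region from normals truncated to
$(-0.5, 1)$, the plausible range of the statistic. Defaults: 0.10 in the
nasopharyngeal region for both groups (the nasopharynx is splinted by bone
and expected not to differ), and 0.30 vs 0.12 (SD 0.15) in the three
collapsible regions. The 0.18 difference at SD 0.15 is a standardized
effect of 1.2 — large, as regional collapse differences in symptomatic OSA
are — giving per-region power above 99% at $n = 30$, so the *joint*
qualitative pattern (three regions significant, nasopharynx not) holds in
well over 90% of replicates while each null metric keeps its nominal 5%
false-positive rate. `nullEffects = TRUE` collapses every test-group
distribution onto its control counterpart for type-I calibration.

# Group comparison

`compareCohort()` mirrors a conventional two-group baseline analysis:
for each continuous metric an independent two-sample t-test — pooled
variance by default, the classical reading of "independent-sample t-test",
with Welch available — switching to the Wilcoxon rank-sum test when a
Shapiro-Wilk check (at $\alpha = 0.05$) fails in either group; the sex
ratio uses an uncorrected Pearson chi-square on the 2×2 table, with a
Yates option. P-values are two-sided throughout. No multiple-testing
correction is applied by default, matching common practice for baseline
tables; a Bonferroni flag is provided.

The rank-sum test enumerates the exact null distribution of U over all
group assignments for combined $n \le 10$ and otherwise uses the normal
approximation with tie-corrected variance and continuity correction, which
agrees with the exact branch within 0.02 already at the crossover size.
`tTestFromSummaries()` computes the t-test directly from published
(n, mean, SD) triples — useful for checking reported baseline tables —
and `tTestFromRaw()` delegates to it, so the two routes agree exactly.

# Numerical choices and degenerate inputs

* Threshold iteration: exact-equality convergence, clamped degenerate
  splits, error with attached trace on non-convergence.
* Binarization: foreground is `value <= k`; the two classes always
  partition the voxel set exactly.
* Erosion at borders: outside counts as background (anti-extensive
  everywhere).
* Component ties: lexicographic smallest minimum coordinate.
* Region with no foreground anywhere: area 0 with a warning; a zero
  expiratory area makes the collapse degree an error, not NaN.
* Both-SDs-zero t-test: t = 0 (p = 1) when means agree, error otherwise.
* All-tied rank-sum: p = 1. Zero-margin 2×2 table: error.
* Classification loss at a zero true-class probability: clamped at
  `eps = 1e-12` by default, an error in strict mode.

# Problem sizes used by the shipped checks

The test-suite and acceptance script sizes are chosen to make the
statistical assertions sharp while staying desk-scale: 1,000 random
histograms for the fixed-point scan, 20 noisy phantoms × 4 regions for
collapse recovery (tolerance ±0.05), 1,000 zero-effect cohorts for type-I
calibration (band 0.05 ± 0.02 per metric), and 100 default-effect cohorts
for the qualitative regional pattern (required in ≥ 90%). A full
run of the suite takes well under a minute.

# Known limitations

* Single global threshold: volumes whose histogram is not essentially
  bimodal (strong inhomogeneity, contrast material) will threshold
  poorly; no adaptive or multi-threshold variant is provided.
* No partial-volume modeling: areas are voxel counts, so sub-pixel
  caliber changes are invisible and small lumina are quantization-limited.
* Landmarks are inputs; mis-placed landmarks shift region boundaries and
  the regional minima with them.
* The detection-loss functions are exactly that — pure functions
  (cross-entropy plus smooth-L1 with the positive-anchor gate) for
  analytic testing; no proposal network, anchors, or training loop is
  included, and no claim is made about detector performance.
* The cohort generator draws independent metrics; it does not model
  correlations between, say, weight and collapse degree.
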