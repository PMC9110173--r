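# airwayCT

Quantifying upper-airway collapsibility from respiratory-phase CT.

Obstructive sleep apnea (OSA) — repeated pharyngeal collapse during
sleep — is a frequent comorbidity of heart failure, and one imaging
route to its anatomy is to scan the upper airway under several
respiratory phases (calm breathing, deep end-inspiration, deep
end-expiration, Muller maneuver) and measure how much each airway
segment narrows. airwayCT implements that analysis for researchers
working with such scans or validating the method in silico:

* **Segmentation** — the airway lumen (the dark air column) is extracted
  by an iterative single-threshold rule. The global threshold is the
  fixed point of the midpoint-of-class-means map on the gray-level
  histogram `H_F`:

  ```
  k0 = (F_max + F_min) / 2
  k_{i+1} = (D_L(k_i) + D_R(k_i)) / 2,   stop when k_{i+1} = k_i
  ```

  where `D_L`, `D_R` are the mean gray values of the classes below and
  above the split. Binarization (air = values ≤ k) is followed by one
  pass of binary erosion (in-plane 3×3 cross) to detach peripheral
  background, and by 26-connected component extraction of the lumen.

* **Measurement** — five axial landmarks (nasopharyngeal dome, hard
  palate, lower soft palate, upper epiglottis, upper hyoid) partition the
  airway into the nasopharyngeal, posterior palatal, retrolingual and
  laryngopharyngeal regions. Each region is summarized by its narrowest
  cross-sectional area (mm²) per phase, and reduced to the collapse
  degree

  ```
  collapse = (A_exp − A_insp) / A_exp
  ```

  from the deep end-expiration and deep end-inspiration phases.

* **Validation data** — a synthetic phantom generator (dark tube in
  bright tissue, per-region caliber per phase, Gaussian noise) whose
  per-region collapse targets hold analytically, and a synthetic
  30-vs-30 case/control cohort generator.

* **Statistics** — two-sample t-tests (pooled or Welch, from raw data or
  from published n/mean/SD summaries), Wilcoxon rank-sum with exact
  enumeration at small n, chi-square on 2×2 tables, and a whole-cohort
  comparison driver with a normality gate.

* **Detection losses** — the multi-task detection objective
  (cross-entropy plus smooth-L1, regression counted on positive anchors
  only) as pure, analytically testable functions.

## Worked example

Generate a synthetic subject with known per-region collapse
(0 / 0.2 / 0.4 / 0.6), segment it, and measure:

```r
library(airwayCT)

spec <- phantomSpec(seed = 7L)            # 64 x 64 x 44 @ 0.5 x 0.5 x 2.5 mm
targets <- c(nasopharyngeal = 0, posterior_palatal = 0.2,
             retrolingual = 0.4, laryngopharyngeal = 0.6)
sub <- generateSubject(spec, targets,
                       phases = c("deep_end_expiration",
                                  "deep_end_inspiration"))

seg <- segmentAirway(sub$volumes$deep_end_expiration)
seg$trace
#> ThresholdTrace: 3 iterates, converged, final threshold 120.027

meas <- measureSubject(sub$volumes, sub$groundTruth$landmarks)
meas$collapse
#>              region collapse_degree
#> 1    nasopharyngeal       0.0000000
#> 2 posterior_palatal       0.2160279
#> 3      retrolingual       0.4255692
#> 4 laryngopharyngeal       0.6298246
```

The threshold lands midway between the phantom's air (40) and tissue
(200) intensities, and every recovered collapse degree is within 0.05 of
its target — the residual is the one-pixel erosion rim and voxel
quantization, not noise. The retrolingual areas behind the numbers:
142.75 mm² at end-expiration vs 82.00 mm² at end-inspiration.

Cohort comparison on a default synthetic cohort reproduces the expected
pattern — the three collapsible regions differ between groups, the
nasopharynx and the demographics do not:

```r
compareCohort(generateCohort(cohortSpec(seed = 7L)))
#>                        metric     method statistic df        p significant
#> 1                   age_years   pooled t   -1.0652 58 2.91e-01       FALSE
#> 7     collapse_nasopharyngeal   pooled t   -0.0777 58 9.38e-01       FALSE
#> 8  collapse_posterior_palatal   pooled t    4.0699 58 1.44e-04        TRUE
#> 9       collapse_retrolingual   pooled t    3.2065 58 2.19e-03        TRUE
#> 10 collapse_laryngopharyngeal   pooled t    3.2522 58 1.91e-03        TRUE
#> ...
```

A published baseline row can be checked directly from its summaries:

```r
tTestFromSummaries(groupSummary(30, 45.54, 10.15),
                   groupSummary(30, 47.69, 11.12))
#> pooled t = -0.7822 (df = 58), p = 0.4373 (not significant at alpha = 0.05)
```

An end-to-end demo configuration (two phantom subjects plus a cohort
comparison) ships with the package:

```r
runPipeline(system.file("extdata", "demo-config.yaml", package = "airwayCT"))
```

and a thin command-line front end with `simulate-volumes`,
`simulate-cohort`, `segment`, `measure`, `compare`, `run` and `loss-demo`
subcommands lives at `inst/cli/airwayct.R`.

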