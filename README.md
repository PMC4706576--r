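# ccmorph

Centile-width morphometry of the mid-sagittal corpus callosum, in R.

Focal brain injury thins specific segments of the corpus callosum while
leaving its overall size nearly unchanged — after perinatal
hypoxic–ischaemic injury, for instance, the commissural fibres of the
paracentral lobules are lost and the mid-posterior body of the callosum
narrows. Whole-structure measures (area, perimeter, length) miss this;
`ccmorph` implements the regional analysis chain that finds it:

1. **Geometry** — from a binary mid-sagittal mask, extract the contour,
   locate the anterior/posterior tips, and divide the structure into 100
   radial segments by fitting 99 percentile slices: the centreline is
   relaxed to the fixed point where it passes through the midpoints of the
   99 slices erected normal to it at equal arc-length fractions. Output:
   the 99 centile widths *w*₁…*w*₉₉ (mm, anterior→posterior), area,
   perimeter, centreline length.
2. **Regionalization** — PCA of the correlation matrix of the widths,
   retention of components explaining >1% of total variance, varimax
   rotation, assignment of each centile to the factor with the largest
   |loading|, and Thurstone regression factor scores (zero mean by
   construction). Factors loading on the extreme tips are flagged as
   end-taper artefacts.
3. **Group statistics** — Shapiro–Wilk screens; paired *t*-tests of the
   global measures; per-centile comparison with 95% CIs and two-sided
   Bonferroni correction over the 99 centiles; one-way ANOVA
   (*F* = MS_between/MS_within, df 1 and n−2) of each regional factor
   score.
4. **Classification** — stratified 10-fold cross-validated linear SVM
   (*K*(x, y) = ⟨x, y⟩, C = 1, per-fold standardization) on the 99
   widths, reporting confusion matrix, precision/recall/F per class,
   sensitivity/specificity, ROC curves and AUC.
5. **Synthetic cohorts** — a generator of callosum-like width profiles
   (regional latent factors, global size variation, per-centile noise, and
   a configurable focal thinning effect peaking at 1.47 mm at centile 63)
   plus a renderer that sweeps any profile into a rasterized arch-shaped
   mask, so the whole pipeline is testable end to end without patient
   data.

## Worked example

```r
library(ccmorph)

cohort <- generate_cohort(generator_config(seed = 7))   # 13 cases vs 13 controls
cohort
#> <cc_cohort> 26 subjects (13 case / 13 control), paired

cmp <- compare_centiles(cohort)
attr(cmp, "summary")
#> $max_abs_diff_mm    1.618004
#> $at_centile         63
#> $test               "paired-t"
any(cmp$sig_bonferroni)
#> FALSE

reg <- regionalize(cohort)
reg
#> <cc_regional_factors> 7 retained factor(s) (97.7% of variance)
#>   factor1: 26.0% variance, centiles 16-37 (22 assigned)
#>   factor2: 24.5% variance, centiles 38-61 (24 assigned)
#>   factor3: 17.1% variance, centiles 5-69 (13 assigned)
#>   factor4: 14.0% variance, centiles 70-83 (14 assigned)
#>   factor5: 8.7% variance, centiles 84-95 (12 assigned)
#>   factor6: 4.7% variance, centiles 1-99 (8 assigned) [end-taper]
#>   factor7: 2.6% variance, centiles 9-14 (6 assigned)

anova_factor_scores(reg$scores[, !reg$end_taper], cohort$group)[, c("factor", "F", "p")]
#>    factor      F        p
#> 1 factor1  0.276 6.04e-01
#> 2 factor2  0.580 4.54e-01
#> 3 factor3 10.940 2.96e-03
#> 4 factor4  0.297 5.91e-01
#> 5 factor5  0.500 4.86e-01
#> 6 factor7 22.660 7.64e-05

classify_cohort(cohort, seed = 7)
#> <cc_classification_report> accuracy 0.923, AUC(case) 0.976, AUC(control) 0.976
#>          predicted
#> truth     case control
#>   case      13       0
#>   control    2      11
```

Reading the output: the largest mean group difference is 1.62 mm at
centile 63 (the mid-posterior body), yet no single centile survives
Bonferroni correction — the per-centile intervals are wide. The factor
analysis condenses the 99 widths into 7 regions; the factors owning the
mid-posterior body (factor3, centiles 62–69) and the genu bundle
(factor7, centiles 9–14) are the two with significant score differences,
i.e. the thinning is regionally coherent even though no individual width
is conclusive. The SVM separates the groups at 92% accuracy on this
particular cohort from the joint profile.

The same stages are scriptable from a shell via `exec/cc-centile`:

```sh
cc-centile simulate --out run1 --seed 7
cc-centile stats    --out run1 --cohort run1/cohort.csv
cc-centile classify --out run1 --cohort run1/cohort.csv --seed 7
```

Masks can be measured directly: `extract_widths(read_mask_png(f, spacing = 0.25))`
returns the 99 widths plus globals for one subject, and
`run_extract()` batches a directory into a cohort CSV.

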