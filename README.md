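# ihcmet

Metabolic phenotyping of tumors from immunohistochemistry (IHC) and
whole-slide brightfield images, with from-formula survival statistics and
synthetic-data generators for end-to-end validation.

## The scientific problem

Solid tumors such as non-small cell lung cancer (NSCLC) mix two opposing
metabolic programs: Warburg-style **glycolysis**, marked by the glucose
transporter **GLUT1**, and **abbreviated gluconeogenesis**, mediated by the
phosphoenolpyruvate carboxykinase isoforms **PCK1** (cytosolic) and
**PCK2** (mitochondrial). Pathology cohorts quantify these markers on
tissue-microarray (TMA) cores with a combined score

```
score = intensity x density,      intensity in {0,1,2,3}, density in [0,100]%
```

giving a 0–300 range; a tumor is *positive* for a marker when its
mean-over-cores score is >= 1. The three positivity flags classify each
tumor into one of four **metabolic phenotypes**:

| GLUT1 | PCK1 or PCK2 | phenotype |
|-------|--------------|---------------|
| +     | −            | glycolytic    |
| −     | +            | gluconeogenic |
| +     | +            | mixed         |
| −     | −            | unspecified   |

Downstream questions — does phenotype predict overall survival, is PCK2
enriched at the invasive tumor margin, how do markers co-vary with
histology and stage — require Kaplan–Meier/logrank/Cox survival analysis,
rank statistics, and an automated margin-versus-center image pipeline.
`ihcmet` implements all of these as a tested, reusable package, and ships
generators that produce TMA cohorts, H-DAB-like slide images and qPCR
plates with *known ground truth*, so every stage is verifiable without
access to the original (non-public) biobank material.

The package is aimed at computational pathology and biostatistics users
who want a deterministic, scriptable re-implementation of this class of
analysis.

## What is inside

- **ihc_scoring** — `core_score()`, `tumor_score()`, `is_positive()`,
  `classify_phenotype()`, `combined_pck_score()`, `score_cohort()`,
  `cohort_summary()` (Table-1-style positivity and phenotype tables).
- **margin_center** — `rgb_to_od()`, `deconvolve_stains()` (Ruifrok–
  Johnston H-DAB), `segment_tissue()`, `build_compartments()` (1 mm
  invasive-margin band via Euclidean distance transform, technical-edge
  exclusion), `detect_macrophages()`, `quantify_slide()`,
  `analyze_slide()`, `margin_center_test()`.
- **cohort_stats** — from formulas: `km_estimate()` (Greenwood CI),
  `logrank_test()`, `cox_ph()` (Newton–Raphson, Breslow/Efron ties),
  `mann_whitney()` (exact by enumeration or tie-corrected normal
  approximation), `spearman_cor()`, `filter_survival()`,
  `median_split()`.
- **expression_quant** — `delta_cp()`, `fold_change()` (2^ΔΔCp),
  `qpcr_fold_changes()`, `normalize_density()`.
- **synthetic_data** — `generate_cohort()`, `generate_slide()`,
  `generate_qpcr()` plus CSV/PNG/JSON writers and a CLI
  (`inst/cli/ihcmet.R`).

## Worked example

```r
library(ihcmet)

# a 450-patient TMA cohort with realistic positivity rates and survival
co <- generate_cohort(cohort_params(n_patients = 450, seed = 1))
scored <- score_cohort(co$cohort)          # one row per patient
summ <- cohort_summary(scored)
subset(summ$positivity, stratum == "LUAD")
#>   stratum marker n_evaluable n_positive  fraction percent
#> 1    LUAD   PCK1         252        107 0.4246032      42
#> 2    LUAD   PCK2         265        179 0.6754717      68
#> 3    LUAD   LDHB         278        256 0.9208633      92
#> 4    LUAD  GLUT1         266        120 0.4511278      45

# survival by phenotype (perioperative deaths excluded)
sv <- filter_survival(merge(co$survival, scored[c("patient_id", "phenotype")]))
ok <- !is.na(sv$phenotype)
logrank_test(sv$time[ok], sv$event[ok], sv$phenotype[ok])$p.value
#> [1] 3.693547e-05

# margin-versus-center quantification on a synthetic H-DAB slide whose
# true margin/center DAB enrichment is 2
sl <- generate_slide(slide_params(margin_effect = 2, seed = 1))
q <- analyze_slide(sl$image, sl$truth$tumor, sl$params$microns_per_pixel)
q$normalized_margin_ratio
#> [1] 1.852858
```

The positivity `percent` column reproduces the printed-table arithmetic
(e.g. 107/252 → 42%); the logrank p-value below 0.05 reflects the
generator's phenotype hazard ratios (1.8 for glycolytic/mixed vs the
gluconeogenic baseline); the normalized margin ratio recovers the
simulated enrichment within the pipeline's ±10% tolerance.

## Documentation

`vignettes/ihcmet-methods.Rmd` describes the scoring and phenotype model,
the margin/center pipeline, the statistical procedures, what the
synthetic generators do and do not emulate, and all numerical
conventions (tie handling, rounding, degenerate cases).
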