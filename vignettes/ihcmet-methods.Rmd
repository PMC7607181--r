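---
title: "Methods: IHC metabolic phenotyping, margin/center quantification, and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IHC metabolic phenotyping, margin/center quantification, and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcmet)
```

# Scope

`ihcmet` implements a complete desk-scale pipeline for metabolic
phenotyping of tumor cohorts: combined-score IHC quantification and
positivity calling on tissue-microarray (TMA) cores, four-way phenotype
classification from GLUT1/PCK1/PCK2, margin-versus-center stain
quantification on H-DAB whole-slide images, survival and rank statistics
written out from their formulas, qPCR/densitometry quantification, and
synthetic-data generators that make every downstream stage testable
against known ground truth. Wet-lab procedures, pathologist visual
scoring, and retrieval of public expression datasets are out of scope;
the package consumes their outputs as tables.

# Scoring and phenotype model

A core's combined score is `intensity x density` with intensity in
{0,1,2,3} and density the percent of stained tumor cells, hence a 0-300
range (an H-score). Tumor-level scores average the evaluable cores;
missing cores are dropped, never zero-imputed, and a marker with no
evaluable core is *non-evaluable* - a distinct state from a true score of
0. Positivity is `mean score >= cutoff` with cutoff 1 by default (any
detectable staining); the cutoff is a parameter so sensitivity analyses
are possible.

The three positivity flags partition tumors into glycolytic (GLUT1+ only),
gluconeogenic (PCK1 or PCK2 positive, GLUT1-), mixed (GLUT1+ and a PCK+),
and unspecified (all negative). Two conventions are deliberate:

* **Strict evaluability.** A sample with any non-evaluable classifying
  flag is excluded from phenotype tallies, even when the remaining flags
  would determine the class logically (GLUT1- and PCK2+ is gluconeogenic
  whatever PCK1 is). The alternative - classify when determinable - would
  change denominators between markers in a way that is hard to audit;
  strictness keeps the phenotype denominator a single well-defined set.
* **LDHB is scored and summarized but never classifies**; it contributes
  to both metabolic pathways and carries no phenotype information.

Cohort summaries report evaluable n, positive n, the raw fraction, and a
percent rounded half-up to integers. Rounding half-up is asserted rather
than R's banker's rounding because printed cohort tables in the
literature use it; the raw fraction is always emitted alongside since
printed rounding is not reliably recoverable (the acceptance suite
documents one printed table row that no single rounding rule can
reproduce from its own counts). An empty stratum reports `NA`
percentages, never 0.

# Margin-versus-center pipeline

The pipeline reimplements, deterministically, a semi-automated
CellProfiler procedure for comparing DAB-stained marker abundance in the
invasive tumor margin against the tumor center.

**Color model.** 8-bit RGB is converted to optical density per channel,
`OD = -log10((I + 1e-6)/255)`, in which stain contributions add linearly
(Beer-Lambert). Stain separation inverts the 3x3 stain matrix per pixel
(Ruifrok-Johnston), clipping negative concentrations to zero. The default
H-DAB matrix uses the standard hematoxylin (0.650, 0.704, 0.286) and DAB
(0.268, 0.570, 0.776) unit vectors with a normalized cross-product
residual completing the basis. The original procedure used unpublished
raw-intensity thresholds; OD deconvolution is the standard reproducible
route to "DAB area" and "hematoxylin area", and the thresholds here
(default 0.15 OD for both channels) are config values calibrated on the
synthetic generator, not reproductions.

**Compartments.** The invasive margin is the band of tumor tissue within
1 mm (configurable) of the tumor/non-tumor interface, measured with an
exact Euclidean distance transform on the pixel grid (square pixels
asserted; the transform is the Felzenszwalb-Huttenlocher two-pass
algorithm in C++). The center is the remaining tumor, so margin and
center partition the tumor exactly. The margin is measured on the tumor
side only; whether a peritumoral band should be included is genuinely
open, and tumor-side-only is the conservative reading of "invasive
margin". Interface segments on the image border cannot be classified as
biological margin - they are cut edges - so the 1 mm band adjacent to
border-touching tumor pixels is excluded automatically, which makes the
manual "technical margin" exclusion rule deterministic. Vessels, bronchi
and artefact exclusions are consumed as user-supplied masks (PNG
sidecars), mirroring the manual step rather than auto-detecting anatomy.
A tumor entirely inside the margin band has no center compartment and
raises an explicit error; such slides are excluded from analysis, as
undersized slides were in the original procedure.

**Macrophages.** Intratumoral and alveolar macrophages take up DAB far
more strongly than tumor cells and would otherwise inflate marker areas.
They are detected as connected components of the DAB channel at or above
a saturation cutoff (default 1.2 OD; synthetic tumor-cell DAB is ~0.8,
synthetic macrophages >= 1.6) with plausible physical size (default
10-600 um^2), and added to the exclusion mask. With exclusion enabled,
seeded speckles move the estimated ratio by well under 5%; disabled, equal
seeding of both compartments inflates both DAB areas equally and biases
the normalized ratio *toward 1* (downward when the true gradient exceeds
1).

**Quantification.** Per compartment, after exclusions: marker area is the
pixel count with DAB concentration >= threshold, nuclei area the count
with hematoxylin >= threshold; the ratio marker/nuclei normalizes for
cellularity and the margin ratio divided by the center ratio gives the
`normalized_margin_ratio` (center = 1 identically). Total integrated OD
per channel is also reported, since it is unclear whether the original
statistic used areas only. Across slides, enrichment is tested with a
one-sample t-test of log2 normalized ratios against 0. Degenerate inputs
are defined by contract: all ratios exactly 1 gives t = 0, p = 1; zero
variance with nonzero mean reports p at the machine floor with a
degeneracy flag, because the t statistic is undefined there.

# Statistical procedures

All of these are written from their formulas; the `survival` package
appears only in the test suite as an independent oracle.

* **Cohort filter.** Deaths within the first month of follow-up are
  removed (perioperative mortality); censored records in the window are
  retained - the exclusion rule names deaths only.
* **Kaplan-Meier.** Product-limit estimate with Greenwood variance on the
  log scale for the 95% CI. With no censoring it equals the empirical
  survival function exactly (a test asserts this).
* **Logrank.** K-group observed-minus-expected with hypergeometric
  variance at each event time; chi-square with K-1 degrees of freedom,
  generalized inverse when the variance matrix is rank-deficient.
* **Cox.** Partial-likelihood Newton-Raphson, converged when the largest
  score component is below 1e-8 (50 iteration cap). Breslow tie handling
  is the default - the original analysis software's default - with Efron
  switchable. Covariates are centered internally for conditioning;
  factors are encoded by the caller (stage indicators against a stage-I
  reference is the documented default in examples). Monotone-likelihood
  separation is detected (diverging coefficients) and flagged with no
  estimates emitted, rather than returning a huge spurious hazard ratio.
* **Mann-Whitney U.** Average ranks; exact two-sided p by enumeration of
  all group labelings when the combined n is at most 12 without ties,
  otherwise a normal approximation with tie-corrected variance and
  continuity correction. The exact path is verified against an
  independent subset-sum dynamic program for every tie-free input with
  group sizes up to 5.
* **Spearman.** Pearson correlation of mid-ranks; p from the t
  approximation with n-2 degrees of freedom.
* **Median split.** "High" is strictly above the median; ties at the
  median go to "low". The original cutoff convention is unstated; ties-low
  is declared and tested. All-equal input cannot form two groups and is an
  error.
* Two-sided p-values throughout, alpha 0.05, no multiplicity correction
  (matching the emulated analysis, which applied none).

# qPCR and densitometry

ΔCp is `Cp(reference) - Cp(gene)` - higher ΔCp means higher expression -
and fold change is `2^(ΔCp_treated - mean ΔCp_control)`. The sentence
defining ΔΔCp in the source methods mixes its symbols; the implemented
reading is the only one consistent with 2^ΔΔCp fold changes.
Multiple control replicates combine by the arithmetic mean of ΔCp
(geometric mean on the fold scale); amplification efficiency is fixed at
2, an efficiency-corrected variant being out of scope. Densitometry folds
are `(band/loading)` normalized to the flagged reference sample, which is
exactly 1 by construction and invariant to rescaling the whole blot.

# Synthetic generators: the stated world

**Cohorts.** Each marker has a standard-normal latent score
`z = a*(T - E[T]) + e` with T the tumor stage and `a` the marker's stage
trend (defaults: -0.3 for PCK2, +0.5 for GLUT1, 0 otherwise, emulating
the reported opposite size trends). PCK2 and GLUT1 residuals share a
Gaussian copula. Positivity thresholds are solved numerically so marginal
positivity matches the configured rates - defaults are the printed TMA
table: LUAD 42/69/91/41% and LUSC 51/40/91/94% for PCK1/PCK2/LDHB/GLUT1 -
and the latent copula correlation is *calibrated* (deterministic internal
Monte-Carlo root-find, fixed internal seed, memoized) so that the
Spearman correlation of the *observed* tumor scores in the LUAD stratum
hits `rho_pck2_glut1` (default -0.2). Calibration is necessary because
negative tumors all tie at score 0 and the shared stage trend itself
induces correlation; even a target of 0 needs a latent correction.
Intensity discretizes the latent into {0..3}; density is a monotone
latent-linked value in {0..100}; positive tumors always have mean score
>= 1 and negative tumors score 0, so the downstream scorer recovers the
generating rates up to sampling noise. Three cores per tumor receive
small intensity/density jitter. Missingness has a patient-level component
(0.12, material lost for all markers) and a marker-level component
(0.09), calibrated so both the per-marker evaluable fractions (~80%) and
the jointly-evaluable fraction (~2/3) match printed cohort denominators;
individual cores drop at 3%. Survival is exponential with hazard
`baseline * HR[phenotype]` (defaults: baseline 0.012/month; HR 1.8 for
glycolytic and mixed, 1.3 unspecified, gluconeogenic = 1, encoding the
reported worse outcome of GLUT1-positive phenotypes), administratively
censored uniformly on [0, 120] months for a configurable fraction
(default 0.3). Times are months since diagnosis. What the generator does
*not* emulate: real score distributions (only medians were reported),
correlated cores within real tumors, cohort-specific stage mixes, or
non-proportional hazards - so a green cohort test establishes correct
arithmetic and calibrated marginals, not biological realism.

**Slides.** The image model is Beer-Lambert mixing of hematoxylin and DAB
OD vectors plus small Gaussian OD noise; background is near-white. Tumor
tissue is a field of small nucleus blobs (radius 7 um, ~900 cells/mm^2 -
sparser and larger than real histology so blobs resolve on the default
4 um/px grid, chosen to keep desk-scale slides a few hundred pixels).
Exactly `round(fraction * n_cells)` cells per compartment carry DAB -
fraction `dab_fraction_center` in the center and `margin_effect` times
that in the margin - so the true normalized margin ratio is
`margin_effect` by construction and free of binomial noise. Macrophages
are saturated speckles (radius 3-8 um, DAB OD >= 1.6) seeded uniformly in
the tumor; artefacts are flat gray rectangles; both are returned as truth
masks along with tumor/margin/center/nuclei/DAB masks. Because cells
overlap, pixel-area ratios saturate slightly at high DAB fractions; the
default coverage (~13%) keeps that bias under ~5% at `margin_effect = 4`,
which is why those defaults were chosen once and left alone. Not
emulated: gland formation, stroma texture, scanner artefacts beyond
rectangles, or multi-resolution pyramids.

**qPCR plates.** Reference-gene Cp constant per sample up to noise; gene
Cp offset by `-log2(fold)` so the expected 2^ΔΔCp equals the requested
fold change; zero-noise plates round-trip exactly.

All randomness in a generator flows from its single `seed` through a
private RNG stream (the global RNG state is saved and restored), and
identical seeds reproduce outputs bit-for-bit.

# Numerical conventions and edge cases

* Distance metric: exact Euclidean distance transform; anisotropic
  pixels unsupported.
* Deconvolution clips negative concentrations to 0; singular stain
  matrices (condition-based check) are rejected.
* `od_to_rgb()` returns continuous intensities; quantization to 8-bit
  happens only when writing files, so OD round-trips are exact to <1% for
  OD <= 2 (8-bit quantization alone would violate this at high OD).
* Percent rounding is half-up (`floor(x + 0.5)`).
* A compartment with zero nuclei area makes a slide non-evaluable rather
  than producing division by zero.
* Slide output uses PNG (8-bit RGB) with 0/255 single-channel PNG mask
  sidecars and a JSON sidecar carrying `microns_per_pixel` and truth
  parameters; no TIFF writer is assumed in the environment.

# Known limitations

* The margin pipeline quantifies one marker per slide and does not tile
  pyramidal whole-slide formats; images must fit in memory.
* The macrophage detector is a cutoff-plus-size rule; on real slides the
  saturation cutoff would need recalibration against the actual stain
  intensity distribution.
* Cox separation handling flags and stops; it does not fall back to
  penalized estimation.
* The generator's survival model is exponential (constant hazard), which
  is the simplest world consistent with the emulated hazard-ratio
  contrasts; Kaplan-Meier shape comparisons beyond proportionality are
  not meaningful against it.
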