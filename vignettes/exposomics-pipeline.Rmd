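---
title: "Chemical exposomics of longitudinal biobank plasma: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical exposomics of longitudinal biobank plasma: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exposomekit)
```

## The problem this package addresses

Wide-scope LC-HRMS chemical exposomics measures, in one injection pair
(ESI+ and ESI-), dozens of validated target analytes (PFAS, steroid hormones,
pesticides, dietary and tobacco markers) together with tens of thousands of
untargeted molecular features in small volumes of archived plasma. Relating
those measurements to reproductive breast-cancer risk factors (age at
sampling, parity, age at menarche) in a longitudinal biobank design raises
four methodological problems that this package implements as a tested,
seed-reproducible pipeline:

1. **Left-censored targeted quantification.** Calibration curves cover a
   finite range; many analytes sit below the method limit of quantification
   (MLOQ) in a large fraction of samples, and a few (caffeine, cotinine,
   hydrocortisone among them) sit above the top calibration level.
2. **Untargeted feature-table treatment.** Aligned feature tables carry
   contamination (procedural-blank signal), cross-polarity duplicates,
   in-source fragments/adducts, and multiplicative instrumental drift that
   must be removed before any statistics.
3. **Annotation with stated confidence.** Spectral-library matches are only
   trustworthy above explicit score thresholds, and identity confidence
   differs between a public-database match and an in-house reference
   standard with retention time.
4. **Repeated-measures association testing.** Many women contribute two
   samples years apart, so per-chemical models need subject-specific random
   intercepts, per-exposure confounder sets, and tiered multiple-testing
   control over ~16,000+ outcomes.

Because individual-level data from the source biobank are access-restricted,
the package ships a first-class synthetic-data module that emulates the
study's design closely enough that every downstream stage is testable,
including parameter recovery of planted effects.

## The synthetic cohort

`generateCohort()` draws 100 women in four parity strata (26 nulliparous, 23
with 1-2 pregnancies, 27 with 3-4, 24 with more than 4), with 0/22/21/18 per
stratum providing a second sample 1-16 years after the first — 161 samples
from 100 women, 61 repeat donors (82% of the 74 parous women). Stratum-level
age, BMI, menarche, tobacco and hormone-use distributions default to the
emulated cohort's summary statistics (nulliparous women are on average two
decades older and born earlier — a deliberate confounding structure that the
models must handle, not a bug). Parous women are sampled within 2 years of
their last pregnancy, mirroring the selection criterion. Samples fall in
calendar years 1987-2006 and are partitioned into 5 injection batches by
sampling-year order, with 2 procedural blanks and pooled-QC injections per
batch.

Concentrations follow a log-normal generative law:
$\log C_{ij} = \beta_0 + \mathbf{x}_{ij}^\top \boldsymbol\beta + b_i +
\varepsilon_{ij}$, with subject intercept $b_i \sim N(0, \sigma_b^2)$ and
residual $\varepsilon_{ij} \sim N(0, \sigma_e^2)$. Linear effects on the log
scale reproduce the left-skewed raw distributions that motivate the
square-root transform; exact $\sqrt{}$-normality is not forced. Censoring is
deterministic — values below MLOQ/3 are `nondetect`, values in
[MLOQ/3, MLOQ) are `below_mloq` — because the study protocol does not
describe detection noise and a deterministic rule keeps tests exact.

What the generator does **not** emulate: raw spectra, chromatographic peak
shapes, matrix effects, batch-specific calibration drift beyond a
multiplicative per-batch factor, breastfeeding behaviour, or the timing of
pregnancies between visits (the last two are exposed as free parameters
without any claim of fidelity). Passing tests therefore demonstrate that the
*computational rules* are implemented correctly and that the models recover
planted effects under the stated generative law — not that the pipeline
would reproduce any particular real-data coefficient.

## Targeted quantification

- `fitCalibration()` fits ordinary least squares of response ratio
  (analyte area / internal-standard area) on nominal concentration; the
  validated method uses 9 points over 0.01-100 ng/mL. Per batch, three curve
  injections are averaged per level before one fit
  (`fitCalibrationBatch()`); drift correction beyond that averaging is not
  modeled.
- `quantifyPeak()` inverts the line. Values above the range high are
  retained and flagged `extrapolated` (linear extrapolation, as applied to
  the six above-range analytes). Boundary conventions are inclusive — a
  value exactly at MLOQ is quantified, exactly at the range high is
  in-range — chosen as the least-surprise default.
- `substituteCensored()` replaces `below_mloq` by MLOQ/2 and `nondetect` by
  MLOQ/4; the operation is idempotent.
- `sumIsomers()` adds chromatographically resolved branched and linear PFAS
  isomers into total concentrations (e.g. total PFOS); censored cells enter
  at their substituted values.
- `selectTargets()` applies the 60% detection-frequency rule with an
  inclusive boundary. The protocol phrase "combined detection frequency
  (i.e. MLOQ/4 and MLOQ/2)" is ambiguous; the default reading counts a
  sample as detected when its value did **not** need substitution
  (quantified or extrapolated), with the alternative reading (anything
  above MLOQ/4, i.e. at least detected) available via `dfMode =
  "substituted"`. Analytes of special interest (cotinine, progesterone by
  default) can be forced in despite falling below the cut-off.

## Untargeted feature processing

The cleaning order is fixed and logged, and every removal is recorded in a
provenance log so the funnel reconciles exactly:

1. **Blank-ratio filter** (per mode): keep features with sample maximum /
   blank average > 5; a blank average of zero keeps any detected feature.
2. **ESI merge**: neutral mass $M = m/z \mp 1.007276$ for \[M+H\]+ / \[M-H\]-;
   cross-mode pairs within 0.002 Da and 0.2 min collapse to the member with
   the higher average sample area.
3. **IS-PCA normalization**: the log internal-standard matrix is
   sample-centered and decomposed by PCA; each feature's log areas are
   regressed on the first 2 score dimensions and the fitted drift (centered,
   so geometric means are preserved) is removed. With zero components or a
   zero-variance IS matrix this is the identity. The regression-on-scores
   formulation is used because the upstream method's exact formula is not
   public; a planted x2 batch drift is removed to below 5% residual in the
   test suite.
4. **Blank subtraction with floor**: blank average + 0.1 pseudo-count in the
   denominator; cells below 5x the blank average are zeroed; the blank
   average is subtracted from survivors; anything below 90,000 area units is
   zeroed. Blank columns are consumed (dropped) by this stage, which is what
   makes re-running the stage on its own output a no-op.
5. **Correlated dedup**: pairs with Pearson r > 0.95 (p < 0.001, t
   distribution with n-2 df, computed over shared nonzero samples) eluting
   within 0.1 min collapse to the higher-average-area member, swept in
   descending-area order with lexicographic tie-break so the survivor set is
   deterministic. Pairs with fewer than 3 co-detections are skipped and
   logged. The protocol's visual peak-shape inspection is replaced by these
   quantitative gates alone (peak profiles are not in the export).
6. **Detection-frequency filter**: DF = fraction of study samples with
   nonzero area; features with DF below 70% are dropped (inclusive
   boundary).

Both pairwise stages (merge, dedup) are verified against exhaustive
O(n²) brute-force oracles in the test suite.

## Annotation

`spectralScores()` bins fragment peaks at 0.01 Da, applies square-root
intensity weighting (common practice; switchable off), and returns cosine
("dot") and reference-restricted cosine ("reverse dot") similarities on the
0-1000 scale. The upstream software's proprietary total score is
approximated as the mean of dot and reverse dot; thresholds are kept at the
printed values (total > 700 with dot or reverse dot > 600, strict
inequalities). `assignLevel()` gives Level 2 for a passing library match and
upgrades to Level 1 when the matched entry is an in-house standard whose
retention time agrees within 0.2 min (the protocol states no RT tolerance;
0.2 min matches the cross-mode merge tolerance). Only the best-scoring hit
is considered. `classifyFeature()` takes the environmental/endogenous class
from library metadata and labels disagreeing sources `ambiguous`.

## Association models

Chemical levels are square-root transformed, PFAS co-exposure groups are
summed on the transformed scale (Group 1: PFDA, PFNA, PFUnDA; Group 2:
FOSA, FOSAA, NEtFOSAA; Group 3: PFOS, PFHpS, PFOA, PFHxS — declared lists,
since the original grouping came from visual inspection of a correlation
matrix), and each outcome is modeled by REML linear mixed models with a
subject random intercept. Adjustment sets are exposure-specific: age models
adjust for BMI, pregnancies, sample year, menarche and tobacco; parity
models for age, birth year, menarche and tobacco; menarche models for age,
BMI and birth year. Tobacco is coded ever/never combining smoking and snuff.
Missing covariates are handled by per-model complete-case deletion.

P-values use the Wald normal approximation by default; a Satterthwaite
option (via lmerTest) is provided and agrees closely at this scale (161
samples, ~100 subjects) — the test suite asserts the difference is below
0.02 on a planted-effect fit. Collinear fixed-effect designs are flagged
non-converged and excluded from multiplicity counts rather than silently
reduced. With fewer than two subjects contributing repeated measures the
model degenerates to OLS with a warning.

Multiplicity is controlled in three nested tiers: nominal alpha 0.05 (used
alone for the 20 targeted analytes), a fixed 0.005 threshold, and Bonferroni
alpha / n_tests. For the study-scale feature-wide analysis (228 annotated +
16,530 unannotated features), the Bonferroni cut-off is
0.05 / 16,758 = 3.0e-6.

The parous-only sensitivity analysis subsets on reported pregnancies >= 1 by
default; the protocol does not state whether pregnancies or deliveries were
used, so `by = "n_deliveries"` is available.

## Numerical and design choices

- Proton mass 1.007276 Da (not stated upstream; any plausible value is
  far inside the 0.002 Da merge tolerance).
- Master seed with derived per-stage child seeds (`childSeed()`), so any
  stage can be regenerated in isolation and a fixed config is bit-for-bit
  reproducible.
- Problem sizes in the test suite and acceptance script: cohorts at the
  emulated study scale (100 women / 161 samples), feature tables of a few
  hundred features per mode, 500 replicate cohorts for parameter-recovery
  and coverage checks, 1000 replicates for the null rejection rate. These
  sizes give Monte-Carlo errors comfortably inside the asserted bands while
  keeping a full run in minutes on one core.
- Empirically calibrated checks asserted by the suite: mean recovered age
  coefficient within 2 Monte-Carlo SEs of the planted 0.01; 95% Wald
  interval coverage within [0.92, 0.98]; null rejection rate within
  [0.03, 0.07].

## Known limitations

- The generator plants area-level structure only; no adduct networks beyond
  the single \[M+H\]+/\[M-H\]- pairing, no cross-batch RT drift (alignment
  is assumed done upstream).
- Reference standardization of steroid hormones is simplified to
  multiplicative pooled-QC scaling; the original protocol is not reproduced.
- Untargeted intensities are comparable within a feature across samples, not
  between features — group sums and volcano tables respect this, but any
  cross-feature interpretation is out of scope.
- Real-data coefficients are not reproducible here by design (restricted
  data); the package validates method implementation, not epidemiology.
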