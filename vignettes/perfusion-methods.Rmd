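---
title: "Methods: infarct perfusion readout from pCASL and the no-reflow classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: infarct perfusion readout from pCASL and the no-reflow classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aslperf)
```

## The quantification model

pCASL magnetically labels arterial blood water below the imaging volume;
after a post-label delay (PLD) the labeled bolus has perfused the tissue and
the control-minus-label difference signal ΔM is proportional to cerebral
blood flow. `quantify_cbf()` applies the consensus single-compartment model
voxelwise:

$$\mathrm{CBF} = \frac{6000\,\lambda\,\Delta M\,e^{\mathrm{PLD}/T_{1b}}}
  {2\,\alpha\,T_{1b}\,M_0\,(1 - e^{-\tau/T_{1b}})}
  \quad [\mathrm{ml}/100\,\mathrm{g}/\mathrm{min}]$$

The model assumes the whole labeled bolus has arrived (PLD longer than the
arterial transit time), no label outflow, and relaxation of the label with
the T1 of blood. The parameters, their defaults and units:

| parameter | meaning | default | unit |
|---|---|---|---|
| τ (`label_duration_s`) | labeling pulse-train duration | 1.8 | s |
| PLD (`post_label_delay_s`) | post-label delay | 2.0 | s |
| α (`labeling_efficiency`) | labeling efficiency for pCASL | 0.85 | — |
| λ (`partition_coefficient`) | blood–brain partition coefficient | 0.9 | ml/g |
| T1b (`blood_t1_s`) | arterial blood T1 at 3 T | 1.65 | s |

τ and PLD come from the acquisition protocol this pipeline targets; α, λ and
T1b are the consensus recommendation values for pCASL at 3 T. They are
deliberately config-overridable, and every value in force is echoed into the
provenance sidecar by `run_subject()`, because quantification constants are a
common source of silent between-site differences. (The 3 T FLAIR inversion
time of 1650 ms that appears in typical protocols is numerically equal to
the T1b default but unrelated; the default's provenance is the ASL
recommendation, which is why it is logged.) Voxels with non-positive M0
cannot be calibrated; they become `NA`, are excluded from all masked means,
and are counted (a region that is > 20% missing triggers a warning).

Two processing steps common in ASL pipelines are intentionally absent:
motion correction / co-registration (inputs are required to be pre-aligned;
this is orthogonal to the statistic and is done by standard tools) and
outlier rejection of control/label pairs before averaging
(`average_difference()` is a plain voxelwise mean; a rejection hook would
sit in front of it).

## The mirrored-mask %CBF difference

Absolute ASL CBF is highly variable between subjects, so the per-subject
statistic is relative: the infarct mask (with any visible bleeding removed),
restricted to gray matter, is averaged; the same mask is mirrored across the
grid mid-plane onto the unaffected hemisphere, restricted to gray matter and
averaged; and

$$\%\mathrm{CBF\ difference} = 100 \times
  \frac{\mathrm{CBF}_{\mathrm{infarct}} - \mathrm{CBF}_{\mathrm{mirrored}}}
       {\mathrm{CBF}_{\mathrm{mirrored}}}$$

Design choices that the field's wording leaves open, fixed here:

- **Central statistic.** The mean over each region (median available via
  `statistic = "median"`). The choice is reported in the provenance log.
- **GM threshold is inclusive.** A voxel enters the GM mask when its
  probability is ≥ 0.6. GM restriction limits intravascular spill-over from
  sulcal vessels and low white-matter ASL signal.
- **Mirroring is a pure grid reflection** about the voxel mid-plane of the
  declared left-right axis (index i → N − 1 − i, 0-based; the central slice
  of an odd-extent axis maps onto itself). Anatomical mid-sagittal
  estimation is out of scope, so inputs must be approximately
  grid-symmetric; the phantom guarantees exact symmetry.
- **The mirrored mask is the hematoma-excluded mask.** Exclusion happens
  before mirroring, so both sides read the same geometry.
- **Minimum region size.** Either side with fewer than 10 readout voxels
  (configurable) raises an error naming the side, rather than returning an
  unstable mean. A mirrored-side mean ≤ 0 raises an undefined-statistic
  error, since the ratio loses meaning.
- **Volume convention.** Infarct volume is voxel count × voxel volume on the
  hematoma-excluded mask. When the acquisition has an interslice gap the
  effective slice pitch (thickness + gap) is used — declared once on the
  `volume_grid`, e.g. 3 × 3 × (5.5 + 0.55) mm.

## The no-reflow classifier

`classify_noreflow()` is the conjunction of three criteria: eTICI grade in
{2c, 3} (near-complete/complete recanalization), %CBF difference strictly
below −15, and hypoperfusion in at least 50% (inclusive) of the infarct
territory. The boundary semantics are exactly as printed and are unit-tested
at the boundaries.

The third criterion is, in the clinical setting, a visual rater judgment.
This package replaces it with a declared voxelwise rule,
`hypoperfused_fraction()`: the fraction of infarct-GM voxels whose CBF is
below (1 − 0.15) × the CBF of the mirrored homologous voxel. The 15%
relative deficit mirrors the whole-infarct asymmetry threshold; it is
configurable and reported next to the result, and every output carries an
`operationalized` flag so downstream users know a rule, not a rater,
produced it. Concordance with visual ratings on real data is not guaranteed
and is not claimed.

## Cohort statistics

- **Descriptives** are median and IQR; quartiles use the linear-interpolation
  rule (`quantile()` type 7).
- **Group comparisons** dispatch by declared type: continuous and ordinal
  variables to the Mann–Whitney U test, binary variables to Fisher's exact
  test on the 2 × 2 crosstab. Display values round to the nearest full digit
  and p-values to three decimals, while full precision is kept internally.
- **Mann–Whitney** uses midranks. For total n ≤ 12 the p-value is exact: the
  permutation distribution of the rank sum (ties preserved) is built by
  dynamic programming, and the two-sided p is twice the smaller tail, capped
  at 1. Larger samples use the tie-corrected normal approximation without
  continuity correction (both are config flags). The exact branch is
  verified in the tests against brute-force enumeration of all label
  assignments.
- **Fisher's exact** uses the probability-ordering two-sided rule (sum of
  all hypergeometric table probabilities ≤ the observed one), computed via
  `stats::fisher.test()` and verified against an independent hypergeometric
  enumeration oracle in the tests. A zero margin returns p = 1 with a
  warning.
- **Stepwise-forward logistic regression** mimics the defaults of the
  clinical statistics packages: at each step the candidate with the smallest
  Rao score-test p enters if p < 0.05 (`entry_p`); after each entry any
  included variable with likelihood-ratio p > 0.10 (`removal_p`) is removed.
  Fits are binomial IRLS run well past the 1e-8 relative-likelihood
  criterion (glm epsilon 1e-12, max 100 iterations), which also drives the
  score-test gradient at the optimum below 1e-6 on the synthetic fits.
  Final-model effects are Wald odds ratios with 95% CIs; candidates never
  selected are reported with their final score-test p only and no odds
  ratio. Non-convergence and quasi-separation (divergent coefficient or
  exploding standard error together with saturated fitted probabilities)
  raise errors naming the offending variable. With `entry_p = removal_p = 1`
  the procedure reduces to the full-model fit, which the tests exploit.
- **mRS conventions.** `mrs_90d = 6` encodes death; functional independence
  is mRS ≤ 2 at 90 days and is kept consistent with `mrs_90d` by
  construction in the generator.

## What the synthetic generators emulate

The phantom exists to give every downstream stage a known ground truth:

- `generate_anatomy()` builds an ellipsoidal brain and a cortical-band GM
  probability map that are *exactly* mirror-symmetric about the grid
  mid-plane, with a unilateral lesion (nearest-voxel growth around a
  jittered lateral seed point) confined strictly to one hemisphere, and an
  optional hematoma nested in the lesion core. Exact symmetry makes the
  mirrored readout exact by construction, isolating the statistic from
  registration error.
- `generate_perfusion()` is piecewise constant — baseline CBF in GM, 40% of
  baseline elsewhere in brain, the infarct scaled by `infarct_ratio` — so
  noise-free masked means are exact: the statistic equals
  100 × (ratio − 1) identically, which the tests assert for ratios 0.5
  through 1.5. Noise is additive Gaussian within the brain. Default noise
  levels (sd 2 at baseline 50) are chosen for testability; per-subject CBF
  distributions of real cohorts are not modeled.
- `generate_asl_series()` is the exact algebraic inverse of the
  quantification equation at zero noise (round-trip relative error < 1e-9),
  with independent per-volume Gaussian signal noise otherwise, so averaging
  more control/label pairs shrinks quantification error as 1/√n.
- `generate_cohort()` draws covariates independently with shapes typical of
  a post-thrombectomy cohort (age ~ clipped N(73, 14²); infarct volume ~
  lognormal around a 51 ml median, clipped at 400 ml; %CBF difference ~
  N(16, 40²); pre-stroke mRS skewed to 0; eTICI 2c/3 in 78%; platelet
  inhibitors in 27%; hemorrhagic-transformation classes at their cohort
  frequencies), and draws the functional-independence outcome from a
  logistic model whose default coefficients are the natural logs of odds
  ratios around 1.013 (per %CBF point), 0.991 (per ml) and 0.286 (per
  pre-stroke mRS point), with intercept 1.4. Because only these three
  covariates enter the generative logit, all others are true nulls — which
  is what the stepwise-selection recovery and type-I-error suites rely on.

What passing tests on these phantoms do **not** show: robustness to
registration error, brain asymmetry from mass effect and edema, arterial
transit delays beyond the single-PLD model, rater behavior, or correlated
clinical covariates. The generators are a correctness harness, not a realism
claim; in particular the synthetic no-reflow prevalence follows from the
covariate model rather than being calibrated to a clinical rate.

## Problem sizes and seeds

The test and acceptance suites run on 16 × 16 × 8 (readout) and 16³
(round-trip) grids, 100 phantom noise realizations, and stepwise recovery on
100 cohorts of n = 2000 plus 200 null cohorts of n = 1000 — sizes at which
the Monte-Carlo checks are well-powered while the whole suite stays fast.
One fixed default seed (20201001) is recorded in every generator signature;
the acceptance script derives all its sub-seeds from its `--seed` argument.
For the null-model check on stepwise selection, the per-candidate entry rate
at 200 replicates has a binomial standard error of 1.5 percentage points, so
the nominal-level assertion (5% ± 2%) is applied to the entry rate pooled
over the seven null candidates (standard error 0.6 points), with a wide
4-standard-error guard per candidate.

## Known limitations

- Single-PLD quantification: no arterial-transit-time or multi-delay
  support; late-arriving collateral flow biases CBF low.
- Grid-reflection mirroring requires approximately symmetric brains; severe
  midline shift violates the precondition and is not detected
  automatically.
- No partial-volume correction; GM thresholding at 0.6 is a hard cut.
- The stepwise entry/removal thresholds are conventions, not estimands;
  sensitivity to them is the user's to explore (`entry_p`, `removal_p`).
- Fisher's two-sided rule is the probability-ordering convention; other
  software occasionally reports tail-doubling or mid-p values, which differ
  in the third decimal and sometimes more.
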