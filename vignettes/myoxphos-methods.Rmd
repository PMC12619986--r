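---
title: "Models and methods in myoxphos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in myoxphos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoxphos)
```

myoxphos implements the quantitative chain used in exercise-intervention
studies of mitochondrial function in dystrophic skeletal muscle: per-fiber
OXPHOS phenotyping by prediction-interval regression, resampling-based
inference on pre/post changes, per-state analysis of respirometry and H2O2
fluorimetry traces, immunoblot normalization into an OXPHOS protein content
index, histological integrity proportions, and the cohort-level statistical
plan. This vignette explains each model, its assumptions, the tunable
parameters and the numerical conventions, and states what the packaged
synthetic data do and do not demonstrate.

## 1. Prediction-interval fiber phenotyping

A muscle fiber's OXPHOS subunit signal scales with its mitochondrial
content, so deficiency must be judged *relative to mitochondrial mass*, not
in absolute terms. `fit_pi_model()` regresses the log2 subunit intensity
(NDUFB8 for Complex I, MT-CO1 for Complex IV) on the log2 VDAC1 intensity
over all pooled unaffected control fibers, and stores the full geometry of
the two-sided 95% prediction interval for a *new* observation:

$$\hat y(x) \pm t_{0.975,\,n-2}\; s\,\sqrt{1 + \tfrac1n +
\tfrac{(x-\bar x)^2}{S_{xx}}}$$

`classify_fibers()` then labels fibers of affected muscle `low` (below the
band: deficient), `high` (above: overabundant) or `normal`. Design choices:

- **log2 transform (default).** Fluorescence intensities are strictly
  positive with multiplicative section-to-section variation; on log scale
  the control relationship is close to linear with roughly constant
  residual spread, and classification becomes invariant to any common
  positive rescaling of the raw intensities. `transform = "none"` is
  available for pipelines that already deliver variance-stabilized values.
- **Pooled controls.** One model per channel is fitted on all unaffected
  fibers pooled across control participants, and the *same* model is used
  for a participant's PRE and POST sections, so pre/post deltas are never
  confounded by refitting. (`delta_proportions()` refuses proportions that
  come from different model fits.)
- **Boundary ties go to `normal`.** A fiber exactly on a bound is not
  called deficient; this minimizes false deficiency calls.
- **QC, not imputation.** Fibers with non-positive or missing intensities
  are excluded and counted (`n_flagged`), never imputed.

On held-out fibers drawn from the control population the normal-call rate
is the nominal 95% up to binomial error plus a small model-conditioning
term that shrinks as $1/\sqrt{n_\text{control}}$; the test suite checks
this at $n = 10{,}000$ against a $\pm 0.7$ percentage-point band.

## 2. Uncertainty for Δfibers: bootstrap, permutation, FDR

Per participant and channel the quantities of interest are
$\Delta^{high} = p^{high}_{post} - p^{high}_{pre}$ and
$\Delta^{low} = p^{low}_{post} - p^{low}_{pre}$.

- **Bootstrap (`bootstrap_delta`).** Fibers are resampled with replacement
  independently within PRE and within POST; since classes are fixed by the
  shared model, a replicate reduces to a multinomial draw on the class
  counts, which is what the implementation draws (exactly equivalent,
  vectorized). 95% percentile intervals are reported; B = 1000 by default.
- **Permutation (`permutation_test_delta`).** The null pools the
  participant's PRE and POST fibers and re-splits them at random into
  groups of the original sizes. For one class, the count landing in the
  post group is hypergeometric, so the null is sampled exactly from that
  law per class. Two-sided p-values use the add-one rule
  $p = (1 + \#\{|\Delta^*| \ge |\hat\Delta|\})/(n_{perm}+1)$, with tie
  comparisons on integer-scaled deltas, so $p \in (0, 1]$ always and a
  degenerate pool gives $p = 1$. This pooled re-split null is a documented
  stand-in — the output carries `null = "pooled_resplit"` — since no
  algorithmic specification of the original analysis code is available.
  999 permutations by default.
- **FDR (`fdr_adjust`).** Benjamini–Hochberg step-up over the whole run
  family (participants × channels × directions), chosen as the standard
  FDR procedure.
- **Call rule (`call_significance`).** `high` is a significant increase
  iff $\Delta^{high} > 0$ and $p < 0.05$; `low` a significant decrease iff
  $\Delta^{low} < 0$ and $p < 0.05$; a significant change in the opposite
  direction is reported as a `significant_negative_change`.

The resampling unit is the fiber; participant-level resampling and
mixed-effects modelling of within-section correlation are out of scope, so
p-values are conditional on the observed sections.

## 3. Respirometry and fluorimetry

`extract_state_rates()` turns an event-annotated trace into per-state rates.
Each titration event (GM = glutamate+malate, state II; +ADP, state III;
+SUCC; +OLI; +AA) opens a state; the steady-state window is the **last 60 s
before the next event** after discarding a **60 s settle time** following
the addition (both configurable). This fixed trailing window is a
deterministic stand-in for plateau-detection heuristics in instrument
software, whose logic is not published; an over-short state is QC-flagged
(`short_state`) rather than dropped. Unit conventions are centralized:

$$J_{O_2} = -\,\text{slope}(O_2)\cdot \frac{V_{chamber}}{m_{wet}} \cdot 60
\quad [\text{nmol } O_2\,\text{min}^{-1}\,\text{mg}^{-1}]$$

H2O2 emission uses the identical window with a daily linear calibration
(`fit_calibration`): rate = (fluorescence slope / gain) scaled the same
way, in pmol min⁻¹ mg⁻¹. Derived quantities:

- **ACR** = state III / state II flux (coupling efficiency); undefined and
  flagged when state II ≤ 0.
- **Free radical leak** = H2O2 rate / O2 rate in the GM+ADP+SUCC state,
  reported as a plain pmol/nmol ratio by default because unit conventions
  differ between laboratories; `mode = "electron_pair_percent"` gives
  $100 \cdot \text{H}_2\text{O}_2 / (2 \cdot \text{O}_2)$ in common molar
  units.
- **Antimycin-A correction** (`aa_correct`) subtracts residual
  non-mitochondrial consumption from the other states; default **off**,
  because the AA state is normally reported as its own condition and no
  correction is assumed.
- **Duplicates** are combined by the per-state arithmetic mean
  (`average_duplicates`), with a QC flag when replicates disagree by more
  than 20% — the combiner for technical duplicates is a package choice.
- Baseline drift of the fluorescence channel beyond the linear calibration
  offset is not modelled or corrected.

## 4. Densitometry

`lane_normalize()` divides each subunit optical density by the lane's
stain-free total-protein signal (loading control);
`fold_change_vs_unaffected()` scales each subunit by the unaffected-group
mean, which maps that group to fold change 1 exactly; `oxphos_index()` is
the per-lane **sum of the five fold changes** (NDUFB8, SDHB, UQCRC2,
MT-CO1, ATP5A), so the unaffected group's expected index is 5. Summing on
the fold-change scale weights the five complexes equally regardless of
antibody brightness; whether an index is summed on fold-change or raw
normalized scale is ambiguous in common practice, so the fold-change
reading is the documented default (compute the sum on your own scale
otherwise). Lanes with a missing band give an `NA` index with a warning —
no imputation.

## 5. Histology and cohort statistics

`marker_proportion()` reports percentages with a `low_n` flag below 100
evaluable fibers (flagged, not dropped). `csa_contrast()` is
$100\,(\bar{CSA}_{+} - \bar{CSA}_{-})/\bar{CSA}_{-}$;
`ncam_csa_analysis()` aggregates fibers within participant first, then
applies the Wilcoxon matched-pairs signed-rank test across participants.

`cohort_summarize()` uses the sample SD (n−1) and excludes missing values
listwise, flagging singleton columns instead of erroring.
`compare_independent()`/`compare_paired()` wrap the base-R Mann–Whitney and
Wilcoxon signed-rank tests (exact for small untied samples); all-zero
paired differences return $p = 1$ by convention. Because the exact-versus-
approximate conventions of commercial statistics software are unknown,
small-sample p-values are validated against enumeration oracles in the test
suite, not against published p-values. `two_way_anova_sidak()` runs the
group × state ANOVA (with a subject error stratum for the repeated case,
requiring a complete balanced design) and Šídák-adjusts the per-state
pairwise t-tests, $p_{adj} = 1-(1-p)^k$; results with $0.05 \le p < 0.1$
are labelled trends by the reporting helpers.

The packaged `cohort_fixture()` carries the published per-participant
baseline rows; missing entries are explicit `NA`s excluded from every
summary. One printed summary cell (the DM1 CTG SD) is internally
inconsistent with its own per-participant values by one unit in the last
digit (203.49 computes vs 204 shown); the tests assert the recomputed
value.

## 6. The synthetic-data generators

The generators produce every input the pipeline consumes, with the
statistical structure the analysis assumes, under one seed (bit-identical
reruns; each public generator takes its own seed so streams are
independently regenerable).

- **Fiber populations** (`generate_fiber_population`): log2 VDAC1 is
  Gaussian (location 10, scale 0.6 — arbitrary camera units); log2 subunit
  = intercept + slope·mass + N(0, resid_sd = 0.25) with the deficient /
  overabundant classes shifted by fixed log2 offsets. Exactly
  `round(frac·n)` fibers per class, with the truth kept in `true_class`.
  The intensity distribution family of real QIF data is not published;
  log-normality is this package's assumption, stated, not asserted of any
  real dataset. Note the **fixed class counts**: they remove the
  between-sample sampling variability an iid draw would have, so percentile
  bootstrap CIs computed on such populations over-cover (the CI-calibration
  study reports coverage near 100% against its ≥90% requirement), and
  permutation type-I studies must draw classes iid instead (the acceptance
  script does).
- **Traces** (`generate_trace`): piecewise-linear O2 and fluorescence with
  per-state slopes given by the closed forms of section 3, additive
  Gaussian noise, default 2 s sampling, 300 s states, 2 mL chamber, 3–6 mg
  bundles, and an initial O2 of 600 nmol/mL (hyper-oxygenated chamber, as
  used for permeabilized fibers so diffusion is not limiting). No
  re-oxygenation events, probe consumption, drift or O2-solubility
  corrections are modelled.
- **Calibration series** (`generate_calibration_series`): exact line plus
  noise; 8 additions at 1% noise recover the gain to well under 1% (median
  over seeds).
- **Histology** (`generate_histology_table`): independent Bernoulli flags
  per marker; log-normal CSA (mean 4500 μm², SD 1500 μm²) with NCAM+
  fibers scaled by 0.822, emulating the −17.8% denervation-atrophy
  contrast observed in baseline DM1 muscle.
- **Bioenergetics cohort** (`generate_bioenergetics_cohort`): group-level
  true rates encode the study's effect directions — DM1-PRE respiration at
  60% of unaffected across states, partially restored to 80% after
  training; absolute H2O2 emission lower in DM1; free radical leak in the
  GM+ADP+SUCC state 0.60 (PRE) vs 0.48 (unaffected) vs 0.45 (POST)
  pmol/nmol. Between-participant variation is a shared log-normal
  "content" factor (CV 15%) scaling both channels — which cancels in the
  leak ratio, exactly why that ratio is used — plus channel-specific
  intrinsic factors (CV 5%) that do move the leak, and paired visit
  factors (CV 5%) linking each DM1 participant's PRE and POST runs.
  Magnitudes (state III CI+II ≈ 25 nmol O2 min⁻¹ mg⁻¹ wet mass in
  controls) are plausible for permeabilized human *vastus lateralis*
  bundles at 37 °C.

**What passing tests show — and don't.** The synthetic data share the
pipeline's assumed structure by construction (linearity on log scale,
piecewise-steady states, linear calibration, independent Bernoulli flags).
Green tests therefore demonstrate correctness of the estimators and their
calibration *under these conditions*; they cannot demonstrate robustness to
real-data pathologies — segmentation errors, spatially correlated fibers
within sections, nonlinear probe behaviour, chamber leaks, or batch effects
between staining rounds.

## 7. Numerical conventions and problem sizes

Tie-breaks: boundary fibers are `normal`; permutation ties are compared on
integer-scaled deltas; all-zero paired differences give p = 1. Degenerate
inputs (zero mass-signal spread, fewer than 3 controls, < 2 calibration
levels, non-positive OXPHOS index, empty groups) are rejected with explicit
messages; too-short respirometry states and sub-100-fiber histology samples
are flagged, not dropped. Seeds: every stochastic function takes a `seed`
and restores the caller's RNG state; `delta_test()` derives independent
bootstrap and permutation sub-streams from its single seed.

The default study sizes used throughout the tests and the acceptance script
— 10,000-fiber coverage checks, 200-replicate CI-calibration studies at 500
fibers per timepoint with B = 1000 and 999 permutations, 1000-simulation
type-I studies, 500-seed calibration recovery, nine participants per group
— were chosen so the full suite characterizes calibration properties to
useful precision while running in well under a minute on a laptop; all are
parameters, not constants.
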