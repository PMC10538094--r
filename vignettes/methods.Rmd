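---
title: "Models and methods behind ncakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ncakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncakit)
```

`ncakit` covers the quantitative stage of a targeted LC–MS/MS serum assay:
calibration and method validation, noncompartmental analysis (NCA), and a
synthetic-data generator that emulates a single-dose oral study so the whole
pipeline can be exercised and tested without clinical samples. This vignette
is the package's own account of the models, the tunable parameters, the
numerical choices, and what the synthetic data can and cannot show.

## The generative model

Serum concentrations are simulated from a one-compartment model with
first-order absorption, first-order elimination and an absorption lag:

$$C(t) = \frac{D\,k_a}{V\,(k_a - k_{el})}
  \left(e^{-k_{el}(t - t_{lag})} - e^{-k_a(t - t_{lag})}\right),
  \quad t > t_{lag},$$

and $C(t) = 0$ otherwise, with the dose $D$ in ng (mg × 10⁶) and the
apparent volume $V$ in mL (L × 10³), so $C$ is in ng/mL. This is the
simplest structural model consistent with a single-peak oral profile; the
NCA layer never assumes it — it only supplies ground truth for
parameter-recovery tests. The degenerate case $k_a = k_{el}$ (the
"flip-flop" limiting form) is rejected rather than special-cased.

Closed forms used as test oracles: the peak is at
$t^* = \ln(k_a/k_{el})/(k_a - k_{el}) + t_{lag}$ and the total exposure is
$AUC_{0-\infty} = D/(V\,k_{el})$, independent of $k_a$ and $t_{lag}$.

### Default parameters and why

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| `dose` | 100 | mg | single oral dose of the emulated study design |
| `kel` | ln2/3.93 ≈ 0.176 | 1/h | typical terminal half-life of ~3.9 h |
| `vd_over_f` | 1500 | L | typical apparent volume of ~1.5 kL |
| `ka` | 3.0 | 1/h | places the noise-free peak at ≈1.1 h post dose |
| `tlag` | 0.1 | h | short absorption delay for an oral capsule |
| `schedule` | 0, 0.5, 1, 1.5, 2, 3, 5, 8, 24 | h | predose sample plus the study's serial sampling times |
| `n_subjects` | 10 | — | analysed arm size |
| `lloq` | 7.5 | ng/mL | lowest calibration level; anchors BLQ censoring |
| `iiv_cv` | 0.4 (ka, kel, vd_over_f) | fraction | consistent with the large between-subject SDs typical of oral small-molecule PK (derived-parameter CVs of 0.5–0.75) |
| `assay_cv` | 0.05 | fraction | replicate-injection RSDs are below 1%, but run-to-run analytical plus processing error is larger; 5% is a realistic total |
| `tlag_halfwidth` | 0.1 | h | lag varied uniformly on a small interval |

Inter-individual variability is log-normal on `ka`, `kel` and `vd_over_f`
— the standard pharmacometric convention for strictly positive
parameters — and is parameterised so that the **mean** of each parameter
equals its typical value (`meanlog = log(typical) − sdlog²/2`,
`sdlog² = log(1 + CV²)`). That choice makes moment-based recovery tests
exact: the sample mean of a simulated parameter converges to the typical
value. Measurement error is proportional (constant CV), because observed
assay RSDs are concentration-independent; negative noisy values are
truncated at zero before censoring.

The predose sample is generated as exactly 0 and flagged BLQ. Censoring
replaces any value strictly below the LLOQ with `NA` plus a BLQ flag; it is
idempotent and monotone in the limit, and both properties are tested.

Calibration batches are simulated as `response = slope·x + intercept + ε`
with `sd(ε) = noise_cv · slope · x`. Response SD proportional to
concentration is exactly the variance structure under which 1/x weighting
(more precisely 1/x² for strict inverse-variance weighting; 1/x is the
assay-field compromise) outperforms ordinary least squares at the low end
of the range.

### What the generator does not emulate

No chromatographic peak shapes, integration or matrix effects (responses
are modeled directly as area ratios); no multi-compartment or
enterohepatic kinetics; no dropout, dosing-time errors or
below-LOD-but-above-blank structure. Passing tests therefore demonstrate
correctness of the *computations* under the stated statistical assumptions,
not robustness to every feature of real bioanalytical data.

## Calibration and validation

`fit_calibration()` minimises the weighted objective with
`stats::lm(weights =)`, weighting 1, 1/x or 1/x² (x = nominal
concentration). The coefficient of determination under weighting is not
uniquely defined; the package computes it on the **weighted** regression
(weighted residual and total sums of squares about the weighted mean) and
reports the unweighted r² alongside for transparency. Duplicate standards
are both retained in the fit, never averaged. Back-calculation inverts the
line; sub-blank responses give negative concentrations that are flagged but
not truncated, so QC statistics remain unbiased.

Acceptance rules are closed intervals: LOQ accuracy 80–120% and RSD ≤ 20%
(warning when claimed on fewer than 7 replicates), ±15% back-calculation
for non-LOQ standards and stability samples. "Within" is read as inclusive;
a sample sitting exactly on a bound passes.

`lod_loq_from_sn()` assumes signal-to-noise proportional to concentration
through the origin, so a single reference (concentration, S/N) pair fixes
LOD (S/N 3) and LOQ (S/N 10) with ratio 10/3. This is a deliberate
simplification: deriving limits from chromatogram noise is out of scope.

## Noncompartmental analysis

Per profile, quantifiable means reported and not BLQ.

- **Cmax/Tmax**: observed maximum; ties broken to the earliest time.
- **Lag time**: time of the last BLQ or zero sample preceding the first
  quantifiable sample (0 if the first post-dose sample is quantifiable).
  The estimate is grid-limited: on a sparse schedule a true lag of 0.4 h is
  reported as 0 or 0.5 h, and recovery is verified on a refined grid.
- **λz window**: best-fit selection over every suffix (≥3 points) of the
  post-Tmax quantifiable positive samples, excluding the Cmax point.
  The window maximising the adjusted r² of the log-linear fit wins; windows
  within 10⁻⁹ of the maximum are tied and the longest wins. The tolerance
  exists so that an exactly mono-exponential tail — where all windows tie
  at r² = 1 up to floating-point — selects the full suffix, while on noisy
  data ties essentially never occur. The scan uses a closed-form simple
  regression for speed; its agreement with `stats::lm` and with exhaustive
  enumeration is tested.
- **λz**: negated OLS slope of ln C on t over the window; a non-positive
  estimate (non-decaying tail) is flagged, never silently used.
- **AUC**: linear trapezoid. BLQ handling follows standard NCA convention:
  pre-/at-Tmax BLQ values enter as 0, post-Tmax BLQ samples are excluded.
  The tail is completed with the observed (not λz-predicted) Clast:
  `AUC0-inf = AUC0-t + Clast/λz`; an extrapolated fraction above 20% raises
  a flag. The trapezoidal-rule statement is completed with this standard
  tail term as a design choice.
- **Derived parameters**: `t½ = ln2/λz`;
  `CL/F (L/h) = 1000 · dose(mg) / AUC0-inf (h·ng/mL)` — the mg→ng (10⁶)
  and mL→L (10³) conversions live in this one documented place;
  `Vd/F = CL/F / λz`.
- **Failure semantics**: any per-subject failure (all-BLQ profile, too few
  quantifiable points, no usable terminal phase) becomes a structured
  `nca_error` record; `summarize_population()` excludes such subjects,
  reports per-parameter n, and counts the exclusions. Summaries are
  arithmetic mean ± sample SD (n−1) of the per-subject parameters —
  never ratios of averages, which differ (e.g. dose/mean-AUC is not the
  mean of dose/AUC).

## Numerical and design choices

- Tie-breaks: earliest Tmax; longest tied λz window (tolerance 10⁻⁹).
- Degenerate inputs rejected with informative errors: `ka == kel`,
  non-increasing times, negative concentrations, zero calibration slope,
  single-level calibration designs, fewer than 2 QC replicates.
- Seeds: every stochastic operation takes or records an integer seed;
  identical seeds give bitwise-identical output, and pipeline artifacts are
  stamped with the seed and a config hash.
- Problem sizes in tests and the acceptance script were chosen to give
  stable statistics at desk scale: 1000 seeded repeats for the stochastic
  validation checks, 500 subjects for moment recovery, a 0.1 h grid to
  48 h (about 12 half-lives) for dense-profile recovery.
- The two-arm low-exposure scenario (a second compound dosed at 90 mg whose
  resulting analyte levels are about one-tenth of the first arm's) is
  representable by reducing the effective dose by a conversion fraction
  (default 0.1); it is a labelled heuristic used only to produce an
  almost-everywhere-BLQ arm for guard-rail tests, not a mechanistic model.
- The `io_cli` surface is the package functions plus a thin `optparse`
  wrapper (`inst/cli/ncakit.R`); config files round-trip through YAML or
  JSON with package defaults filled in for omitted fields.

## Known limitations

- The lag-time rule is one of several reasonable conventions; NCA software
  differs, and on sparse schedules the estimate is coarse.
- The best-fit λz window criterion (maximum adjusted r²) can, on noisy
  short tails, select a window whose slope is biased high; flags
  (`lambda_z_unavailable`, `extrapolation_gt_20pct`) surface the cases
  where results rest on few points or long extrapolation.
- Weighted r² is reported as the linearity metric; with 1/x weighting it
  is not comparable across weighting schemes.
- No sparse-sampling (Bailer-type) NCA, bioequivalence statistics,
  compartmental fitting or multiple-dose accumulation.
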