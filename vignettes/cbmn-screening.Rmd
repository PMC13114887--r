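---
title: "Screening radioprotectors with the CBMN assay: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening radioprotectors with the CBMN assay: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbmnscreen)
```

## The problem

The cytokinesis-block micronucleus (CBMN) assay quantifies radiation-induced
chromosomal damage in human lymphocytes: cells are blocked with
cytochalasin B after one nuclear division, and micronuclei (MN) -- acentric
fragments or lagging chromosomes left outside the daughter nuclei -- are
counted in binucleated cells (BC). The damage endpoint is the MN frequency
per 500 BC. Because that frequency rises monotonically with gamma dose, a
calibration curve fitted on untreated irradiated cultures doubles as a
biological dosimeter: an observed frequency can be inverted into the dose
that would have produced it in untreated cells.

`cbmnscreen` packages the analysis side of a radioprotector screen built on
this assay: candidate substances are added to blood cultures immediately
before or after a fixed 2 Gy gamma exposure, and their effect on the MN
frequency is converted into two endpoints,

* **magnitude of protection**,
  \(\mathrm{MP} = 100\,(f_c - f_t)/f_c\), the percent reduction of the
  treated irradiated frequency \(f_t\) relative to the irradiated control
  \(f_c\); and
* **dose reduction factor**,
  \(\mathrm{DRF} = D_{\mathrm{nominal}} / D(f_t)\), where \(D(y)\) is the
  inverse calibration curve, so the DRF says how many-fold the delivered
  dose exceeds the dose whose damage the treated cultures actually express.
  DRF > 1 indicates protection.

## The calibration model

The forward model is a straight line on the frequency scale,
\(y = c_0 + c_1 D\) (MN/500 BC; \(D\) in mGy), fitted by ordinary least
squares (`fit_calibration()`). Its exact inverse,
\(D = a + b\,y\) with \(a = -c_0/c_1\) and \(b = 1/c_1\), is the dosimetry
equation; both parameterisations live in one `mn_calibration` object and
are kept algebraically consistent at all times. A linear-quadratic fit
(`fit_calibration_lq()`), the classical cytogenetic dose-response form, is
available for comparison but is deliberately not used in DRF scoring.

Two sources of curve are supported and kept distinguishable through a
`provenance` field:

* a curve refit from a calibration scoring table, which carries
  diagnostics (\(R^2\), reported also as percent reliability, and the
  residual SD) and supports a seeded percentile bootstrap (2000 resamples
  by default) for dose confidence intervals; and
* a **published** inverse equation supplied directly via
  `from_inverse_coefficients(a, b)`, with diagnostics marked absent.

Screening DRFs are computed against an explicitly supplied curve rather
than a refit of the screening controls. This is a substantive choice: in
the study design this package targets, the observed 2 Gy irradiated control
(26 MN/500 BC) does not lie on the calibration line (the line predicts
about 37.7 MN/500 BC at 2000 mGy), so silently refitting would change every
DRF. For the same reason the DRF numerator is the *nominal delivered dose*
(2000 mGy), not the interpolated dose of the irradiated control; with the
worked frequencies this reading reproduces the published endpoints
(DRF 7.2 pre, 1.8 post, equivalent dose 0.27 Gy), whereas the alternative
numerator (the control's interpolated 1244 mGy) would not.

Frequencies below the curve's zero-dose intercept invert to negative doses.
These are expected in strongly protected samples and are clamped to 0 mGy
with a `clamped` flag and a warning rather than raised as errors; the
corresponding DRF is reported as infinite with a `complete_protection`
flag, never as a large number.

## Display conventions

Internal arithmetic is never rounded. At report time MP is rounded to the
nearest integer percent, DRF to one decimal, and equivalent doses are shown
in Gy *truncated* (not rounded) to two decimals -- truncation is what maps
278.53 mGy to the conventional 0.27 Gy. Doses are stored in mGy everywhere;
Gy appears only in display contexts.

## Solvent normalisation and tiers

Lipophilic substances are dissolved in DMSO, itself a mildly protective
sulfur compound when present *before* irradiation. Where a solvent-only arm
exists for the same timing, `score_screening()` reports a DMSO-normalised
MP obtained by subtracting the solvent-only MP from the total
(`dmso_normalize()`); negative net values flag net radiosensitisation.

Substances are tiered against the irradiated control from the
Tukey-adjusted p-value and the direction of the frequency change: a
decrease at p < 0.001 is a strong protector, at p < 0.01 a moderate one; an
increase at p < 0.01 is a radiosensitizer; anything else is not
significant. These tiers mirror the marker convention of screening figures
(0.001/0.01/0.05). Genotoxicity of the substance itself
(`assess_genotoxicity()`) requires both an increase over the unirradiated
control and two-tailed significance at 0.05.

## Inference

Group comparisons are classical fixed-effects one-way ANOVA on the
MN/500 BC scale (`one_way_anova()`), followed by Tukey HSD pairwise
comparisons (`tukey_hsd()`), with the Tukey-Kramer harmonic adjustment for
unbalanced groups. Adjusted p-values come from the studentized range
distribution via R's `ptukey`; the test suite cross-checks them against a
direct double-quadrature evaluation of the range CDF and against published
critical values (e.g. \(q_{0.05; k=3, \nu=6} \approx 4.34\)). Analyses run
on untransformed frequencies, which is the convention in this assay; a
square-root variance-stabilising transform can be applied by the caller
before the inference functions if desired.

The replication unit is the (donor, experiment) culture. Donors are treated
as a blocking factor: pooling across donors is licensed by
`donor_interaction_screen()`, a two-way fixed-effects ANOVA of frequency on
donor x treatment whose interaction p-value must be at least 0.05.
Unreplicated or single-donor designs return an explicit cannot-test verdict
with pooling disallowed, rather than a p-value. No mixed-model variance
component for donors is estimated; the screen is intentionally the simple
fixed-factor interaction test.

## The synthetic generator

`synthetic_config()` encodes the study conditions the analysis assumes, and
its defaults are fixed at those conditions:

| parameter | default | meaning |
|---|---|---|
| `baseline_freq` | 10 MN/500 BC | spontaneous frequency, 0.02 MN/BC |
| `slope` | 1/64.37 MN/500 BC per mGy | forward slope matching the inverse equation |
| `calibration_doses` | 20 points, 0--16,362 mGy | calibration schedule |
| `nominal_screen_dose` | 2000 mGy | the 2 Gy screening exposure |
| `irradiated_control_mean` | 26 MN/500 BC | irradiated control |
| `n_donors`, `n_experiments` | 6, 5 | design size |
| `dispersion` | 0 (Poisson) | count overdispersion, `var = mean (1 + dispersion)` |
| `donor_sd` | 0.05 | log-scale SD of the mean-one log-normal donor factor |
| `dmso_offset` | 0.04 | additive solvent protection fraction, pre arm only |

Counts per 500 BC are Poisson (negative binomial when `dispersion > 0`,
parameterised so dispersion 0 degenerates continuously to Poisson) around
arm means; substance effects are protection fractions \(f\) acting
*multiplicatively on the total irradiated-control mean*,
\(\mu_t = (1-f)\,\mu_c\). That choice makes the configured \(f\) and the
expected MP coincide exactly (MP is defined on total frequencies), so
parameter-recovery tests compare estimates against a known truth. The
generator emits that truth alongside the records (`attr(., "truth")`,
`write_synthetic_dataset()`), so tests never re-derive truth from outputs.
One seed in the config governs the whole dataset; identical configs give
byte-identical CSVs.

Choices where the design was genuinely open, decided once:

* the source design is described once as five independent experiments and
  elsewhere as four; the generator defaults to 5 with `n_experiments`
  exposed, and nothing downstream assumes either value;
* the dose range appears both as "0--16.362 mGy" and as "1.3--1636 cGy";
  the schedule is taken as 0--16,362 mGy (the cGy range read as the
  non-zero doses), and the grid is configuration, not an assumption;
* the solvent offset (4% MP) applies in the pre arm only, since DMSO shows
  no effect administered after exposure;
* CBPI tallies are a multinomial draw whose class probabilities hit a
  target expected CBPI (default 1.65, the control value), with the
  multinucleate share capped at 5%;
* the CBPI quality band 1.3--1.7 is inclusive at both ends, which keeps
  the reported control value range self-consistent;
* the 3000-BC-per-condition scoring convention is enforced as a warning,
  not an error, so small fixtures remain analysable.

What the generator does **not** emulate: per-cell MN multiplicity
distributions (only totals per 500 BC are drawn), cell-cycle kinetics,
scorer variability, or any mechanistic chemistry of the substances. Passing
recovery tests therefore shows the *analysis* is unbiased under the assumed
count model -- not that real CBMN data is Poisson, nor anything about a
particular compound.

## Numerical choices and degenerate inputs

* Least squares is unweighted by default (no weighting is implied by the
  MN/500 BC convention); a Poisson-style weighted fit is available.
* A fit needs at least three distinct doses; identical doses raise a
  singular-design error, and a non-positive slope returns a curve with
  inversion disabled rather than a nonsense inverse.
* All-constant groups make the within-group variance zero; the ANOVA
  raises a degenerate-variance error, and `score_screening()` degrades
  gracefully by leaving the p-values `NA` while still reporting MP/DRF.
* The studentized-range tail is evaluated by `ptukey`; the suite verifies
  it against an independent double quadrature to 1e-4.
* Permutation checks of the ANOVA p-value account for the discreteness of
  small fixtures: ties at the observed F are non-negligible there, so the
  continuous F p-value is required to fall inside the permutation tie band
  rather than to match a single tail count.

## Problem sizes used in the checks

The packaged checks run at desk scale: worked-example endpoints on the
printed condition means; parameter recovery over 200 seeded replicates of
the default 6 x 5 design; family-wise error of the Tukey screen under a
simulated global null (five arms drawn from the irradiated-control
distribution, five cultures each) over 1000 replicates, required to stay at
or below 0.07 at nominal 0.05; and a 20,000-shuffle permutation oracle for
the ANOVA fixture.

## Known limitations

* The screen tests a single concentration per substance by design; no
  concentration-response modelling is attempted.
* Dose uncertainty is percentile-bootstrap only; no Poisson-exact
  dosimetry intervals or partial-body exposure models.
* The DRF is undefined (infinite, flagged) once a treated frequency drops
  below the calibration intercept; comparisons among such substances need
  a lower-baseline curve, not this package.
* Published DRFs that depend on unpublished per-culture counts cannot be
  recomputed from first principles here; the package reproduces endpoints
  only where their inputs are available.

## A worked run

```{r, eval = FALSE}
curve <- from_inverse_coefficients(-429.54, 64.37)
cfg <- synthetic_config(seed = 1,
                        effects = list(RA = list(pre = 0.58, post = 0.08)))
recs <- simulate_screening_experiment(cfg)
csv <- tempfile(fileext = ".csv"); write_scoring_table(recs, csv)
cj <- tempfile(fileext = ".json"); write_calibration(curve, cj)
run <- run_pipeline(run_config(csv, curve_json = cj,
                               out_dir = tempdir(), seed = 1))
run$results
```
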