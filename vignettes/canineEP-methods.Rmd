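---
title: "Methods: biomarkers, synthetic cohort, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomarkers, synthetic cohort, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canineEP)
```

## The study design this package serves

canineEP implements the quantitative layer of a two-group canine cardiac
electrophysiology design: a sedentary control group (SED) and an
endurance-trained group (TRN), each typically 12 animals, characterised
before (week 0) and after (week 16) a training period by resting ECG
recordings, echocardiography, and - terminally - cellular
electrophysiology (microelectrode and patch-clamp).  The package turns
beat-interval tables, sampled voltage traces, voltage-clamp step records
and echo panels into the biomarkers such a study reports, and compares
them between groups.  A synthetic cohort generator with known ground
truth makes every stage testable end to end without any animal data.

## The rate-correction model

QT shortens as heart rate rises, so raw QT cannot be compared across
groups whose RR differs.  The package uses an intra-study, individualized
linear correction rather than a generic Bazett or Fridericia transform.
On baseline data, ordinary least squares fits

$$\mathrm{QT}_x = a\,\mathrm{RR}_{x-1} + b,$$

pairing each QT with the *preceding* RR interval: ventricular
repolarization adapts to the length of the previous cycle, and this
pairing makes the rearranged correction exact.  The corrected interval,
referenced to a fixed RR of 528 ms (a ventricular rate of about 118 bpm),
is

$$\mathrm{QTc}_x = \mathrm{QT}_x - a\,(\mathrm{RR}_{x-1} - 528).$$

`qtrr()` fits the model (a classed S3 object with `coef`, `predict`,
`residuals`, `plot` methods); `qtrr_reference()` builds it from stated
coefficients (default slope 0.045 ms/ms, intercept 187 ms); `correct_qt()`
applies it.  When the model is fitted and applied on the same data, the
OLS orthogonality of residuals makes the slope of QTc against RR exactly
zero - `verify_zero_slope()` checks this property, which holds to machine
precision in the test suite.

Two fitting choices were genuinely open.  The baseline relation could be
fitted pooled across groups or per animal: the default is pooled over all
week-0 windows, because the correction is defined by a single printed
relation; a per-animal fit is a straightforward loop over `qtrr()` calls.
And QT could be paired with its own cycle instead of the preceding one;
`pairing = "same"` exists for sensitivity analysis, but the preceding-RR
pairing is the default and the one the zero-slope property relies on.

## Beat-to-beat variability statistics

Two statistics summarise beat-to-beat instability over an analysis window
of 40 consecutive sinus beats selected at the 10th minute of a recording
(`select_analysis_window()`; an ectopic beat resets the run, so the
window is always ectopy-free):

* **rmsSD** (`rmssd()`): root mean square of successive differences,
  $\sqrt{\tfrac{1}{N-1}\sum (x_{i+1}-x_i)^2}$ - the classical
  time-domain vagal-tone index, applied to RR.
* **STV** (`stv()`): mean absolute successive difference divided by
  $\sqrt2$, $\sum |x_{i+1}-x_i| / ((N-1)\sqrt2)$ - geometrically the
  mean perpendicular distance of Poincaré points
  (`poincare_pairs()`) from the identity line, applied to QT and to
  cellular APD90.

The divisor convention (differences, i.e. $N-1$) is exposed as a switch
in `stv()`.  Under i.i.d. Gaussian jitter with SD $\sigma$ the analytic
expectations are $E[\mathrm{rmssd}] \to \sigma\sqrt2$ and
$E[\mathrm{STV}] = \sigma\sqrt{2/\pi}$; the suite checks both to 1% at
$n = 10^5$, and the generator's jitter defaults are chosen by inverting
these identities (below).  Jensen's inequality gives
$\mathrm{STV} \le \mathrm{rmssd}/\sqrt2$ always.

The heart rate of a window is `60000 / mean(RR)` - the rate implied by
the mean cycle length, not the mean of per-beat rates.

## Ventricular ectopy classification

Ectopic beats are classified from interval geometry plus morphology
flags, an operationalization of the qualitative consensus definitions
(Lambeth-convention classes) in dimensionless form
(`classifier_params()`, `classify_beats()`):

* the **prevailing RR** is the trailing median of the last 10
  sinus-morphology RRs - robust to the ectopic beats themselves;
* a ventricular-morphology beat (wide QRS, no associated P wave) is
  **premature** when its coupling interval is at most 0.80 of the
  prevailing RR, **escape** when its preceding pause is at least 1.50 of
  it, and `other` when neither;
* narrow-QRS beats stay sinus.

Because the thresholds are ratios, classification is invariant to a
uniform rescaling of all intervals (asserted in the suite).  The
generator injects escapes at pause factor 1.8 and prematures at coupling
factor 0.6, clearly beyond the 1.5/0.8 thresholds, so on synthetic data
with default geometry the classifier is exact - the suite asserts 100%
agreement with injected truth.  The 0.80/1.50 thresholds and the
trailing-median are this package's choices, exposed in
`classifier_params()`; real ECGs with fusion beats or marginal coupling
will not be classified perfectly.

Counts aggregate across an animal's recordings (`count_and_rate()`; by
default three 20-minute resting recordings) into per-hour rates, and
`incidence()` builds per-group proportions with the 2x2 table for the
chi-square test.

## Cellular electrophysiology extraction

`extract_ap_features()` measures, per paced beat: resting membrane
potential as the mean voltage over the 20 ms before the stimulus (the
averaging window is this package's choice; it is not standardized),
amplitude as peak minus RMP, and APD90 from the maximum-upstroke-velocity
point to the first downward crossing of
$\mathrm{peak} - 0.9\,\mathrm{amplitude}$, linearly interpolated between
samples.  Onset at maximal dV/dt (rather than the stimulus artifact) is
standard practice and robust to stimulus latency; `onset = "stimulus"`
switches it.  Beats with RMP more positive than -70 mV or amplitude
below 90 mV are excluded *before* any aggregation, as are beats that do
not recross the level before the next stimulus.  On noise-free synthetic
traces the extraction error is below one sampling interval (1 ms).

`stv_apd()` computes STV over exactly 30 consecutive APD90 values taken
from the end of a run of at least 60 recorded beats, discarding the
initial equilibration - which 30 of the recorded beats enter the
statistic is not standardized, so the tail-of-run rule is explicit and
configurable.

`current_density()` normalizes peak currents by cell capacitance
(pA/pF), and `assemble_iv()` aggregates per-cell densities into a group
current-voltage relation (mean ± SEM per step), refusing groups of one
cell (SEM undefined).  Averaging densities per cell first matters: the
pooled ratio mean(current)/mean(capacitance) differs whenever capacitance
varies, and a test demonstrates exactly that.

## Echocardiographic indices

All derived indices are deterministic pure functions of the raw panel
(`derive_echo_panel()`):

* BSA by the canine Meeh formula $0.101\,\mathrm{BW}^{2/3}$ (kg to m²).
  The constant is configurable; 0.101 is the classical canine value.
* LVM by the cube formula
  $0.0008\,(1.04\,(\mathrm{LVEDD}+\mathrm{LVPW}+\mathrm{IVS})^3 -
  \mathrm{LVEDD}^3 + 0.6)$ g with mm inputs, implemented with the
  `+0.6` inside the braces exactly as reported; a `devereux` mode moves
  it outside (conventional placement) - the two differ by a few tenths
  of a gram, immaterial against canine masses of 45-85 g.
* Teichholz volumes $V = 7D^3/(2.4+D)$ with D in cm (mm inputs are
  converted - the formula yields ml only in cm), EF as
  $100\,(\mathrm{EDV}-\mathrm{ESV})/\mathrm{EDV}$, and the per-BW and
  per-BSA normalizations.

Evaluating these nonlinear formulas at group-*mean* inputs does not equal
the group mean of per-animal values (a Jensen gap); at the reference
group means the gap is within 2% for the quantities the suite checks,
and the hand-computed values (54.36 g, 40.96 ml, 74.88%) are asserted to
4 significant figures.

## The group-comparison layer

`choose_and_run()` reproduces the statistical decision procedure:
a Kolmogorov-Smirnov normality check on each sample - with estimated
mean/SD, i.e. Lilliefors critical values (`nortest::lillie.test`), since
parameters are never known a priori - gates between Student's t
(paired or unpaired, equal variances) and a two-sided Mann-Whitney U
test.  Significance is $p \le 0.05$; no multiple-testing adjustment is
applied, matching per-variable reporting.  The procedure's provenance
(normality p-values, test used) is always returned.  Monte-Carlo checks
hold its type-I error near the nominal 5% under Gaussian and
heavy-tailed nulls.  The Lilliefors tables require $n \ge 5$, which is
therefore the procedure's minimum sample size.  `chi_square_2x2()`
implements the closed form $n(ad-bc)^2/((a{+}b)(c{+}d)(a{+}c)(b{+}d))$
without continuity correction by default (the uncorrected form reproduces
the classical worked values; Yates is behind a flag), cross-checked
against an expected-counts oracle and `stats::chisq.test`.

## What the synthetic cohort emulates - and what it does not

The generator's defaults *are* the study conditions; they are set once
and not tuned:

* **RR dynamics**: stationary AR(1) Gaussian, group mean RR 841.8 ms
  (TRN) / 644.2 ms (SED) at week 16, 579.3 / 588.4 ms at week 0.  No
  beat-dynamics model is specified by the design, so the AR(1) form,
  its stationary SD (40 ms) and autocorrelation (0.8) are this package's
  choices, picked to mimic respiratory sinus arrhythmia at a plausible
  canine scale.  RR is floored at 200 ms.
* **QT**: linear in the preceding RR.  At week 0 both groups use the
  pooled relation (slope 0.045, intercept 187 ms); at week 16 the
  intercepts (213.419 TRN, 194.011 SED) are set so the generated QT
  means reproduce the group means at the group mean RR - training
  lengthens repolarization beyond the rate effect, and the intercept is
  where that lives.  QT noise SDs (4.4 TRN / 3.2 SED ms) invert
  $E[\mathrm{STV}]$ so the generated STV-QT matches the reported 3.6 /
  2.6 ms.  Because no within-dog beat-level SDs are reported, these are
  inferred assumptions, flagged as such.
* **Ectopy**: independent Poisson processes; escape rate 29.7/hr (TRN)
  vs 0/hr (SED).  Premature rates are reported only as "low, not
  significantly different", so both groups default to 1/hr.
* **Cells**: per-beat APD90 = cell mean + i.i.d. jitter.  Group means
  472.8 / 370.1 ms; between-cell SDs convert printed SEMs via
  $SD = SEM\sqrt n$ (159 / 163 ms), which is wide - cell means are
  rejection-truncated to [100, 820] ms so every beat repolarizes within
  the 1 Hz cycle.  The truncation is nearly symmetric for TRN (bias
  under 3 ms) but biases the SED mean upward by roughly +15 ms; SED
  APD90 is not a calibration surface, and the bias is documented here
  rather than hidden by narrowing the SD.  Jitter SDs (36.97 / 21.93 ms)
  invert $\sigma\sqrt{2/\pi}$ for the target STV-APD (29.5 / 17.5 ms).
  I_to densities at +50 mV are Gaussian (6.4 ± SD 3.67 TRN, 8.8 ± 5.83
  SED, again SEM-converted), deliberately *not* truncated at zero -
  truncation would bias the group mean upward by ~0.3 pA/pF.  Other
  steps follow a monotone activation curve, zero at and below -20 mV,
  normalized to 1 at +50 mV.
* **Echo**: raw panels Gaussian around the group/timepoint means
  (SEM-converted SDs), with draws rejected until LVEDD > LVESD; body
  weight uniform on 9-15 kg.

The generator does **not** emulate: waveform-level ECG (intervals are
generated directly), biophysical ionic AP models (the waveform is
parametric; only APD90 ground truth matters downstream), tachyarrhythmia
runs (salvos/VT - none are expected at rest in this design),
ventricular-fibrillation dynamics (VF outcomes enter as Bernoulli
columns), or drug-isolation chemistry in the clamp protocols (metadata
tags only).  Passing tests on this cohort therefore demonstrate the
*analysis* pipeline is correct and calibrated, not that real dogs would
yield these numbers.

Determinism: the master seed fully determines the cohort; each animal
uses `seed + animal index` and cell blocks use fixed offsets, so the
cohort is extensible without reshuffling existing animals.

## Problem sizes and numerical choices

The calibration-recovery checks run 20 Monte-Carlo seeds of the
study-sized designs (54 I-V cells, 29 AP trains of 60 beats at 1 ms
sampling, 12 animals x 3 x 20-min recordings), comparing recovered group
means with their targets at 3 SEM over seeds; unit tests use smaller
cohorts chosen to keep the default suite under a couple of minutes while
exercising every code path.  Tolerances: exact formula checks at 1e-10
to 1e-12 (against independent normal-equation and expected-count
oracles), sampling-based checks at 3-sigma Monte-Carlo bounds, APD
extraction at one sampling interval.  Degenerate inputs fail loudly
rather than silently: zero RR spread, zero-variance paired differences,
groups of one cell, EDV <= ESV, and windows without 40 consecutive sinus
beats all raise informative errors.

## Known limitations

* Interval tables are inputs: there is no QRS detection or delineation
  from raw ECG waveforms.
* The ectopy classifier assumes trustworthy wide-QRS / P-association
  flags; it does not detect morphology itself.
* The AP extractor assumes monotone repolarization after the plateau;
  pronounced phase-1 notches deeper than the APD50 level could trigger
  early crossings at low repolarization fractions.
* Between-animal RR variation is not modelled separately from
  beat-to-beat variation; group comparisons on synthetic ECG metrics
  therefore understate between-animal variance relative to a real
  cohort.
* The statistical layer implements exactly the reported decision tree;
  it is not a general modelling framework (no mixed effects, no
  repeated-measures structure beyond the paired design).
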