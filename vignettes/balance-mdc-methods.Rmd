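---
title: "Methods: MDC-based balance assessment and individual monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MDC-based balance assessment and individual monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balancemdc)
```

This vignette is the package's own account of the statistics it implements:
the measurement model, the reliability and minimal-detectable-change (MDC)
chain, the magnitude-based decision (MBD) rule for individual patients, the
synthetic-data generators that stand in for platform recordings, and the
numerical and design choices that were genuinely open.

## 1. The measurement chain

A stabilometric platform with four load cells at known positions $p_i$
measures vertical forces $f_i(t)$; the centre of pressure is the
force-weighted centroid

$$\mathrm{COP}(t) = \frac{\sum_i f_i(t)\, p_i}{\sum_i f_i(t)},$$

computed by `compute_cop()`. A sample with zero total force has no defined
COP and is refused with an error naming the sample, rather than being
interpolated: a recording in which the subject left the platform should not
silently produce numbers.

From a COP trajectory, `extract_variables()` computes the per-task panel:

* **COP mean speed** [mm/s]: total path length over elapsed time.
* **RMS position** [mm]: root-mean-square radial distance from the
  trajectory's own mean point.
* **Sway area** [cm²]: by default the 95% prediction ellipse
  $\pi\,\chi^2_{2,0.95}\sqrt{\det\Sigma}$, with $\Sigma$ the sample
  covariance of (ML, AP). This is the standard posturographic area measure
  and has a closed form we can test against simulated Gaussian clouds. A
  convex-hull area is offered as an alternative because "area covered by the
  trajectory" admits both readings; the hull is noisier (it is an extreme
  statistic) and is not the default. A collinear trajectory has ellipse
  area 0; the hull of collinear points is refused as degenerate.
* **AP / ML displacement** [mm]: max − min of the coordinate. (Peak-to-peak
  about the mean gives identical values; we document the max − min form.)
* **LOS variables**: for each of 8 octagon directions at 45° steps,
  clockwise from Forward, the **COP limit** is the maximum scalar projection
  of $\mathrm{COP}(t) - \mathrm{COP}(0)$ onto the direction, floored at 0,
  and **Success** is a control-quality score in [0, 100].

Coordinate convention: ML = $x$ (rightward positive), AP = $y$ (forward
positive), origin at the platform centre. COP limits are referenced to the
trajectory's start point because the protocol begins in quiet stance at the
centre; referencing to the platform origin instead would punish a subject
who starts slightly off-centre.

The success score's published defining formula lives in device-specific
prior work that we do not reproduce; it is therefore a **pluggable scorer**.
The default is a path-efficiency ratio: during the phase in which direction
$d$ was the target, $100 \cdot 2 R_d / L$, where $R_d$ is the peak on-axis
excursion and $L$ the path length travelled, clamped to [0, 100]. A
perfectly straight out-and-back excursion scores 100, a meandering path of
twice that length scores 50, no movement scores 0. Any
`function(phase, ux, uy)` can replace it without touching other code, and
conclusions that depend on Success values should state the scorer used.

No filtering is applied by default; `lowpass_cop()` provides an optional
zero-phase Butterworth low-pass (configurable cutoff) for noisy recordings.

## 2. Reliability and the MDC

For each variable measured twice (test, retest) on $n$ subjects,
`reliability_table()` computes the two-way consistency ICC from the
subjects × sessions ANOVA mean squares, then

$$\mathrm{SEM} = \mathrm{SD_{pooled}}\sqrt{1 - \mathrm{ICC}}, \qquad
  \mathrm{MDC_{95}} = 1.96\,\sqrt{2}\,\mathrm{SEM}, \qquad
  \mathrm{MDC_{es}} = \mathrm{MDC_{95}} / \mathrm{SD_{test}},$$

with $\mathrm{SD_{pooled}} = \sqrt{(\mathrm{SD^2_{test}} +
\mathrm{SD^2_{retest}})/2}$, the root-mean-square pooling appropriate for
two sessions of equal size (the arithmetic mean of SDs differs only in the
third decimal and is not offered). ICCs are banded qualitatively at 0.40 /
0.60 / 0.75 (poor, fair, good, excellent).

**Which ICC?** With $MS_R$ the between-subjects and $MS_E$ the residual
mean square (at $k = 2$ sessions no subject × session interaction is
estimable), the consistency family has two forms:

* single measures: $(MS_R - MS_E)/(MS_R + (k-1) MS_E)$, estimating
  $\sigma_b^2/(\sigma_b^2 + \sigma_e^2)$ — the reliability of *one*
  measurement;
* average measures (often written ICC(3,k)):
  $(MS_R - MS_E)/MS_R$ — the Spearman–Brown-boosted reliability of the
  *mean of both* sessions.

`icc_consistency()` offers both; `reliability_table()` defaults to
**single measures**. The reason is internal consistency of the chain above:
$\mathrm{SD^2_{pooled}}$ estimates $\sigma_b^2 + \sigma_e^2$, so
$\mathrm{SD_{pooled}}\sqrt{1 - r}$ recovers the within-subject error
$\sigma_e$ — and hence $\mathrm{MDC_{95}} = 1.96\sqrt2\,\sigma_e$ — only
when $r$ is the single-measures ICC. With the average-measures form the SEM
would be understated by the factor $\sqrt{(1 + r_1)/2}$ wherever only one
measurement per visit is taken, which is exactly the monitoring use case.
The package's parameter-recovery tests (Section 4) check this identity
numerically.

The report layout (`format_reliability()`) rounds means, SDs and MDCs
half-up to one decimal and ICCs to two, marks the most reliable variables
of each task block with `*` (ICC ≥ 0.83 by default; the threshold is an
argument because the marking rule is a convention, not a formula), and
keeps all internal values unrounded.

`sample_size()` implements the precision-based formula
$N = z^2_{1-\alpha/2}\,\mathrm{SD}^2/d^2$ used to size a monitoring study,
returned unrounded.

## 3. Magnitude-based decision for one patient

For a variable with threshold MDC and observed values $x_{pre}$, $x_{post}$,
the observed difference is $x_{dif} = x_{post} - x_{pre}$. Each of the two
measurements carries error with SD = SEM, so the difference carries error
with SD $\sqrt2\,\mathrm{SEM} = \mathrm{MDC}/1.96$. The true change is
modelled as

$$\Delta \sim \mathcal N\!\left(x_{dif},\; \mathrm{MDC}/1.96\right),$$

and `change_probabilities()` reports
$p_- = P(\Delta < -\mathrm{MDC})$, $p_+ = P(\Delta > +\mathrm{MDC})$ and the
trivial remainder, as percentages summing to exactly 100 before rounding.
The dispersion choice $\mathrm{MDC}/1.96$ is the only one consistent with
using the MDC both as relevance threshold and as the 95% bound of the
difference's error distribution; it also makes $p_- = 50\%$ exactly when the
difference sits on the threshold. `monitor_patient()` aggregates to a
probability of relevant change $p_{change} = \max(p_-, p_+)$ with its
direction (the sum $p_- + p_+$ is also emitted as `p_outside` for users who
prefer the two-sided reading), and labels it on the conventional qualitative
scale: most unlikely (< 1%), very unlikely (1–5%), unlikely (5–25%),
possibly (25–75%), probably (75–95%), very likely (95–99%), most likely
(> 99%). Band edges are half-open on the left (so 1% is "very unlikely",
5% "unlikely", …) except that exactly 99% remains "very likely", matching
the "> 99%" wording of the top band.

Display rounding is half-up to integers (`round_half_up()`), so a rounded
triplet can sum to 99 or 101; no largest-remainder correction is applied
because the unrounded triplet is the statistical object and is preserved in
all machine-readable output. Reports use the ASCII hyphen-minus.

An optional annotation layer (on by default when task labels are present)
interprets direction as improvement/worsening — static sway decreasing and
LOS variables increasing are improvements — but never alters the statistics:
whether a relevant change is good news is ultimately the clinician's call.

`plot_change()` / `autoplot()` draw the monitoring chart: per variable a
grey band spanning (−MDC, +MDC), a black bar from 0 to the observed
difference, and the probability in the right margin, facetted into static
and LOS panels. Tests assert the plot's underlying data (band extents, bar
ends, labels), not pixels.

## 4. Synthetic data: what it emulates and what it does not

The generators exist so that every downstream stage has a ground truth.

**Quiet-stance sway** (`gen_sway_trajectory()`): each axis is an exactly
discretized stationary Ornstein–Uhlenbeck process,
$x_{t+1} = \phi x_t + \sigma\sqrt{1-\phi^2}\,z_t$ with
$\phi = e^{-\Delta t/\tau}$, initialized from its stationary law. The model
was chosen not for biomechanical realism but because it is the simplest
mean-reverting process with closed-form stationary moments: the long-run SD
per axis *is* $\sigma$, which gives the tests an analytic oracle.
Defaults: 40 Hz sampling, 30 s trials, $\tau = 1$ s, and per-task sigmas
(ML, AP in mm) RSEO (2.5, 3.0), RSEC (3.5, 4.0), SSEO (4.0, 4.5),
SSEC (7.5, 9.0) — ordered RSEO < RSEC < SSEO < SSEC, since removing vision
and compliant surfaces both increase sway, and sized to land near healthy
young-adult values. These are conventions of the generator, not measured
facts, and are configurable.

**LOS trials** (`gen_los_trajectory()`): one out-and-back excursion per
direction, visiting the octagon clockwise from Forward, with a triangular
on-axis profile whose apex is exactly `target × (1 + overshoot)`, plus
Gaussian tracking noise. The triangular profile guarantees the noiseless
round-trip identity *limit = target* to machine precision, which anchors
the metric tests. Defaults: 80 mm targets, 5 s per direction.

**Cohorts** (`gen_testretest_cohort()`): value = mean + subject effect +
session noise, all Gaussian, giving true ICC
$\sigma_b^2/(\sigma_b^2+\sigma_e^2)$ and true MDC95 $1.96\sqrt2\,\sigma_e$.
**Patient pairs** (`gen_patient_pair()`): pre/post with a known true change
and SEM-sized noise. Gaussian noise throughout, deliberately matching the
normal model the MBD stage assumes.

What passing tests on this synthetic data shows: the estimators recover the
parameters of their own generating model (e.g. across 500 cohorts of
$n = 50$ at true ICC 0.9, the mean estimated ICC is within ±0.02 of truth
and the mean estimated MDC within ±5%). What it does not show: behaviour
under real sway, which is non-Gaussian, non-stationary, has 1/f-like
spectra and task-correlated variables; nor robustness to platform artefacts
(load-cell noise, drift, foam mechanics), which are out of scope.

## 5. Numerical choices, degenerate inputs, problem sizes

* All probability work uses `pnorm` directly (both tails through the same
  routine, so swapping pre and post mirrors the triplet exactly); the
  trivial remainder is clamped at 0 against floating-point underflow.
* Degenerate inputs fail loudly with classed errors: zero total force,
  fewer than 2 samples, collinear hulls, unbalanced cohorts (offending
  subject/variable pairs are listed), zero between-subject variance
  (ICC undefined), missing MDC thresholds (the variable is named).
  A variable present in only one of the two sessions is skipped with a
  warning rather than failing the whole report.
* Seeded generation is bit-reproducible; file outputs of the pipeline are
  byte-identical under identical config and seed.
* Simulation sizes used by the test suite — 600 s of sway for the
  stationary-SD check, cohorts of $n = 200$ for single-run recovery, 500
  replicate cohorts of $n = 50$ for the bias check, 10,000 random pairs for
  the probability invariants — were chosen so Monte-Carlo error sits well
  inside the asserted tolerances.

## 6. Known limitations

* The reliability module assumes a balanced two-session design; more
  sessions, raters or confidence intervals for the ICC are not implemented.
* MBD is the plain normal-theory variant; Bayesian or t-based versions and
  multi-visit trend monitoring are out of scope.
* The default success scorer is a reasonable path-efficiency definition,
  not a reimplementation of any particular device's score.
* MDC thresholds transported from a healthy young cohort to elderly
  patients quantify instrument-plus-protocol noise, not disease-specific
  variability; the bundled reference panel should be replaced by a local
  test-retest study where available.
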