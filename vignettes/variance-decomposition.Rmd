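---
title: "Separating measurement uncertainty from between- and within-subject variation in bed-rest responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating measurement uncertainty from between- and within-subject variation in bed-rest responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedrestvar)
```

## The problem

Bed rest is the standard ground analog for microgravity: weeks of strict
(often 6° head-down-tilt) bed rest produce muscle atrophy and bone loss in
the lower leg that resemble spaceflight adaptations. Group means of these
losses are well characterised; what is much harder is deciding whether the
*spread* of individual responses is real biology. An individual's observed
percent change mixes three things:

* **measurement uncertainty** (`U_Meas`) — pQCT repositioning and
  segmentation noise;
* **between-subject variation** (BSV) — genuinely different response
  magnitudes across individuals;
* **within-subject variation** (WSV) — one individual responding
  differently at different measurement sites.

This package implements a variance-decomposition framework that separates
the three, on scan-level records of bone mineral content (BMC, mg/mm) at
four tibia sites (4%, 38%, 66%, 98% of tibia length) and muscle
cross-sectional area (CSA, mm²) at the two diaphyseal sites.

## The model

For subject $i$ in study $k$, the observed response at a site is the
percent change relative to the first baseline scan (BDC1):

$$pc_{ik} = \frac{x_{\mathrm{resp},ik} - x_{\mathrm{BDC},ik}}{x_{\mathrm{BDC},ik}} \times 100.$$

Muscle responses are read at the end of bed rest; bone responses at the
14-day follow-up, because bone loss continues for another 10–20 days after
re-ambulation while muscle loss does not.

Assuming measurement noise and the individual response are independent and
normally distributed, the variances superpose:

$$U_{Obs} = U_{Meas} + U_{IR},$$

where $U_{Obs}$ is the sample variance (divisor $n-1$) of the control-group
percent changes in a study × site cell, $U_{Meas}$ is the measurement
variance on the percent scale, and $U_{IR}$ — the individual-response
uncertainty — is the biological between-subject response variance obtained
by subtraction. All three are in %².

$U_{Meas}$ is estimated from studies with duplicate baseline scans: per
subject, the sample variance of the two baselines times $(100/\bar{x})^2$,
then averaged over all subjects of the study — including intervention-group
subjects and both legs where scanned, since baseline scans are unaffected
by the intervention and more pairs give a more precise estimate.

### The donor rule

Only three of the eight packaged studies (LTBR, RSL, Valdoltra) took
duplicate baselines. Every other study × site cell borrows the pooled
$U_{Meas}$ of the duplicate-baseline study with the most similar
measurement conditions. The package encodes this as an ordered filter over
the design metadata, applied at the study level:

1. scout-view orientation at the proximal tibia (frontal vs sagittal) —
   the dominant determinant of repositioning error at TIBIA_98;
2. detection mode of the 66% site (manual vs scout-view);
3. device model (XCT2000 vs XCT3000).

Site availability is checked only on the winning donor: if that study never
measured the requested site, the rule falls back to the *maximum* pooled
$U_{Meas}$ among studies that did — a deliberately conservative choice that
avoids overstating biology. This ordering is a design decision: the source
framework states the similarity principle but not a metric, and the
study-level reading is the only one consistent with its own worked fallback
case (a 21-day horizontal-bed-rest study whose preferred donor lacks the
muscle site, falling back to the largest muscle $U_{Meas}$). The mapping is
overridable by passing any `study, site, u_meas` table to `decompose()`.

Negative $U_{IR}$ (possible when there is no true loss and a borrowed
$U_{Meas}$ exceeds $U_{Obs}$) is preserved and flagged, never truncated:
it is informative about the borrowing, and the packaged reference tables
contain exactly one such cell.

### Derived statistics

* **ABD**, the adjusted between-subject deviation,
  $\sqrt{U_{IR}}/|\overline{pc}_k|/\mathrm{weeks}$, makes response spread
  comparable across studies of different durations. The magnitude
  convention (|mean change|) makes it a positive dispersion measure;
  it is undefined for negative $U_{IR}$ or zero mean change.
* **Responder classification**: a 95% interval
  $\overline{pc}_k \pm 1.96\sqrt{U_{Meas}}$ around the cell mean; subjects
  outside it (open exceedance, closed interval) show BSV beyond
  measurement noise. The SD form is the package default because it is
  dimensionally consistent; the literal form $\pm 1.96\,U_{Meas}$ (%² mixed
  with %) is kept as `mode = "literal"` for fidelity to the framework's
  original wording. Which of the two produced the published fractions is
  not decidable from the source text, so no exact fraction is asserted
  anywhere — only the qualitative ordering (bone above muscle).
* **WSV** is read from the inter-site Pearson correlation matrix of
  percent changes, pairwise-complete over all subjects providing both
  sites of a pair, with conventional strength bands (|r| < 0.3 negligible,
  0.3–0.5 low, 0.5–0.7 moderate, 0.7–0.9 high, ≥ 0.9 very high; exact
  cutpoints to the higher band). Cells with p ≥ 0.05 are reported as "no
  correlation" regardless of r. No multiple-testing correction is applied,
  matching the framework's reporting.
* **Geometry**: absolute bone loss $BL = BMC_{BDC} - BMC_{post}$ regressed
  on endocortical circumference (ENDO), per study (≥ 3 bone sites) and
  pooled; and percent change regressed on the baseline ENDO/BMC ratio, a
  surface-to-volume marker.
* **Crew projection**: with a mean loss rate $\mu$ %/month and
  between-subject SD $\sigma$ %/month, the largest expected loss in an
  $n$-person crew after $m$ months is
  $m\mu + m\sigma\, z_{1-1/n}$ ($z_{1-1/n}$ the standard-normal quantile;
  0.967 for $n=6$). The SD scales linearly with months, i.e. an
  individual's deviation from the mean rate persists month to month. This
  quantile heuristic understates the true expected maximum of $n$
  independent normal losses (for $n = 6$, 1.267 SD rather than 0.967);
  `method = "mc"` computes the Monte-Carlo expected maximum instead, and a
  test asserts the direction of the difference.

## The synthetic cohort generator

No subject-level data are deposited with the framework, so the package
ships a generator that emulates the statistical structure the analysis
assumes; every pipeline stage is exercised against it.

Per study: a subject's baseline level at a site is the site mean plus a
study effect and a subject effect (per tissue). The true response vector
over the sites of a tissue is the study × site mean change plus a mean-zero
multivariate normal deviation with exchangeable correlation
(`intersite_rho`). Epiphyseal bone sites are generated as compact plus
trabecular compartments — their own response deviations, uncorrelated with
each other by default — and the emitted total series is exactly their sum.
All three series of an epiphysis share each scan's noise draw (one scan,
one repositioning error), so total-site correlations are attenuated
mixtures of the compartment structure, as in real epiphyseal data.

**Noise modes.** `per_scan` multiplies every scan by $1+\varepsilon/100$,
$\varepsilon \sim N(0, \sigma)$ — realistic, and it makes
$\mathrm{Var}(pc) \approx U_{IR} + 2U_{Meas}$ because baseline and response
scans both carry noise. `single_draw` (the default) exists so the
superposition identity holds *exactly*: BDC1 is noise-free, the tissue's
response scan carries one noise draw composed additively on the percent
scale ($x = \mathrm{base}\,(1 + (pc+\varepsilon)/100)$, so
$pc_{obs} = pc + \varepsilon$ with no $(1+pc/100)$ attenuation of the
noise), and BDC2 carries a $\sqrt{2}$-scaled deviation so that the
duplicate-pair variance estimator remains unbiased for $\sigma^2$. With a
literal "response scan only" noise placement the duplicate baselines would
be identical and $U_{Meas}$ inestimable; the $\sqrt{2}$ construction keeps
both the identity and the estimator calibrated, which is what the recovery
tests verify.

**Endocortical link.** ENDO is drawn per subject and bone site around a
site-typical circumference; the configured slope (mg/mm of absolute loss
per mm of ENDO, default 0.5) tilts the subject's response around the
per-site ENDO mean, leaving the configured site mean change untouched. The
link therefore acts on within-site deviations; a cohort in which the
*pooled across-site* regression also shows that slope additionally needs
the site mean losses placed on the same line, which is how the slope
recovery test constructs its cohort. Scenarios that specify total
between-subject response variance directly (parameter recovery, null
coverage) set the slope to 0, because a non-zero link is itself
between-subject response variance.

**Defaults.** Cohort sizes, durations, devices, scout orientations and
duplicate-baseline flags default to the packaged eight-study design table.
Baseline variance components default to the mixed-model estimates reported
for this data class (between-subject SD 47.1 mg/mm bone / 8.9 mm² muscle;
between-study SD 4.9 / 3.0). Mean losses default to the canonical disuse
magnitudes: bone 1.25% of BMC per month; muscle an exponential approach to
a 24% plateau with time constant 27.8 days (≈ 6% after 8 days). Inter-site
response correlations default to 0.9 (muscle) and 0.4 (bone), matching the
coherent-muscle / heterogeneous-bone contrast the framework reports.
Response SDs (3% muscle, 0.8% diaphyseal bone, 1.8–2% epiphyseal/
compartment) and scan noise SDs (≈ 0.9–1.1% muscle, 0.3% diaphyseal bone,
0.5–1% epiphyseal) are set to the magnitudes implied by the published
uncertainty tables. `truth_table()` returns all of this on the estimator
scale (including the compartment-mixture variance of epiphyseal totals and
the endo-link contribution) so recovery tests compare against exact truth.

What the generator does **not** emulate: scan artifacts and operator
drift, non-normal or skewed responses, secular improvement of measurement
precision within a study, left/right asymmetry of true responses (the
optional second leg shares the true baseline), and partial BDC2 coverage
within a duplicate-baseline study. Passing recovery tests therefore show
the estimators are correct under the model's own assumptions, not that
real pQCT data satisfy those assumptions.

## Numerical and design choices

* Percent change requires strictly positive baselines; values ≤ 0 are
  rejected at I/O validation.
* `U_IR = U_Obs - U_Meas` holds exactly (machine precision) row by row in
  every decomposition table.
* The baseline for percent change defaults to BDC1; the duplicate-baseline
  mean is an explicit opt-in (`baseline = "mean"`), since duplicate
  baselines improve the baseline estimate but the framework's definition
  uses the first scan.
* Percent-change analyses use one leg per subject (preferring the right);
  leg duplicates only ever feed measurement-uncertainty estimation.
* Degenerate inputs return flagged results rather than NaN: the paired t
  test on identical vectors reports t = 0, p = 1, `degenerate = TRUE`; an
  all-constant ANOVA reports an undefined F; zero-variance correlation
  inputs report an undefined r.
* Strength-band cutpoints are assigned to the higher category (0.5 is
  "moderate") — the convention of the cited scoring scale is ambiguous at
  boundaries, and the choice is isolated in `label_strength()`.
* Monte-Carlo problem sizes used by the test-suite: parameter recovery
  averages 20 cohorts of 500 subjects; null coverage averages 5 cohorts of
  1000; correlation-structure recovery averages 3 eight-study cohorts of
  60 subjects per study; these sizes put the Monte-Carlo error well inside
  the asserted bands while keeping the default test run fast.

## Limitations

* The donor-similarity map reproduces every published subtraction that is
  exact at printed precision; cells published from unrounded intermediates
  differ by one unit in the last printed decimal, and the package makes no
  attempt to sharpen beyond the printed values.
* Pooled summaries across studies can be weighted by subject or by study;
  both are legitimate, and per-study tables are the primary output.
* The linear mixed model whose variance components seed the generator
  defaults is out of scope; the package consumes its printed components,
  it does not refit them.
* Formal responder inference against an intervention contrast (SD-of-change
  methods) is out of scope — control-group data only.
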