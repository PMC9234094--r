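---
title: "Methods: surveillance rates, ascertainment and detectable risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveillance rates, ascertainment and detectable risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perisurv)
```

perisurv implements the analysis pipeline of a facility-based perinatal
surveillance network: births at participating hospitals are screened for
seven adverse outcomes, site-level rates are estimated with exact binomial
intervals, the completeness of routine case-finding is quantified against
standardized re-classification, and the observed baseline rates are turned
into minimum detectable effect sizes for planning future vaccine-safety
studies. This vignette records the statistical model behind each stage, the
defaults and why they were chosen, and what the packaged synthetic data
generator does and does not emulate.

## Outcome definitions

Seven outcomes are classified per delivery. The measurement-defined four
use strict (`<`) thresholds, so a value exactly at a cut-off is never a
case:

* **Low birthweight** — livebirth with birthweight < 2,500 g.
* **Preterm birth** — livebirth before 37 completed weeks, i.e.
  gestational age < 259 days. Gestational age is stored in days throughout;
  completed weeks are `floor(days / 7)`, which removes any week-rounding
  ambiguity at the boundary.
* **Small for gestational age (SGA)** — livebirth with birthweight below
  the 10th percentile of a sex- and gestational-age-specific reference.
* **Congenital microcephaly** — livebirth with head circumference below a
  configurable cut-off: the reference 3rd percentile (default), or mean
  minus 2 or 3 SD.

The remaining three come from recorded events: **stillbirth** (fetal death
at or after a configurable gestational-age floor, default 196 days = 28
weeks; fetal deaths with missing gestational age count by default),
**in-hospital neonatal death** (death on days 0–27 of life) and **neonatal
infection** (one of invasive bloodstream infection, meningitis or
respiratory infection; one subtype per case, matching reporting practice
where subtype counts partition all infections).

Every threshold is exposed in `classification_config()` because facility
networks in practice use diverse charts and cut-off values; the defaults
are the internationally standard choices, not a claim about any one site's
protocol. Records whose measurements cannot support a rule (for instance a
missing gestational age for the preterm rule) are never dropped: the label
is simply absent and the record is tallied in a per-outcome *unassessable*
count while staying in the livebirth denominator. This mirrors surveillance
reporting, where the denominator is all livebirths, not all assessable
livebirths, and it biases rates of measurement-defined outcomes downward
when missingness is high — which is precisely the phenomenon the
ascertainment analysis quantifies.

## The growth reference

SGA and microcephaly need a reference table keyed by sex and completed
gestational week (24–42): 10th-percentile, median and SD birthweight, and
3rd-percentile, median and SD head circumference. The packaged table
(`growth_reference_synthetic.tsv`) is **synthetic**: medians follow a
smooth, published-style grid (monotone Hyman splines through round-number
knots such as a 3,550 g male median at 40 weeks) and the percentile columns
derive from a normal model (p10 = median − 1.2816 SD, p3 = median − 1.8808
SD). It is internally consistent with the simulator's anthropometry draws
— which makes the simulator-classifier agreement property exactly testable
— but it is *not* INTERGROWTH-21st, Fenton or any national chart. Which
chart the network's statisticians actually used is not recorded in the
public material, so the chart is data, not code: `load_growth_reference()`
accepts any file with the same header. Lookups at non-integer week ages
interpolate linearly between adjacent rows; ages outside the 24–42-week
span clamp to the nearest endpoint by default (the extremely preterm tail
has no chart row), or raise an error with `clamp = FALSE`.

## Exact rate estimation

Rates are reported per 1,000 livebirths, except stillbirth per 1,000 total
births. Confidence intervals are exact Clopper–Pearson: the lower bound is
the α/2 quantile of Beta(x, n−x+1) (0 when x = 0) and the upper the
1−α/2 quantile of Beta(x+1, n−x) (1 when x = n), equivalent to inverting
the binomial tail sums. The exact interval is conservative — simulated
coverage at 95% nominal stays at or above 95%, which the test suite checks
at event probabilities 0.005, 0.05 and 0.25 with 2,000 replicates each.

Two rounding rules matter when comparing against typeset tables. Scaling
by 1,000 happens on the unrounded proportion and display rounding (one
decimal) happens last, so no double-rounding drift accrues; and rounding
is half *away from zero*, not banker's rounding, since that is how the
tables this package reproduces appear to have been typeset. Whether a
knife-edge `.05` cell was rounded up or to even in the original tables is
unknowable from the printed values; the half-up convention is applied
uniformly and could disagree on such a cell.

## Ascertainment sensitivity

Routine site surveillance misses cases. After measurement collection was
systematized for all livebirths, each measurement-defined outcome has two
routes to identification: the site's routine flag and the standardized
rule applied to the measurements. `union_cases()` counts a record once if
either route found it (`n_total`) and counts the site-flagged among them
(`n_site`); `ascertainment_proportion()` then reports `n_site / n_total`
with a Clopper–Pearson interval, in percent. The union is per record — a
case both flagged and rule-identified is one case — because site-found
cases were also verifiable by the statisticians; a strict additive mode
(`mode = "sum"`) exists purely for comparison and can double-count.
Records the site flagged but the rule cannot confirm because measurements
are missing stay in the union (they were identified by the site) and are
reported in an `n_unconfirmable` diagnostic column. Structurally
`n_site <= n_total` always; under a zero false-flag rate the union equals
the rule count whenever flags are a subset of labels.

`sensitivity_table()` evaluates this per site over the post-amendment
window, configured as a per-site number of trailing weeks — matching how
measurement collection started at different calendar times per facility.

## Minimum detectable risk

For planning, the observed annual baseline count x/n is inverted into the
smallest effect a future study would detect. Power for two proportions
uses the classical normal approximation with pooled variance under the
null and unpooled variance under the alternative, no continuity
correction:

$$\mathrm{power} = \Phi\!\left(\frac{|p_1-p_0| - z_{1-\alpha/2}\,s_0}{s_1}\right),
\quad s_0 = \sqrt{\bar p(1-\bar p)\left(\tfrac1{n_1}+\tfrac1{n_0}\right)},
\quad s_1 = \sqrt{\tfrac{p_1(1-p_1)}{n_1}+\tfrac{p_0(1-p_0)}{n_0}}.$$

At $p_1 = p_0$ this degenerates to α/2, one rejection tail. The formula
choice was validated two ways: against Monte-Carlo rejection rates of the
z-test (within three Monte-Carlo standard errors at three parameter
points) and by reproducing the published large-site detectable-risk values
to two decimals. Group sizes stay fractional — the computation is a
planning approximation, and rounding to whole subjects would change
third-decimal results for no gain in meaning.

**Cohort (relative risk).** A study of duration $d$ years accrues
$T = d \times$ annual denominator births, split 1:k exposed:unexposed
(default 1:3). The minimum detectable RR is the smallest ratio > 1 whose
power at $(RR\,p_0, T/(1+k))$ versus $(p_0, kT/(1+k))$ reaches the target
(default 0.80 at two-sided α = 0.05), found by bisection on (1, 100] to
tolerance 1e-6. The bracket is capped where $RR\,p_0$ would reach 1, and
an infinite sentinel is returned if even the cap lacks power.

**Case-control (odds ratio).** The expected case series is
$(x/n) \times$ annual denominator $\times d$, with m controls per case
(default 1:1) and exposure prevalence $q_0$ among controls (default 0.25).
A candidate OR implies case exposure prevalence
$q_1 = OR\,q_0 / (1 + q_0(OR-1))$, and the same bisection applies to the
power comparing $q_1$ in cases against $q_0$ in controls.

Confidence bounds on a detectable risk propagate the exact interval of
the baseline rate: the rate's *upper* bound yields the *lower* detectable
bound (more events make smaller effects detectable) and vice versa. This
rate-bound substitution is the natural reading of pairing exact intervals
with the inversion; the original analysts did not state their propagation
operationally, so it is a design choice here.

Two caveats are deliberate. First, detectable risks are only meaningful
for outcomes whose site counts are internally valid; the pipeline defaults
to low birthweight, preterm birth and stillbirth. Second, published
cohort-mode values for the two aggregated-submission sites (e.g. a 4.56
minimum detectable relative risk at one Spanish secondary hospital) are
not reproducible under any per-site cohort computation that also
reproduces every other site under these assumptions, while the same sites'
case-control values are consistent; those two cohort cells likely reflect
a different handling of aggregated-only data and are documented rather
than imitated.

`scenario_grid()` evaluates the Cartesian product of durations, allocation
ratios and control exposure prevalences in one deterministic long table —
the data backend one would put behind an interactive planning dashboard.

## The synthetic cohort generator

No line list from the network is public, so `simulate_site()` generates
one with the statistical structure the downstream stages assume. Per
record: sex (male probability 0.515, the conventional secondary sex
ratio); stillbirth as a Bernoulli per total birth; gestational age from a
two-component mixture — a term component, truncated normal mean 276 d and
SD 8 d on [259, 294], and a preterm component $259 - d$ with $d$
exponential with mean 16 d, truncated so no birth falls below the
profile's viability floor (default 154 d = 22 weeks; the network's
per-site registration floors are not public, so the floor is a parameter
rather than a guess). Birthweight and head circumference are normal around
the reference median with the reference SD for the record's sex and
gestational age, so the implied SGA proportion among fully measured
livebirths is the reference percentile (10%) by construction; a
configurable fraction of head circumferences is redrawn from below the 1st
percentile to represent pathological microcephaly in excess of the
distributional tail. Neonatal death (day exponential with mean 4, capped
at 27 — front-loaded, as observed clinically) and infection (subtype from
the profile's mix) are Bernoulli per livebirth. Missingness then blanks
each measurement independently per the profile.

Imperfect routine surveillance is overlaid by
`apply_site_ascertainment()`: per outcome, a true case is flagged with the
profile's ascertainment sensitivity and a non-case with its false-flag
probability, independently across outcomes — the simplest model consistent
with per-outcome reporting completeness, deliberately ignoring that a site
that misses SGA probably also misses microcephaly.

The packaged `site_profiles.yaml` encodes 21 facility profiles whose
loads, outcome probabilities and ascertainment sensitivities are derived
from the packaged network count tables, so a single
`simulate_network(load_site_profiles(), seed)` produces a structurally
faithful network-scale line list (~85,000 records). Cohort sizes are fixed
at `round(annual_births × duration_weeks / 52)` by default, with Poisson
jitter behind a flag, because fixed counts make tests reproducible; both
are defensible models of a year of deliveries.

What the generator does **not** emulate: seasonality, the pandemic-era
disruption the real network experienced, referral patterns between
facilities, twinning, maternal covariates, or correlation between
missingness and outcome severity (missingness is completely at random
here, while in real facility data sicker neonates are plausibly measured
*more* often). Passing tests therefore demonstrate that the estimators
recover the parameters of this generative model, not that any specific
facility's data meet its assumptions.

## Numerical and testing choices

* All simulation is seeded through a local RNG context (Mersenne–Twister,
  inversion normals) that restores the caller's RNG state, so identical
  (profile, seed) pairs give byte-identical line lists and library code
  never perturbs a user's stream.
* The Clopper–Pearson implementation (beta quantiles) is checked against
  an independent root-finding inversion of the binomial tail sums to
  1e-9 for every x at every n ≤ 200, and the bisection inversion of the
  power function against an exhaustive 0.001-step grid walk on 50
  randomized designs.
* `run_pipeline(verify = TRUE)` re-runs both of those oracle routes over
  every interval and detectable risk in a report and stops on any
  disagreement — an internal double-programming pass, in the spirit of the
  dual independent implementations used for the original analysis.
* Simulation-based tests use one mid-size facility (5,500 annual births)
  over 100 seeds for rate-recovery coverage, and facilities of 800–6,000
  births elsewhere; these sizes make the full suite run in well under a
  minute while leaving Monte-Carlo error far smaller than the tolerances
  being checked.

## Known limitations

Beyond the generator's simplifications above: the power formula is a
normal approximation and will be optimistic for very small case series
(where exact unconditional methods differ); the detectable-risk engine
offers no matched or survival designs and no multiplicity adjustment
across outcomes; rates are site-specific by design, with the totals row
providing summed counts rather than a pooled or meta-analytic estimate;
and the packaged growth reference, being synthetic, should be replaced by
the user's chart of record before any substantive reanalysis of real
measurements.
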