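---
title: "Estimating the lifetime risk of surgery from stratified registry counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the lifetime risk of surgery from stratified registry counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liferisk)
```

## The estimand

The lifetime risk of surgery is the probability that an average newborn
will undergo at least one surgical procedure before dying, assuming
current age- and sex-specific incidence and mortality rates persist. It is
the same quantity routinely reported for cancer or diabetes, applied here
to operative care: a single, interpretable number for health-service
planning ("about 60% of people will have surgery at some point").

The raw material is aggregate: for every calendar year, sex and 5-year
age band (0–4, 5–9, …, 85–89, 90+), the number of surgical procedures
(all procedures, and first-ever procedures per person), the mid-year
population, and all-cause deaths. No individual-level records are needed,
which is why the method works from routinely published tables.

## From counts to rates

For a period (one or more calendar years), exposure in band $x$ is
approximated as person-years $P_x = \sum_{\text{years}} N_x \times 1$
with $N_x$ the mid-year population — the standard demographic
approximation. Incidence and mortality rates are pooled over the period:

$$\lambda_x = \frac{\sum E_x}{P_x}, \qquad \mu_x = \frac{\sum D_x}{P_x},$$

with $E_x$ either first events or all events depending on the event
definition, summed over the period's years (pooled counts over pooled
exposure, not an average of yearly rates). First-event rates never exceed
all-event rates, and all-event rates may exceed one per person-year: a
person can have several procedures.

The mortality rate is the all-cause rate of the tabulated population; the
package does not attempt to separate mortality of people who have already
had surgery from mortality of those who have not.

## The life-table estimator

The primary estimator treats first surgery and death as competing risks
with constant hazards within each band. With total hazard
$h_x = \lambda_x + \mu_x$ and band width $n_x$, the probability that a
person entering band $x$ event-free has a first surgery within the band
is

$$a_x = \frac{\lambda_x}{h_x}\left(1 - e^{-h_x n_x}\right),$$

and the probability of reaching the next band alive and event-free is
$s_x = e^{-h_x n_x}$. The open final band (90+) is followed to
extinction: $a = \lambda/h$, $s = 0$, so the 90+ row of the output is the
full lifetime risk. Starting from a radix $l_0$ (100 000 by convention;
results are radix-invariant), $l_{x+1} = l_x s_x$, expected first events
are $d_x = l_x a_x$, and the cumulative risk by the end of band $x$ is
$\sum_{y \le x} d_y / l_0$. The per-band cumulative risks are the
age-conditional column reported in national lifetime-risk tables.

Two conversion conventions exist in the life-table literature: the
exponential form above and mid-interval (Chiang-type) approximations
$q = n r / (1 + n r / 2)$. They agree to the second decimal at the rates
seen here; the package uses the exponential form because it is exact
under the piecewise-constant hazard model, which makes the estimator
provably consistent against the package's own generative model (see
below). `band_transition()` is the single point where this choice lives.

For the "all surgery" definition the same machinery is applied to the
inflated all-event rate; the result is interpreted as the risk of at
least one procedure under that rate, which is why it exceeds the
first-surgery risk while staying below 100%.

## The cumulative-incidence estimator

The secondary estimator ignores competing mortality:

$$\text{risk} = 1 - \exp\!\Big(-\sum_x \lambda_x \tilde n_x\Big),$$

where $\tilde n_x = n_x$ for closed bands. The open band has no natural
width, so it is truncated at `final_band_width` years (default 10,
i.e. following the cohort to roughly age 100 under the default schema);
the truncation is configurable because published analyses rarely state
it. Because death never removes anyone from the at-risk pool, this method
always reports at least the life-table value — the gap between the two is
a direct measure of how much competing mortality suppresses the
achievable risk, and is larger for men, whose mortality is higher.

## Confidence intervals and the period comparison

*Multi-year periods.* Yearly lifetime risks are averaged; the interval is
$\bar x \pm t_{0.975,\,k-1}\, s/\sqrt{k}$ over the $k$ years. With $k=4$
pre-pandemic years a t quantile (not a normal one) matters: the 97.5%
point on 3 degrees of freedom is 3.18, not 1.96. Per-band risks are
averaged and intervalled the same way.

*Single years.* The pandemic period is one year, so no between-year
dispersion exists. `single_year_ci()` instead redraws every stratum's
event and death count independently as Poisson with the observed count as
mean, recomputes the lifetime risk per replicate (5000 by default), and
reports percentile 2.5/97.5 bounds. The choice of a parametric count
bootstrap reflects what the data are: large Poisson-like counts with
fixed exposure. The interval is deterministic given a seed.

*Comparison.* `compare_periods()` reports the absolute change in
percentage points, the relative change as a percent of the pre value,
whether the two 95% intervals overlap, and a two-sided paired t-test.
The pairing unit is the 19 age bands of the per-band cumulative risk
curve (19 pairs, 18 degrees of freedom); the unit is recorded in the
output because other pairings (years, sexes) are conceivable and would
change the test. Adjacent bands of a cumulative curve are correlated, so
the t-test should be read as a descriptive summary of a systematic shift
across the whole age range rather than as an exact inference.

*Presentation.* Risks are reported to one decimal and relative changes to
the nearest integer, rounding half away from zero (`round_half_up()`),
only at the presentation layer — internal values are never rounded.

## The synthetic registry generator

Real hospital-episode extracts are access-controlled, so the package
ships a generative stand-in. Each individual carries three
piecewise-constant hazards per band: mortality $\mu_x$, first-surgery
$\lambda_x$ (acting while event-free), and a recurrence rate $\rho_x$
(a Poisson process from first surgery until death, the simplest mechanism
that makes all-event counts exceed first-event counts). For every
calendar year and sex a fresh birth cohort is simulated and its whole
life course is tallied as that year's stationary cross-section.

One convention matters: the emitted population and death tables describe
the **event-free (at-risk) population** — person-time and deaths are
counted only up to the first surgery. Under this convention events,
population and deaths are mutually consistent with the life-table model,
so the pipeline's rates are unbiased estimates of the generative hazards
and the full pipeline recovers the generator's analytic lifetime risk
(`analytic_lifetime_risk()`, the exact first-passage probability
$\sum_x S_x a_x$). That property is what makes the generator useful as a
test oracle: parameter recovery and interval coverage can be checked
against a known truth. Real national denominators are *not* event-free —
mid-year population estimates include people who have already had
surgery — so rates from real data underestimate the event-free hazard at
older ages and the published estimator inherits a conservative bias that
the synthetic tables deliberately do not reproduce. Other features of
real data the generator does not emulate: migration, cohort-to-cohort
rate trends, finite record history (which inflates observed "first"
surgeries), coding artefacts (such as male infants removed alongside
obstetric episodes), and private-sector activity. Passing tests
demonstrate internal statistical correctness of the estimators, not
fidelity of any particular real-world figure.

### Default parameters

The defaults emulate the English 2016–2019 surgical population:

* **Mortality**: an England-like all-cause schedule rising from
  $\sim 10^{-4}$ per person-year in childhood to 0.22 at 90+, scaled
  1.25× for men and 0.85× for women (reflecting the male–female life
  expectancy gap).
* **First-surgery hazards**: inverted band-by-band from the published
  England cumulative first-surgery risk profile under that mortality
  schedule, so the analytic lifetime risks are 0.602 (women) and 0.591
  (men).
* **Recurrence**: $\rho_x = 1.45 \lambda_x$ (women) and
  $1.0 \lambda_x$ (men), chosen so the simulated all/first event ratio is
  about 1.96, matching the national totals (23.4M procedures, 11.9M first
  procedures over 2016–2020).
* **Obstetric fractions**: 15%–50% of female events in the 15–44 bands
  are labelled obstetric, peaking at 25–34; zero elsewhere and for males.
  Excluding the category therefore lowers female estimates and leaves
  males untouched.
* **Pandemic scenario**: `pandemic_scenario()` multiplies $\lambda$ (and
  $\rho$) by 0.66 and $\mu$ by 1.14 for one year, mirroring the observed
  one-third fall in surgical volume and the 2020 excess-mortality rise.
* **Cohort size**: 100 000 per sex and year by default — large enough
  that a single simulated year pins the lifetime risk to a few tenths of
  a percentage point.

One RNG stream is split off the master seed per (year, sex), so adding a
year or a sex never perturbs the other strata's draws, and identical
seeds give bitwise-identical tables.

## Numerical and degenerate-input choices

* Zero total hazard in a closed band: survival 1, event probability 0.
  Zero total hazard in the *open* band would make the cohort immortal and
  event-free; the life-table functions warn and treat it as risk 0, and
  the simulator refuses it (the cohort cannot be followed to extinction).
* Strata with zero person-years raise an error if they contain events,
  otherwise the rate is 0 with a warning.
* The bootstrap recomputes risks on rate *matrices* (replicates × bands)
  with a triangular-matrix cumulative-hazard product rather than a loop,
  keeping 5000 replicates effectively instantaneous.
* Ties in `max_successive_increase()` (within $10^{-8}$, which absorbs
  float noise on one-decimal published values) resolve toward the older
  band pair, consistent with published reporting of the male
  first-surgery maximum, which is tied at one decimal.
* The simulated mid-year population is rounded to whole persons; a
  stratum with events or deaths is floored at 1 so validation never sees
  activity without exposure.

## Problem sizes used by the test-suite

The suite checks oracle equivalence (life table vs analytic first-passage
formula) to $10^{-12}$ on 20 random hazard sets; Monte-Carlo agreement of
both estimators at $10^6$ simulated individuals; end-to-end parameter
recovery at cohort size $10^5$; interval coverage over 200 simulated
single-year registries of 20 000 individuals at 1000 bootstrap
replicates; and a pandemic scenario at cohort size $10^5$ across both
methods and both event definitions. These sizes keep every statistical
check's Monte-Carlo error well below the tolerance it asserts.

## Known limitations

* Period, not cohort, estimates: the number answers "what if today's
  rates persisted", not the prognosis of any birth cohort under changing
  rates.
* The whole-population denominator approximation of real registry data
  (discussed above) is inherited by design when the package is run on
  real tables.
* The paired t-test across age bands ignores the serial correlation of a
  cumulative curve.
* No direct age standardisation, rate smoothing, cause-specific
  mortality decomposition, or projection of future rates.
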