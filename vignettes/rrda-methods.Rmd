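---
title: "Curating and analysing longitudinal GP event data with rrda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and analysing longitudinal GP event data with rrda}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Raw general-practice (GP) event extracts are noisy: rows arrive with missing
person identifiers, dates or practice identifiers; events are re-inserted as
exact copies; GP-to-GP record transfer re-files the same clinical event under
a new practice; some events belong to periods when the person held no valid
GP registration; and the clinical codes mix an official 5-character
terminology (Read V2), numeric SNOMED-CT concept identifiers, supplier-local
(EMIS/Vision) codes, undocumented legacy codes and outright malformed
strings. `rrda` turns such an extract into a research-ready data asset
(RRDA): a validated, de-duplicated, normalised three-table store, plus the
two analysis stages built on it — population-coverage models and monthly
activity-trend models — and a synthetic data generator that makes the whole
pipeline testable end to end.

## Curation model

Curation is a fixed sequence of set operations on the event table, each a
pure function with an explicit contract:

1. **Cleaning** — drop rows missing any of person id, event date or practice
   id. Each dropped row is counted once, under the first missing field.
2. **Registration validation** — an event must fall inside a GP registration
   spell of its person. Spells are half-open `[start, end)`: an event on the
   start date is inside, on the end date outside, so a same-day practice
   transfer yields exactly one active practice. Where spells overlap
   (source-system noise), the spell with the latest start wins, ties broken
   by smallest practice id; both choices are arbitrary but deterministic.
   The registration-derived practice is *annotated* as
   `canonical_practice_id` rather than overwriting the recorded practice —
   overwriting here would make the GP-to-GP comparison in step 4 vacuous.
3. **Exact de-duplication** — one representative (smallest source row id)
   per group of rows identical on all recorded fields. Clinical values are
   compared as trimmed strings, never as floats, so identity is exact.
4. **GP-to-GP de-duplication** — rows identical except for the recorded
   practice are treated as transfer copies. The row whose recorded practice
   matches the canonical practice is retained; when none matches the
   smallest practice id is kept (the source data give no better signal).
   Only after this step does the canonical practice become the output
   practice.
5. **Code resolution** — every code resolves (see below); resolution is
   total by construction, so no event is lost at this stage.
6. **Normalisation** — one *person-day* row per distinct
   (person, date, practice) with dense integer keys, a clinical-event table
   keyed by person-day, and the code look-up as the third table. Joining the
   three tables reproduces the de-duplicated event multiset exactly, which
   the tests assert.

Record counts are non-increasing across steps, and the pipeline is a fixed
point on its own output: re-curating a curated RRDA drops nothing.

## The code look-up

Non-SNOMED codes are standardised to the 5-character level: truncated if
longer, right-padded with `"."` if shorter; case is preserved because Read
V2 is case-sensitive. "Basic format validation" is made concrete as an
explicit alphabet — letters, digits, `.`, `-`, `%`, `_`, at most 7
characters before standardisation — anything else is *blank/invalid*.
SNOMED identifiers bypass standardisation and are stored verbatim.

When the same standardised key appears in several source lists, the entry is
retained by code-type priority — official Read V2, SNOMED-CT, local Vision,
local EMIS, additional Read/Vision, additional EMIS — regardless of input
order, so a code present in both a Read and an EMIS list is a Read code.
Within a type, the first description by source order wins and the loser is
logged as a collision. Structurally valid codes absent from every list
become *unknown* entries; malformed forms become *blank/invalid* entries.
These two supplementary categories make resolution total: every event in
the RRDA has a code id.

## Four-layer classification and activity categories

Each code is classified on four layers — care provider, access mode,
interaction type, interaction detail — by an ordered rules engine: exact
code match beats the longest matching code prefix, which beats
case-insensitive keyword match against the code description. Assignments
are validated against the hierarchy (for example, a drug-prescription
detail can only sit under the clinical-data access mode, and non-primary
providers carry no lower layers). SNOMED codes are excluded from
classification and stay unassigned.

Person-days are then categorised into eight activity types (consultation,
prescription-only, vaccination, administrative-only, certificate,
review/monitoring, screening/assessment, failed encounter) from the
assignments of that day's events. Categories form a set, not a partition.
Two deliberate readings of the definitions:

* A certificate is patient-admin data with access mode ADMIN, *and* the
  consultation criterion lists certificates; a certificate-only day is
  therefore simultaneously `ADMIN_ONLY`, `CERTIFICATE` and `CONSULTATION`.
  We keep this triple co-occurrence.
* A day consisting solely of failed encounters would, read literally, also
  be administrative-only (failed encounters are admin-mode records), while
  failed encounters are meant to be exclusive. `ADMIN_ONLY` therefore
  additionally requires that not every event is a failed encounter. This is
  the one place the implemented definition departs from a literal reading,
  and it is what makes the failed-encounter exclusivity invariant hold.
* The remote-prescription consultation criterion requires a qualifying
  remote or visit record to exist anywhere within the person-day; it need
  not be the prescription record itself.

Prescription-only and consultation can never co-occur: a prescription-only
day contains no remote/visit record, so the second consultation criterion
cannot fire. The tests assert both invariants over every generated
person-day.

## Coverage analysis

Residence on a 1-July snapshot requires a Welsh LSOA spell covering the
date and either gap-free Welsh residence over the preceding three months or
birth within them. "Three months" is three *calendar* months
(`date %m-% months(3)`), not 90 days; back-to-back spells count as gap-free
under the half-open convention. Coverage holds when the active
registration's practice shares data, or any later registration spell is
with a sharing practice (historic records added retrospectively).

The annual panel (year x sex x age group x deprivation quintile x health
board, residents and covered residents) is modelled as a binomial GAMM:
logit link, penalized thin-plate spline over year (basis dimension 10),
covariate fixed effects (one covariate unadjusted, all adjusted), and an
AR(1) process between year-on-year observations within each stratum.
Reference levels are male, ages 0-15, quintile 1, Betsi Cadwaladr.

Estimation uses `glmmTMB`: the AR(1) series is a latent Gaussian process
per stratum (`ar1()` covariance) and the spline enters through its
mixed-model representation, all estimated by maximum (Laplace) likelihood.
We considered the penalized-quasi-likelihood route (`mgcv::gamm`, which
wraps `nlme`) and rejected it after simulation: with the smoothing
parameter estimated jointly, the year spline absorbs much of the AR(1)
signal and the correlation parameter is recovered at roughly half its true
value, whereas the marginal-likelihood fit recovers both the covariate
odds ratio and the correlation without bias worth worrying about. The
model contract here is parameter recovery, verified by simulation in the
test suite: 200 replicated 35-year, ten-stratum panels with a true odds
ratio of 1.10 and AR(1) 0.5, with the mean estimated odds ratio required
within 0.02, empirical interval coverage within [90%, 98%], and the mean
AR(1) estimate within 0.1.

## Activity-trend analysis

The analysis outcome is the average daily number of person-days per month
per 100,000 GP-registered covered people:
`rate = (n / days_in_month) / population * 1e5`. The monthly population
denominator is linearly interpolated between annual 1-July snapshots of the
covered population (the paper-style offset is "the GP-registered
population"; we use the covered population, since only covered persons can
contribute events).

Monthly counts are modelled as negative binomial with log link and offset
`log(population / 1e5 * days_in_month)`, a cyclic penalized cubic
regression spline over calendar month (period 12, basis dimension 8, knots
at the month boundaries), a thin-plate trend spline over continuous time
(basis dimension 20 for 25 years), and AR(1) errors between consecutive
months. Pandemic-disrupted years (2020-2021; 2021-2022 for vaccination,
matching the COVID-19 vaccination-programme rollout) are omitted from
fitting entirely, so the fitted model provides counterfactual expected
rates for those months and observed-vs-expected percentage deviations.

Fitting of the seasonal-trend model is two-stage, the standard route for
this model family: the dispersion is estimated by REML in a working
independence fit (`mgcv::gam(family = nb())`), then held fixed while
`mgcv::gamm(family = negbin(theta), correlation = corAR1())` estimates the
smooths and the AR(1) parameter by penalized quasi-likelihood. A fully
marginal likelihood with free dispersion, free AR(1) and flexible trend on
a single 300-month series is weakly identified — in our simulations it
collapsed (dispersion to infinity, correlation to 0.93). In the trend model
the AR(1) parameter is only weakly identified (confounded with the
dispersion); expected rates and deviations, the quantities this model
reports, are insensitive to that.

The year-categorical model replaces the trend spline with calendar year as
a factor (reference 2019); no trend smooth is retained alongside the year
factor, so the factor absorbs the full between-year structure. Its point
estimates come from the REML negative-binomial fit, exponentiated into
rate ratios. Its interval standard errors need more care: a year factor
absorbs every year's mean, and the autocorrelation of the resulting
residuals is biased far towards zero (the classic demeaning bias at block
length 12), so both quasi-likelihood and joint-likelihood routes
underestimated the rate-ratio uncertainty badly in simulation. We
therefore fit an
AR(1)-plus-white-noise working covariance on the log-scale residuals by
matching their empirical autocovariances to closed-form expectations under
12-month-block demeaning, and propagate that covariance into the
year-contrast Wald intervals. The test
suite verifies the resulting intervals by simulation: across replicated
null series the yearly rate-ratio intervals must contain 1 close to the
nominal 95% of the time, and across 200 series with a true +8% final-year
shift the mean recovered rate ratio must lie within 0.02 of 1.08. The
`endpoint_change()` helper reproduces printed endpoint contrasts with the
printing conventions used for them: percent change rounded to the nearest
integer, ratio to one decimal.

## The synthetic generator

The generator emulates the structure of national GP data, not its clinical
content: persons with sex, birth date, deprivation quintile and health
board; residence histories (about 10% of persons move out of and back into
Wales, creating gaps and non-Welsh spells); registration histories that
partition residence spells into 1-3 practice spells with occasional
unregistered lead-ins; and a practice network whose data-sharing flags are
Bernoulli at the configured fraction (a *static* attribute — the data give
no onboarding dates, so temporal onboarding is out of scope).

Events arise per person-month and activity category from a log-linear
Poisson intensity: `log λ = log(base/12) + trend·years +
amplitude·cos(2π(month − peak)/12) + pandemic log-multiplier`, thinned by
the fraction of the month actually covered by a registration spell and
dated uniformly over the covered days — so every clean event lies inside a
registration spell by construction. Default magnitudes are chosen once as
realistic for UK general practice: ~5 consultation and ~6 prescription-only
days per person-year, 0.7 vaccination days with a sharp October peak
(cosine amplitude 2.5 — flu-campaign seasonality is strongly concentrated,
and this is what makes October the annual maximum in ≥90% of simulated
years), long-run trends matching the published national endpoint contrasts
(+90% consultations, +107% prescription-only over 25 years), and pandemic
windows (consultations ×0.6 during 2020/21, vaccination ×3 during 2021-22).

Each generated bundle carries codes from pools whose four-layer assignment
is fixed by construction; 15% of consultation bundles are a
remote-prescription pair (prescription code plus phone-contact code) to
exercise the second consultation criterion. The ground-truth category set
of every person-day is computed from these known assignments by a second,
direct implementation of the eight definitions, kept separate from the
rules-engine path so the two can disagree if either is wrong.

Corruption is injected into disjoint row samples drawn from one
permutation, so the ledger partitions injections: field blanking,
out-of-registration re-dating (always before the person's first spell, so
the event is provably uncovered), exact and GP-to-GP duplicate appends, and
code swaps to malformed or undocumented strings. Every injection is
ledgered with its clean twin, which is what lets the tests demand *exact*
consort accounting per curation step rather than approximate retention.

What passing these tests does **not** show about real data: the generator's
duplicates are verbatim copies, whereas real transfer duplicates sometimes
mutate values; its code usage is stationary within source, with no
terminology drift like the post-2018 shift away from Read V2; and its
corruption is independent of person and time, while real missingness is
strongly period-dependent. The pipeline's correctness claims (exact
de-duplication, totality of code resolution, lossless normalisation) do not
depend on those features; its realism claims would.

## Numerical choices and problem sizes

Seeded determinism is end-to-end: one root seed derives a fixed per-stage
stream, and rerunning any stage with the same configuration reproduces its
outputs byte-for-byte (the run manifest hashes every artefact). Simulation
studies in the test suite use 200 replicates for both recovery studies
(35-year coverage panels; 25-year monthly series at national count
magnitudes, where dispersion and latent noise are identifiable), 100
replicates for the null interval-coverage study, 20 replicates for the
single-month shock, and a 2,000-person, 10-year cohort for the end-to-end
demonstration run. Wald intervals are used throughout for effect
summaries. Degenerate inputs fail loudly and early: zero or missing
population months, a missing reference year, panels with fewer than two
years, series with fewer than 36 non-excluded months.

## Known limitations

* The AR(1) parameter of the trend models is reported but only weakly
  identified at realistic dispersion; treat it as a diagnostic.
* The binomial coverage model assumes the latent AR(1) process is the only
  extra-binomial variation; real coverage series have practice-level
  onboarding shocks it smooths over.
* Keyword rules match descriptions, so description quality bounds
  classification quality; real Read V2 rule sets are not shipped.
* Rate-ratio models fit all years by default; if pandemic years are
  excluded there, their rate ratios are simply absent rather than
  counterfactual.
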