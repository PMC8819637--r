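---
title: "Micro-costing community-based PrEP delivery: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-costing community-based PrEP delivery: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prepcost)
```

## The costing problem

Community-based HIV counselling and testing (CBCT) platforms can deliver oral
PrEP to adolescent girls and young women close to where they live, together
with counselling that supports effective use. Whether health systems can
afford such delivery depends on its unit cost. `prepcost` implements an
ingredients-based (micro-)costing of that service from a provider
perspective, in the style of the Global Health Cost Consortium reference
case: every input — staff minutes, laboratory tests, drug, capital, overheads
— is priced and aggregated, and the headline result is the

**cost per person-month of PrEP** = total annual cost / person-months of PrEP
dispensed.

Three service models are costed: standard care (nurse-run community
dispensary, passive adherence support), clubs (group effective-use
counselling by a lay counsellor, groups of 7) and individual (one-on-one lay
counselling). Three scenarios re-price the same service:

1. **as implemented** — study salaries and study prices, trial client volume
   (603 initiators, 1280 person-months over one year);
2. **DoH** — South African Department of Health salaries, public-sector test
   prices (HIV serology \$4.44, HBsAg \$10.12), published public-sector drug
   cost, guideline test schedule, same client volume;
3. **scaled DoH** — DoH prices at full clinic capacity.

## Cost taxonomy and ledger model

Costs are *fixed* (capital, training, demand creation, supervisory personnel,
site overheads, administrative supplies) or *variable* (service-delivery
personnel time, PrEP medication, miscellaneous medical consumables, and the
HIV, HBsAg, creatinine, pregnancy and syphilis tests). Expenditure enters as
an itemized ledger (`date, category, amount, currency, service_model`) over
the costing window 2018-11-01 to 2019-11-01; entries outside the window are
rejected. Site-level entries (`service_model = "shared"`) are attributed in
full to each model, which is why fixed rows are identical across the three
models within a scenario. Amounts in ZAR convert at 14.31 ZAR per USD;
arithmetic is at full precision, with 2-decimal rounding only in renderers.

Syphilis testing belongs to the service package but carried zero recorded
cost in every scenario; it is kept as a zero-cost category rather than
invented or dropped. Capital and demand-creation totals are held equal across
scenarios (the programme runs inside existing platforms); the other fixed
categories are scenario-specific ledger inputs — they are audited totals, not
quantities this package recomputes from first principles.

## Time-and-motion module

Each observation times one staff member through one visit as segments flagged
`service`, `waiting` or `research`; only service segments count
(`active_minutes()`). The same log feeds two summaries:

- **medians and IQRs** of combined nurse + social-worker visit time, for
  reporting (`summarize_durations()`); quartiles use linear interpolation
  between order statistics (`stats::quantile` type 7) — a convention the
  source material does not fix, chosen and held constant;
- **cell means** per (model, visit type, role), for costing
  (`build_profile()`), because personnel cost is mean minutes × cost per
  minute. Initiation procedures are identical in all arms, so initiation
  observations are pooled and the pooled mean replicated into each model.

The published mean profile (`reference_staff_times()`) is the authoritative
costing profile: e.g. initiation takes 19 social-worker + 34 nurse minutes in
every arm; a standard-care monthly refill takes 6 nurse minutes; club monthly
counselling takes 41 social-worker minutes *per group* (flagged `per_group`),
while the club nurse still dispenses per client. Reminder calls/texts are a
distinct visit type costing 2 social-worker minutes per participant-visit,
charged to variable personnel cost in all arms. Note the published per-role
column totals (55 nurse minutes in standard care, 75 social-worker minutes in
the individual model) differ by one minute from the sums of the printed cells
(56 and 74); this package always recomputes totals from cells.

## Costing engine

- **Personnel**: cost per minute = annual salary / (260 days × 8 h × 60 min);
  equivalently hourly = annual / 2080 (as-implemented nurse:
  `r round(hourly_cost(reference_salaries("as_implemented"), "nurse"), 2)`
  USD/h). Variable personnel cost sums minutes × rate × events over visit
  types and roles; per-group club cells are charged once per
  `ceiling(visits / group_size)` sessions. Counsellor salaries are
  model-specific as implemented (club \$5963.09, individual \$4587.16 a
  year; standard-care social-worker minutes are priced at the individual
  counsellor rate, a choice the source leaves open) and a single lay-counsellor
  wage (\$2318.16) under DoH.
- **Capital**: annuity-factor annualization, `price·r/(1−(1+r)^−life)`,
  r = 3 % (0–5 % supported), life 3 years; the r = 0 limit is straight-line.
  The annuity form is the standard reference-case choice; tests verify the
  identity that the discounted annualized payments return the purchase price.
- **Overhead**: total site overhead × fraction of client activities that are
  PrEP visits.
- **Tests**: unit cost × tests done. Event rules: HBsAg once per initiation;
  HIV serology at initiation and every attended quarterly visit (the
  3-monthly retesting rule); creatinine excluded under DoH scenarios (not
  essential for well AGYW); pregnancy testing free under DoH (family-planning
  service, initiation only).
- **Medication**: monthly supply cost (\$11.00 as implemented including
  importation/storage/distribution; \$4.72 DoH) × person-months.

## Scenario assembly and the role of audited totals

`run_scenario()` builds one cost column: fixed categories pass through from
the scenario's ledger; variable categories are computed by the engine *unless
the scenario supplies an audited total as an override*. The built-in
scenarios (`reference_scenario()`) supply the published per-category annual
costs as overrides, because several published variable totals cannot be
recovered from the published unit inputs alone: exact attended-visit counts
were never released, and reconstructing them (603 initiations, follow-ups
split by each model's published visit mix — 54/35/11 % for standard care,
63/27/10 % clubs, 46/40/14 % individual) prices the per-visit minutes at
roughly a third of the published variable personnel totals, which evidently
include PrEP personnel time beyond the per-visit service minutes. The engine
path is therefore verified against independent hand-computed oracles and used
for user-supplied scenarios, while the published columns reproduce exactly
from the audited inputs. Unit-cost columns are annual cost / person-months;
the as-implemented costs per person-month that equal total/1280 at full
precision (105.71 / 105.58 / 106.09) are the authoritative ones, and the
2-decimal unit-cost rows reproduce annual costs only to within the half-cent
× 1280 rounding bound, which is how the tests bound them.

Comparison metrics: `percent_increment()` is `100·(cpm_model −
cpm_sc)/cpm_sc` rounded to whole percent (at scale: individual +89 %, club
+11 %); `driver_shares()` is category/total as whole percents (as
implemented, fixed personnel 40 %, admin 18 %, medication 10 %). Note the
whole-percent convention makes some republished shares differ by one point
when recomputed (e.g. DoH fixed personnel recomputes to 58 %), and the DoH
total is 47.5 % below the as-implemented total under total-ratio arithmetic;
this package always reports the computed value.

## Capacity model

Nurse and social worker work in series, so the clients a site can serve per
day is limited by the *bottleneck* role — the one with the larger total
service time (ties go to the nurse). `daily_capacity()` finds the largest
whole `N` with mix-weighted bottleneck minutes ≤ the working day (480
productive minutes, matching the 8-hour salary assumption; the source does
not state a capacity day length), charging club groups stepwise via
`ceiling`. Under the published times and mixes this gives 21 (standard care,
nurse-limited), 30 (club, social-worker-limited but amortized over groups)
and 20 (individual) clients/day, i.e. 5460 / 7800 / 5200 annual person-months
at one month dispensed per attended visit over 260 days.

The published at-scale denominators (10,171 / 9360 / 5069 person-months) are
not derivable from the published staff times and mixes alone — the underlying
capacity worksheet is unavailable, and no parameterization of the stated
bottleneck formula reproduces either the magnitudes or the strict ordering
(the grouped club counselling necessarily lifts club throughput above the
nurse-limited standard-care 21/day, while the published volumes put standard
care first). The scaled-DoH scenario therefore takes person-month volumes as
**inputs**, defaulting to the published values, and the capacity model is
exposed as a documented, parameterized estimator whose monotonicity
properties (non-increasing in per-visit times, non-decreasing in day length
and group size) are tested.

## Synthetic-data generators

All generators are pure functions of `(config, seed)` and emulate the study
conditions; they exist so the ingestion path is exercised, not to re-estimate
the published numbers.

- **Enrolment/visit log**: 603 initiators, arms 1:1:1, monthly visits at
  months 1, 2, 4, 5, 7, 8, 10, 11 and quarterly at 3, 6, 9 (12-month cap),
  one month dispensed per attended visit. A single geometric dropout cannot
  match both the reported median of 1 month (IQR 1–2) and the mean of
  1280/603 = 2.123 months, so retention is two-stage: return after the
  initiation month with probability 0.45, then continue month-to-month with
  probability 0.5994, giving median 1 and mean 1 + 0.45/(1 − 0.5994) = 2.123.
  Arms share one retention curve (arm differences were shown graphically but
  never quantified).
- **Observation log**: 50 observations (9 initiation, 15 standard care, 8
  club, 18 individual; follow-ups split ~2:1 monthly:quarterly), log-normal
  service segments located at the reported visit-level medians split by role,
  `sdlog` 0.3 (right-skew comparable to the reported IQR asymmetry, e.g.
  51 (46, 63)), plus waiting and research segments that processing must strip.
  Tests bound median recovery by the sampling error of a log-normal sample
  median, `exp(2.58·sdlog/√n)`, since the smallest cells hold only 2–3
  observations.
- **Ledger**: each (model, category) target split into 1–10 items with random
  in-window dates; the final item takes the remainder, so aggregation
  recovers targets exactly by construction.

What passing these tests does *not* show about real data: the generators have
no site structure (the trial ran one rural and one urban site; everything
here is site-pooled, as the published tables are), no seasonality, no
arm-specific retention and no observer effects in the timing data.

## Problem sizes and determinism

The test suite and acceptance script run the full nine-column costing (a few
hundred arithmetic operations), 20-seed Monte-Carlo checks of the enrolment
generator (603 participants each) and single-seed observation/ledger checks —
seconds of compute in total, the natural scale of the problem. Every
stochastic quantity flows from an explicit integer seed; identical inputs and
seed give byte-identical outputs.

## Known limitations

- The engine's variable-personnel path underestimates the audited personnel
  totals for the reasons above; audited totals are preferred wherever they
  exist.
- Back-derived test counts (e.g. creatinine and pregnancy as implemented) are
  reconstructions, flagged as such, not published data.
- No cost-effectiveness, budget-impact or probabilistic sensitivity analysis;
  the outputs here are the unit-cost inputs such analyses would consume.
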