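---
title: "The diaspora extrapolation model for FGM/C prevalence and risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The diaspora extrapolation model for FGM/C prevalence and risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgmcprev)
```

## The model and its assumptions

Direct, survey-based measurement of female genital mutilation/cutting
(FGM/C) is not feasible in a diaspora, where the practice concerns only
immigrant minorities. The extrapolation model sidesteps this by combining
two data sources that *are* available: origin-country survey prevalences
(DHS/MICS) and a population register of the resident immigrant population.
The core assumption is that a woman who migrated *after* the ages at which
cutting is customarily performed in her origin country carries the origin
country's prevalence with her, while cutting *after* migration is assumed
not to occur at all — there is consistent evidence of attitude change in
migration contexts, and no reliable incidence data to support any other
number. The model therefore produces a point estimate for those already
subjected, and brackets the future-risk estimate between two scenarios
instead of pretending to know a post-migration incidence rate.

Every quantity is computed per origin country and summed; there is no
pooling of prevalences across countries.

### Cohorts

For a country with customary cutting-age window
$[a_{\min}, a_{\max}]$, each female resident is assigned exactly one label
from her generation, age at arrival $a_{\mathrm{arr}}$ and age at the
reference date $a_{\mathrm{ref}}$ (both in completed years):

* **1a** — first generation, $a_{\mathrm{arr}} > a_{\max}$;
* **1c** — first generation, $a_{\mathrm{arr}} \le a_{\max}$ and
  $a_{\mathrm{ref}} \le a_{\max}$;
* **1b** — first generation, $a_{\mathrm{arr}} \le a_{\max}$,
  $a_{\mathrm{ref}} > a_{\max}$ and $a_{\mathrm{ref}} < 18$;
* **1x** — first generation, $a_{\mathrm{arr}} \le a_{\max}$ and
  $a_{\mathrm{ref}} \ge 18$;
* **2a** / **2b** — second generation under / at-or-over 18.

The upper margin of the window is the cut-off: "arrived older than the
customary age" is read strictly ($a_{\mathrm{arr}} > a_{\max}$), "younger
than or within" as $a_{\mathrm{arr}} \le a_{\max}$, and "under 18" as
$a_{\mathrm{ref}} < 18$, so a girl on her 18th birthday is out. Second
generation means **both** parents from one of the listed countries; with
two different listed countries the mother's country attributes the record,
and one or zero listed parents excludes it (the risk is too uncertain and
most likely low to extrapolate anything onto such girls).

The **1x** bucket deserves a note, because five-cohort published count
tables have no column for it. Women who arrived young but have since turned
18 belong neither in the undergone numerator (the model assumes they were
not cut: they arrived below the window) nor in any at-risk group (they are
adults). Folding them into 1a would inflate the undergone estimate. The
package therefore carries 1x as its own label, includes it in the
denominator population, and offers `fold_g1x = TRUE` in `tabulate_groups()`
only for table-shape compatibility.

### Estimates

With $p_{49}$, $p_{19}$ the 15–49 and 15–19 prevalences, $s_{49}$,
$s_{19}$ the type-III shares of each, and $f \in [0,1]$ the migration and
acculturation impact factor applied to the second generation:

$$U_c = N_{1a,c}\, p_{49,c}, \qquad
  PAR_c = N_{1b,c} + N_{1c,c} + N_{2a,c}, \qquad
  R_c(f) = \bigl(N_{1b,c} + N_{1c,c} + (1-f) N_{2a,c}\bigr)\, p_{19,c}.$$

$f = 0$ is the high-risk scenario (migration changes nothing), $f = 1$ the
low-risk scenario (migration removes the second generation's risk; the
first generation cohorts 1b/1c remain fully at risk in both scenarios).
The canonical formulation treats $f$ as binary and selects a scenario from
qualitative evidence; `scenario_config(acculturation_factor_gen2 =)`
additionally accepts intermediate values so partial attitude change can be
expressed, defaulting to computing both scenario presets.

The at-risk base deliberately keeps first-generation girls who are already
past the customary window but still under 18 (cohort 1b): in a migration
context the *opportunity* to cut (e.g. a visit to the origin country)
matters more than the customary age, so excluding them would understate
risk. The only first-generation girls excluded from the risk base are
those who arrived older than the window (they are in the undergone
estimate instead) and those now 18 or older.

## Parameters and conventions

* **Reference date** — default `2013-01-01`; all cohort ages are evaluated
  at this date, and generated arrival dates fall strictly before it.
* **Age convention** — birthday-based completed years; the anniversary
  itself counts as attained, and leap-day births attain their birthday on
  1 March of non-leap years. Some register statistics use calendar-year age
  (reference year minus birth year); `age_mode = "calendar_year"` provides
  it, but the default is birthday-based because the cohort definitions are
  phrased in exact ages.
* **Rounding** — per-country estimates are rounded half-away-from-zero by
  default (`"half-even"` available). National totals are sums of *rounded*
  per-country values, which is how published country tables are usually
  assembled. Exact .5 ties essentially never occur with three-digit
  prevalences; a `1e-9` epsilon in the rounding guards against binary
  representation error in products of decimal inputs.
* **Type-split conventions** — the undergone split uses the *complement*
  convention (type III rounded from the unrounded base, other types = total
  − type III, so the pair sums exactly); the at-risk split rounds both
  cells *independently* from the unrounded base, so the pair may differ
  from the rounded scenario total by one. Published tables of this kind
  use both conventions; each is available for either split via
  `scenario_config()`, with the defaults chosen to match the published
  layout cell-for-cell in the package's acceptance tests.
* **Missing typology** — four countries (Liberia, Iraq, Uganda, Yemen) have
  no survey typology breakdown. They get a type-III share of zero with an
  explicit `type3_assumed_zero` flag, i.e. "assumed zero" is a modelling
  assumption carried visibly through the output, not silent missingness.
* **Disclosure control** — cells between 1 and 9 are suppressed
  (`"<10"`), zero stays visible, and countries with fewer than 20 total
  residents are pooled into an "Other countries" row. Totals are computed
  before suppression, so visible cells need not sum to printed totals —
  that is a property of the published originals too, and the tests assert
  that visible sums never exceed the totals. Pooling membership is decided
  on resident totals, but each pooled constituent is estimated with its own
  country's prevalence and the pooled row is the sum of those estimates:
  pooling is a reporting step, not a modelling step.

## Packaged inputs

`inst/extdata/fgmc_country_profiles.csv` transcribes the 29-country
DHS/MICS reference data (prevalence 15–49 and 15–19, customary age window,
type-III shares, source survey). Values are stored as printed in survey
reports, decimal comma and percent sign included; the loader normalises
them to proportions and validates ranges, the age window and name
uniqueness.

`inst/extdata/group_counts_printed.csv` is an aggregate cohort-count table
for the 29 countries at the 2013-01-01 reference date, as published:
disclosure-suppressed cells are blank and eight small countries appear only
as a pooled row.

`inst/extdata/group_counts_completed_synthetic.csv` is the same table with
every suppressed cell filled and the pooled row split into its eight
constituent countries — this is the table the worked examples and the
acceptance script run on, because estimation needs complete cells. Most
filled cells are *exactly determined* by row totals, column totals and the
cross-table structure of the published tables; where only a sum was
determined (a few 1b/1c pairs, and the split of the pooled row) values were
chosen once, consistent with all published marginals, and are labelled
synthetic in the file name. One row of the source tabulation is internally
inconsistent by four records (its pooled-row cells cannot satisfy its own
row and column totals simultaneously); the completion resolves this in
favour of the column totals, which is why the package's grand total
(44,471) exceeds the published one (44,467) by four and a handful of
suppression-dependent national totals differ from their published
counterparts by a few units. All fully printed per-country cells are
reproduced exactly.

## The synthetic-register generator

Register microdata cannot be deposited, so `generate_register()` emulates
it. In marginal mode it is *constructive*: for each requested cohort it
samples an age at reference uniformly from the integer range that defines
the cohort, converts it to a birth-date interval, samples a day inside it,
and (for the first generation) repeats the construction for the age at
arrival — so classifying the output reproduces the requested counts
*exactly*, which the generator verifies internally before returning. A
`margin_days` parameter (default 1) keeps sampled dates away from interval
boundaries; setting it to 0 permits boundary dates (birthdays on the
reference date itself), which the tests use to confirm that generator and
classifier share one boundary convention. Rates mode draws cohort counts
from a multinomial first and then constructs records the same way.

Infeasible requests fail loudly: cohort 1b requires an age strictly past
the window and under 18, which no age satisfies when the window reaches
17 or beyond (Sierra Leone and Uganda, window to 18, are the packaged
examples) — real registers can show such counts only under a different
(e.g. year-resolution) age convention than the date-exact one used here.

What the generator does **not** emulate: realistic arrival-cohort and
birth-year distributions (ages are uniform within cohort-defining
intervals), migration histories, households, male relatives, or any
correlation between arrival age and origin country beyond the window
constraint. Passing tests therefore demonstrate the correctness of the
classification/estimation machinery, not the demographic realism of the
synthetic population.

## Numerical and degenerate-input choices

* Classification is total: every record lands in exactly one of the seven
  labels (including `excluded`), and tabulation preserves the partition
  (tested on 10,000 random synthetic records).
* An empty register yields an empty (zero-row) count table; a
  zero-population estimate reports zero shares rather than `NaN`.
* Suppressed (`NA`) cells in an aggregate input are refused by the
  estimators with a pointer to `impute_suppressed()`; silently treating
  them as zero would bias estimates downward.
* Country identity is by trimmed, case-folded name throughout; unknown
  countries are a legitimate classifier outcome (exclusion), but a hard
  error in estimation, where every counted country must have a profile.

## Problem sizes in the test suite

The suite runs the full 29-country estimation repeatedly, a 10,003-record
partition property, ten random generator round-trips per property block
and a two-country (≈8,900 records) end-to-end register regeneration in the
acceptance script — sizes chosen to exercise every code path in well under
a minute while matching the scale of the real analysis (≈44,000 records).

## Known limitations

* National prevalences hide large ethnic and regional variation (Iraq is
  the canonical example: the national prevalence is a fraction of the
  prevalence among its Kurdish population). Register data carry no
  ethnicity, so the model inherits this bias in either direction.
* Migration is selective with respect to age, wealth and education, which
  correlate with prevalence; no selection adjustment is applied.
* Typology (type-III) survey data are markedly less reliable than
  prevalence data and tend to under-report infibulation; the type-III
  splits should be read as rough shares.
* The model yields point estimates; survey sampling error and the
  uncertainty of the zero-incidence-after-migration assumption are not
  propagated.
* The acculturation factor is a modelling device. Choosing between the
  low- and high-risk scenario (or an intermediate factor) requires
  qualitative evidence about the population at hand; the package computes
  the bracket and leaves that judgement to the analyst.
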