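---
title: "Methods: disproportionality signal detection for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous-reporting systems such as FAERS collect case reports of
suspected adverse drug events without a denominator: we observe which
drug-event pairs get reported, never incidence. Signal detection therefore
works by *disproportionality*: a drug-event pair is interesting when it is
reported more often than the pair's reporting rates would predict under
independence within the database itself. This package implements that
screen for one target drug (a ceftazidime/avibactam-style name list by
default) against the rest of a FAERS-shaped database, together with the
standard companion analyses: time-to-onset modelling, subgroup and period
comparisons, and a covariate-adjusted logistic model for
combination-therapy questions.

Everything is exercised against a synthetic report generator with known
ground truth, because the conclusions one can draw from spontaneous data
hinge on exactly the biases a generator can make explicit.

## Data model and cleaning

A dataset is four relational tables keyed by a report identifier:
demographics (one row per submitted report, carrying a case id and a
version), drug rows (name, role code PS/SS/C/I, sequence number), reaction
rows (preferred term, event date), and therapy rows (start date per drug
sequence). The ASCII dialect is "$"-delimited with a header line; dates are
`YYYYMMDD` and partial dates (`YYYY`, `YYYYMM`) are padded to the first
day/month. Ages arrive with a unit code (`YR`, `DEC`, `MON`, `WK`, `DY`,
`HR`) and are converted to years; unknown codes and out-of-range values
(outside 0–130) become missing. Unparseable fields are always missing,
never errors: real extracts are dirty, and a parser that aborts on the
first malformed date is useless.

Cleaning is a fixed chain: quarterly files are concatenated (UNION-all),
the quarterly deletion lists are consolidated by set union and purged, and
repeat submissions of one case are collapsed to a single report. The
deduplication rule — highest case version, ties broken by latest receipt
date, then by largest report id — is deterministic and order-independent;
the public documentation of FAERS does not pin down a unique rule, so this
package states one and tests its idempotence rather than leaving the
choice implicit. Case-level assembly INNER-joins demographics to drug rows
(a report without drug rows cannot be attributed and is dropped) and
LEFT-joins reactions (a report with drugs but no coded reaction is
retained — it still contributes to the drug's report margin).

## Counting units

The fourfold table for term *t* is counted over **distinct (case, PT)
pairs**, not over cases and not over raw rows: one case reporting three
PTs contributes three units; duplicate PT rows within a case collapse to
one. At SOC level each (case, PT) pair contributes to its PT's organ
class, so a case with two PTs in the same SOC counts twice there. This is
the only convention under which a cohort can have ~1,000 cases while event
percentages are quoted out of ~2,400 records, as published report tables
do. "Other drugs" means all reports lacking the target as primary
suspect; target reports where the drug is SS/C/I count as background,
matching the primary-suspect restriction of the screen itself.

## The four algorithms

With cells `a, b, c, d` and `N = a+b+c+d`:

* **ROR** `= ad/(bc)` with the log-normal interval
  `exp(ln ROR ± 1.96·se)`, `se = sqrt(1/a+1/b+1/c+1/d)`.
* **PRR** `= a(c+d)/(c(a+b))` with the uncorrected chi-square
  `(ad−bc)²N / ((a+b)(c+d)(a+c)(b+d))`. A log-scale PRR interval is also
  reported, but the PRR flag is gated on the classical triple
  (PRR ≥ 2, chi² ≥ 4, a ≥ 3), not on that interval.
* **IC** `= log2(aN/((a+b)(a+c)))` in bits, with interval
  `IC ± 2·sd(IC)`. The variance of IC is not uniquely defined in the
  closed-form tradition this package follows; the default is the delta
  method on the log scale, `sd(IC) = (1/ln 2)·sqrt(1/a+1/b+1/c+1/d)` —
  the same sampling variance the ROR and EBGM intervals use, which keeps
  the three intervals mutually consistent. `ic_method = "posterior"`
  switches to the classic BCPNN closed-form posterior moments, which
  shrink small-count ICs toward zero.
* **EBGM** `= aN/((a+c)(a+b))` — the observed/expected reporting ratio —
  with the same log-normal interval as the ROR.

Two consequences are worth stating plainly. First, `IC = log2(EBGM)`
identically under these definitions; the package tests this to 1e-12 and
treats it as a feature, not a coincidence. Second, this EBGM is **not** a
multi-item gamma-Poisson shrinker: a true MGPS fits a two-component gamma
mixture across all pairs and shrinks small counts toward the prior. The
closed form is kept because it is what the published signal tables this
pipeline mirrors actually compute; the shrinkage variant would flag fewer
small-count terms. Users comparing against shrinkage-based outputs should
expect the difference precisely at small `a`.

Zero cells make a statistic non-evaluable by default (its flag is false);
a Haldane–Anscombe +0.5 correction is available behind
`zero_correction = TRUE` rather than silently applied, because the
thresholds were calibrated by tradition on uncorrected tables.

Threshold boundary semantics are explicit and tested: PRR ≥ 2, chi² ≥ 4
and a ≥ 3 are inclusive; ROR lower CI > 1, IC025 > 0 and EBGM05 > 2 are
strict. The combined flag is the conjunction of all four — deliberately
conservative; under a global null (20,000 synthetic cases, 200 terms) the
combined flag rate in the acceptance run is ~0%, and the ROR lower bound
alone exceeds 1 on ≤ 7% of terms (nominal 2.5% one-sided plus small-count
inflation).

## Time to onset

Onset is `event date − earliest start date of the target drug + 1 day`:
the +1 maps same-day onsets to day 1 so the Weibull likelihood is finite
on day-granular data. Records missing either date are excluded and
counted; negative latencies (event before start) likewise — they usually
indicate an event attributed to a previous course.

Summaries use type-7 quantiles (linear interpolation between order
statistics) and half-open bins `[1,6), [6,11), …, [31, ∞)` so the first
bin reads "within the first 5 days". The Weibull fit maximizes the
likelihood on the (log shape, log scale) scale with BFGS; CIs come from
the observed information on that scale, exponentiated. The
three-parameter variant profiles a location over a 64-point grid on
`[0, min(days))`; the default is the two-parameter fit because with
integer days and heavy ties a free location estimate chases the smallest
observation. A shape CI entirely below 1 is labelled a decreasing hazard
(early-failure profile). Note one systematic effect the synthetic runs
make visible: ceiling-rounding continuous Weibull draws to whole days
biases the fitted shape slightly upward when the scale is small relative
to a day — recovery tests therefore use continuous draws, and the
end-to-end scenario expects the rounded-data shape above its generating
value but with the CI still below 1.

## Stratified comparisons

Subgroup (age, sex), period (pre/post a cutoff year, default 2020) and
regimen (with/without a comedication) comparisons all reduce to the same
primitive: per term, the 2×2 of (stratum × term-vs-other) over (case, PT)
records within target-drug reports. The effect axis is the log2 odds
ratio of that table (+0.5 on all cells when any is zero), the p-value is
the uncorrected chi-square when all expected cells are ≥ 5 and Fisher's
exact test otherwise. Published volcano plots rarely define their axes;
this reconstruction is stated rather than guessed at silently. No
multiplicity adjustment gates the `significant` flag (matching practice
in the signal-detection literature); a Bonferroni column is emitted so a
reader can apply their own standard. Both age-band conventions found in
report tables (18–60/60–80 and 18–64/65+) are supported via
configuration; intervals are left-closed, and missing ages are excluded
from age subgroups.

## Adjusted reporting odds ratio

The regimen question — does comedication X raise the odds of outcome PT Y
among target-drug cases — is confounded by indication: sicker patients
get combination therapy. The package builds one record per case (binary
outcome, binary exposure, age per 10 years centred at 55, sex
reference-coded with female as reference, reporting year as a centred
linear trend, nephrotoxin co-reporting as a binary proxy for baseline
renal risk) and fits a logistic model with its own IRLS/Newton fitter:
convergence when the maximum absolute score < 1e-8 or coefficient change
< 1e-10, cap 100 iterations, step-halving so the log-likelihood never
decreases, Wald intervals from the inverse observed information,
quasi-separation reported when any |coefficient| exceeds 15. With no
covariates the fit reproduces the closed-form `ad/(bc)` odds ratio to
1e-8 — the contingency module supplies that oracle in the tests, and
`stats::glm` serves as an independent cross-check, never as the
implementation.

Missing age is the dominant design decision: spontaneous reports lack age
in well over half of cases. Complete-case analysis is the default
(`age_policy = "complete"`, with `n_used` always reported); a
missing-indicator policy keeps all cases at the cost of a formally biased
coefficient. Neither is privileged as "the" published setting, because
published analyses rarely say which they used.

## The synthetic generator

The generator emulates the statistical structure the pipeline assumes:
case-level demographics (sex mix 47.4/26.9/25.7 male/female/unknown,
63.4% missing age, the published country/occupation/year mixes of a
~1,000-case cohort), a target-drug share of 10%, ~200 background PTs with
per-case probabilities evenly spaced in [0.002, 0.02] (a rare-event
regime, so ROR ≈ PRR ≈ RR and ground-truth recovery checks are
meaningful), injected signals as per-PT relative risks (default: one
RR-50 "Pathogen resistance"-like term), Weibull(0.7, 8 days) onset times
(median ≈ 5 days), a meropenem-like comedication whose respiratory-
failure interaction follows a logistic model with a true exposure OR of
3.26, duplicate submissions (5%) with incremented versions, and deletion
lists that reference real case ids so the purge path is exercised.
Generation uses a private Mersenne-Twister stream per seed; written files
are byte-identical across runs and round-trip through the readers
unchanged.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: reporting biases (Weber
effect, notoriety spikes), duplicate reports that differ in content
rather than version, free-text drug-name noise, correlated PT clusters
within a case, country-specific reporting cultures, and
confounding-by-indication structure beyond the single built-in
comedication interaction. Calibration statements ("the combined flag
fires on ≤ 5% of null terms") are statements about this generative model,
not about FAERS.

## Simulation sizes and numerical choices

The validation suites use: 1,000 random fourfold tables for the formula
oracle (agreement to 1e-10 relative); a 20,000-case, 200-term null for
calibration; 100 seeds of a 5,000-case scenario (target share 0.2,
injected RR 5 at baseline 0.02, ~100 expected co-occurrences) for ROR
interval coverage; n = 5,000 for Weibull point recovery (±0.04 shape,
±0.5 scale) and 100 seeds of n = 200 exponential data for shape-CI
coverage; and 100 seeds of n = 2,000 confounded records for adjusted-OR
coverage — sizes chosen to make the 90%-coverage bounds sharp while a
full run stays comfortably under a minute. Ties in screening ranks break
by term label; all cell arithmetic is done in double precision (the
chi-square denominator overflows 32-bit integers on realistic database
sizes).

## Known limitations

* The EBGM/IC pair is the closed-form tradition, not shrinkage; small-`a`
  terms are flagged more liberally than a true MGPS would.
* No censoring in the onset model: cases still on therapy at reporting
  are treated as observed onsets, which a survival formulation would
  handle more honestly.
* The PT→SOC mapping is a flat two-column file; the real MedDRA hierarchy
  (HLT/HLGT, multi-axiality) is out of scope, and unmapped PTs are
  bucketed and flagged rather than resolved.
* Signal flags are statistical associations within a biased reporting
  stream — the package deliberately contains no causality language.
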