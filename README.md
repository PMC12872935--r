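# pvsignal

Signal detection for spontaneous adverse-event reports, end to end: from raw
FAERS-style quarterly ASCII tables to ranked disproportionality signals,
time-to-onset Weibull diagnostics, subgroup volcano tables and
covariate-adjusted reporting odds ratios.

## Who this is for

Pharmacovigilance analysts and methods researchers who work with
spontaneous-reporting data (FAERS or FAERS-shaped extracts) and want a
tested, scriptable R implementation of the standard disproportionality
toolkit — plus a synthetic report generator with known ground truth, so
every stage of the pipeline can be validated without downloading a
multi-gigabyte database.

## What it computes

For a target drug versus all other drugs, each adverse-event term (MedDRA
preferred term, PT, or system organ class, SOC) gets the classic fourfold
table — `a` reports with both drug and event, `b` drug with other events,
`c` event with other drugs, `d` the rest, `N = a+b+c+d` — counted over
distinct (case, PT) pairs, and four statistics:

| Algorithm | Estimate | Signal criterion |
|---|---|---|
| ROR   | `ad/(bc)`, log-normal 95% CI with `se = sqrt(1/a+1/b+1/c+1/d)` | CI lower bound > 1 and `a >= 3` |
| PRR   | `a(c+d)/(c(a+b))` with uncorrected chi-square | PRR >= 2, chi2 >= 4, `a >= 3` |
| BCPNN | `IC = log2(aN/((a+b)(a+c)))`, interval `IC ± 2·sd(IC)` | IC025 > 0 |
| EBGM  | `aN/((a+c)(a+b))`, log-normal 95% interval | EBGM05 > 2 |

A term flagged by all four algorithms is a combined signal. The EBGM here
is the closed-form observed/expected ratio with a log-normal interval (so
`IC = log2(EBGM)` identically); it is not a gamma-Poisson shrinkage
posterior — see the methods vignette for why, and for the IC variance
options.

Around that core:

* **faers_io** — readers for the FDA "$"-delimited dialect (header line,
  `YYYYMMDD` dates with partial-date padding, age-unit codes), quarterly
  UNION merge, deletion-list purge, case-version deduplication
  (highest version, then latest receipt date, then largest report id),
  INNER/LEFT case-level joins, target-drug filtering by role-restricted
  substring match, and record-count validation.
* **synthetic generator** — FAERS-shaped tables with configurable
  drug-event relative risks, demographic mixes, Weibull onset times,
  duplicate submissions and deletion lists; fully seeded and byte-stable.
* **time to onset** — onset day = event date − earliest therapy start + 1;
  median/IQR, day bins, and a Weibull MLE whose shape parameter (with CI)
  labels the hazard trend (shape CI entirely below 1 = early-failure type).
* **stratified** — age/sex subgroup, reporting-period and
  mono-vs-combination comparisons as volcano/forest-ready tables
  (log2 odds-ratio effect axis, chi-square or Fisher p).
* **regression** — case-level logistic model (own IRLS fitter) giving the
  adjusted reporting odds ratio for an outcome PT under a comedication
  exposure, controlling for age, sex, reporting year and nephrotoxin
  co-reporting.

## Worked example

```r
library(pvsignal)

# synthetic study: ~400 target-drug cases among 4,000 reports, one strong
# injected signal ("Pathogen resistance", RR = 50), meropenem comedication
# interacting with respiratory failure
gen   <- generate_faers(generator_config(n_cases = 4000, seed = 42))
clean <- clean_dataset(gen$dataset, gen$deleted)

drug  <- c("Avibactam", "Avycaz", "Zavicefta")
pairs <- case_pt_pairs(clean, drug)           # distinct (case, PT) units
res   <- screen_signals(build_pt_tables(pairs))
head(format_signal_table(res), 3)
#>   term                case      `ROR (95% CI)`      `PRR(chi2)`   `EBGM(EBGM05)` `IC(IC025)` signal
#> 1 Respiratory failure 52 (5.6%) 2.50(1.82-3.42)     2.41(34.47)   2.10(1.53)     1.07(0.61)  ""
#> 2 Pathogen resistance 36 (3.9%) 45.64(20.25-102.86) 43.92(246.98) 7.99(3.54)     3.00(1.80)  "*"
#> 3 PT_185              12 (1.3%) 1.75(0.94-3.26)     1.74(3.14)    1.61(0.86)     0.69(-0.23) ""
```

The injected RR-50 term tops the count ranking and is starred: it passes
all four criteria (ROR lower CI 20.25 > 1, PRR 43.92 >= 2 with chi2 246.98,
EBGM05 3.54 > 2, IC025 1.80 > 0). Respiratory failure is enriched (it was
generated with an exposure interaction) but does not clear the EBGM05 > 2
bar — the combined criterion is deliberately conservative.

```r
tgt <- filter_target_drug(clean, drug)
oa  <- onset_analysis(tgt, drug)
oa$fit
#> <weibull_fit> n=457 shape=0.854 [0.798, 0.914] scale=10.42 [9.30, 11.68] location=0.00
#>   hazard: decreasing
```

The fitted shape CI sits entirely below 1: onset risk is front-loaded
(the generator draws onsets from Weibull(0.7, 8 days); day-granular
rounding biases the fitted shape slightly upward, as the vignette
discusses).

```r
adjusted_ror(tgt, "Respiratory failure", "MEROPENEM",
             age_policy = "indicator")$aor
#>   term     estimate    se    or or_lo or_hi     z  p_value
#> 1 exposure     1.58 0.336  4.86  2.52  9.39  4.71 2.43e-06
```

The adjusted OR for respiratory failure under meropenem co-exposure is
4.86 (95% CI 2.52–9.39) in this small replicate — the Wald interval around
an injected true effect of 3.26.

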