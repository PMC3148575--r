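---
title: "Comparing proxy indicators of material circumstances: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing proxy indicators of material circumstances: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matcirc)
```

## The problem

Individual income is hard to collect: many study participants decline to
report it, and response can differ sharply by subgroup (in the setting this
package targets, 15% of men answered the household-income question against
71% of women). Epidemiologists therefore fall back on proxies. Two are
compared here against self-reported household income, all on a common
five-category ordinal scale:

* a **residential value index** — the assessed monetary value of one
  residential unit of the building the subject lives in, an
  *individual-level* proxy derived from municipal property-assessment rolls;
* **census income** — the median household income of the subject's census
  tract, the conventional *area-level* proxy.

The package computes how far two ordinal classifications of the same
subjects disagree (signed category-difference distributions, concordance
proportions), and how much they agree beyond chance (overall and linearly
weighted Cohen's kappa, Spearman correlation). It also reconstructs kappa
statistics from *published summaries* when the subject-level data are
confidential, and ships a synthetic-cohort generator so the whole pipeline
is testable end to end.

## The residential value index

Municipal assessment rolls record, per building: the total assessed value,
the proportion of floor area identified as commercial, and the number of
residential units. The per-unit value is

$$v = \frac{V_{\text{total}} \,(1 - c)}{u},$$

with $c$ the commercial proportion and $u$ the unit count. Condominiums are
assessed individually per unit, so a condominium record is taken at face
value ($v = V_{\text{total}}$, one unit, no commercial subtraction): a
condominium assessment already isolates the residential unit, and applying
the building-level commercial share to it would double-count space that is
not part of the unit. Records with no residential units (e.g. community
homes) or that are fully commercial cannot be assigned a value; they are
excluded with an explicit reason code and rows are conserved
(included + excluded = input). A missing commercial proportion is read as
"none", with a warning, since the field is only populated when commercial
space exists. No adjustment is made for owning versus renting — the unit
value is read as a measure of what the occupant can afford in housing —
and no attempt is made to model the appraisal method or to apportion value
by per-unit floor area, neither of which is recorded in assessment rolls.
Unit values are kept at full floating precision internally; rounding to
currency happens only in printed reports, to avoid categorization-boundary
artifacts.

## Reference-marginal categorization

Self-reported income arrives in ordinal bands (eight questionnaire choices
collapsed to five categories; the collapse mapping is a configurable input,
with the five published bands as the default, because the original
questionnaire vocabulary varies between studies). The two continuous
proxies are cut into five categories so that their marginal distributions
match the self-report distribution — otherwise kappa would mix genuine
disagreement with a mismatch of marginals.

Cutoffs are inverse-empirical-CDF (type 1) quantiles at the cumulative
reference proportions. Two consequences drove this choice:

* every cutoff is an observed value, so the "`<= c` / `c+1 -`" integer
  dollar convention of published tables is exactly reproducible; other
  quantile definitions shift category counts by at most one subject;
* for tie-free samples the achieved marginals differ from the reference by
  at most $1/n$ per category (a tested invariant).

Ties at a cutoff go to the *lower* category (upper-inclusive intervals),
matching the printed "<= $42,102" style. Heavily tied inputs that cannot
support five non-empty categories collapse the duplicated cutoffs with a
warning; identical values or fewer values than categories are errors.

`run_analysis()` defaults to using the *observed* self-report distribution
of the analysis sample as the reference, which is what an analyst comparing
proxies against self-report does in practice; the fixed presets
(`reference_marginals()`: 30.2/24.1/21.0/12.6/12.1, or the rounded
30/24/21/13/12) are available when cutoffs must be reproduced exactly
across samples. Whether cutoffs should be derived on income responders or
on complete triples is study-specific, so the sample on which
`run_analysis()` derives them is simply the analysis sample it is given,
and schemes can be passed in explicitly for anything else.

## Agreement statistics

For a $k \times k$ cross-tabulation with cell proportions $p_{ij}$ (rows:
self-report; columns: proxy; positive differences mean the proxy
*overestimates*), with weights $w_{ij}$:

$$P_o(w) = \sum_{ij} w_{ij} p_{ij}, \qquad
  P_e(w) = \sum_{ij} w_{ij} p_{i\cdot} p_{\cdot j}, \qquad
  \kappa_w = \frac{P_o(w) - P_e(w)}{1 - P_e(w)}.$$

Linear weights $w_{ij} = 1 - |i - j|/(k - 1)$ (for $k = 5$: 1, 0.75, 0.50,
0.25, 0) give a one-category difference the same credit anywhere on the
scale; identity weights recover the overall kappa exactly, which is tested
to $10^{-12}$ against a double-loop oracle.

**Confidence intervals.** Published comparisons of this kind report 95%
CIs without stating a variance formula. The default here is the
Fleiss–Cohen–Everitt large-sample standard error of the weighted kappa
(with the unweighted kappa as its identity-weight special case) and a Wald
interval truncated at 1; a seeded multinomial bootstrap percentile interval
is available as an alternative (`ci = "bootstrap"`). Neither is claimed to
replicate any particular published CI width exactly, since the estimator
behind published intervals is usually unstated.

**Spearman correlation** is computed on the five-category variables with
mid-ranks for ties, the dominant case for ordinal data; passing the
continuous values instead is possible but not the default.

## Reconstruction from published summaries

When only summary tables are published, two operations recover what is
identified:

* `kappa_from_summaries()` — the two marginal distributions determine
  $P_e$, and together with the published perfect-concordance proportion
  they identify the unweighted kappa *point estimate*. No SE or CI is
  returned: the joint table is not identified from marginals.
* `weighted_kappa_bounds()` — published difference tables lump extreme
  differences ("<= -3", ">= 3"), so the weighted observed agreement is
  known only up to where the tail mass sits, between $|d| =$ the lumping
  threshold and $k - 1$. For weights that depend only on $|i-j|$ the
  extremes of $P_o(w)$ are attained by pushing all tail mass to the
  smallest or largest absolute difference, giving sharp bounds on
  $\kappa_w$. With empty tails the bounds collapse to the exact value, and
  the exact $\kappa_w$ of any table always lies inside the bounds computed
  from its own lumped summary (both tested).

On the shipped Montreal summary tables (`montreal_income_tables()`,
$n = 676$) these reproduce the published overall kappas (0.21 residential,
0.09 census, at two decimals) and bracket the published weighted kappas
(0.37 inside [0.337, 0.383]; 0.25 inside [0.192, 0.260]).

## The synthetic cohort generator

No generative model accompanies confidential cohort data, so the generator
uses the simplest structure that yields three correlated ordinal/continuous
indicators with controllable marginals and agreement: a **single-factor
Gaussian latent-variable model**. Each subject has a standard-normal latent
trait $z$ of material circumstances; indicator $m$'s continuous score is

$$s_m = \frac{z + \varepsilon_m}{\sqrt{1 + \sigma_m^2}}, \qquad
  \varepsilon_m \sim N(0, \sigma_m^2),$$

again standard normal, with trait correlation $1/\sqrt{1 + \sigma_m^2}$.
The self-report score is thresholded at the normal quantiles of the
cumulative target marginals; the residential score is mapped through a
log-normal currency transform (meanlog 11.04, sdlog 0.68, landing the
quantiles near mid-1990s Montreal per-unit values) and wrapped in a
property record — multi-unit buildings (72% of subjects by default),
Poisson-sized unit counts, occasional commercial proportions, condominium
flags — constructed so `residential_unit_value()` recovers the intended
per-unit value exactly. The census indicator takes a second log-normal
transform (meanlog 10.36, sdlog 0.39, a census-tract median-income scale),
then replaces each subject's value with the *median over their synthetic
tract*, tracts being consecutive blocks of similarly-valued subjects.

Tunable parameters, defaults, and why:

| parameter | default | rationale |
|---|---|---|
| `n_subjects` | 676 | the analysis-sample size the method targets |
| `target_marginals` | .302/.241/.210/.126/.121 | observed self-report distribution |
| `noise_sd` | 0.55 / 1.15 / 1.90 | see below |
| `prop_multi_unit` | 0.72 | share of subjects in 2+ unit buildings |
| `response_rate_by_sex` | m 0.15 / f 0.71 | sex-differential income nonresponse |
| `prop_female` | 499/676 | cohort composition |
| `tract_size` | 8 | subjects per tract (see below) |

The default noise SDs were fixed once, by a coarse grid evaluation at
$n = 40{,}000$, so that the default cohort run through the full pipeline
lands at the weighted-kappa operating points the analysis is designed
around (residential ≈ 0.37, census ≈ 0.25 against self-report); they were
not tuned further. The self-report noise (0.55) encodes that self-report
is itself an error-prone measure, not a gold standard.

`tract_size` is 8 rather than the tract *population*: a city-wide cohort
of a few thousand subjects spreads over several hundred tracts, so the
number of cohort members sharing one tract value is small. Very large
tract sizes relative to `n_subjects` leave too few distinct census values
to support five categories and trigger the tie-collapse warning by
design.

A note on what aggregation does here. Because categorization is
rank-based, replacing each subject's noisy indicator value by their
tract's median — a rank-preserving coarsening — turns out to be nearly
agreement-neutral: within-block variation is mostly measurement noise, so
sharing the block median neither helps nor hurts (the tested invariant is
that aggregation never *inflates* agreement, checked with a common seed
with aggregation switched on and off). The area-level indicator's real
disadvantage is within-tract heterogeneity — even neighbors differ in
financial means, so one median stands for genuinely different households
— and the generator encodes that as the census indicator's larger noise
SD, which is why the default census noise (1.90) exceeds the residential
noise (1.15). Under the default conditions the published qualitative
ordering (census agreement below residential agreement) is reproduced
and tested.

Nonresponse is independent of the trait by default; `trait_slope` adds a
log-odds dependence for selection-bias experiments. All randomness flows
from the configuration seed; an identical configuration reproduces the
cohort bitwise.

`calibrate_noise_for_kappa()` scales the noise vector by a common factor,
bisecting on the pipeline-estimated residential weighted kappa of a large
simulated cohort (default $n = 20{,}000$); a shared seed across bisection
evaluations makes the response curve strictly decreasing in the scale.

**What passing tests on synthetic cohorts do and do not show.** The
generator reproduces marginals, agreement levels, multi-unit structure,
sex-differential nonresponse, and the individual-vs-area aggregation
contrast. It does not emulate real geography, real property markets,
cell-level joint structure beyond what marginals and difference
distributions constrain, or outcome (case/control) dependence — the
case/control label is exchangeable by construction. Tests passing on
synthetic cohorts validate the *statistical machinery*, not the
substantive claim that residential value tracks income in any particular
city.

## Pipeline and sensitivity strata

`run_analysis()` enforces the complete-triple restriction (subjects with
all three indicators), keeps an auditable accounting ledger (input =
analysis sample + exclusions, each with a reason), and computes all
statistics on the analysis sample. `run_strata()` re-runs the analysis per
stratum (sex, case/control, respondent type, interview-period flags) with
one deliberate constraint: **category schemes are derived on the pooled
analysis sample and reused in every stratum**. Subjects then keep the same
category wherever they appear, and the pooled cross-tab equals the
cell-wise sum of the stratum cross-tabs — recomputing cutoffs per stratum
would make stratum kappas incomparable with the pooled one. Strata with
fewer than 25 analysable subjects (configurable) are skipped with a
warning. The census join is an exact postal-code lookup against a
user-supplied table; no geocoding is attempted.

Reports print at conventional precision (percentages to one decimal,
kappas to two); `write_report()` keeps full precision in its JSON output.

## Numerical choices and problem sizes

* Kappa is undefined when $P_e = 1$ (both marginals degenerate): an error,
  not an NA.
* The chance-zero and reduction identities are validated at $10^{-9}$ and
  $10^{-12}$; bound consistency at $10^{-12}$.
* Monte-Carlo validation sizes were chosen to make sampling error small
  relative to the tolerances tested: $n = 20{,}000$ for
  parameter-recovery checks (kappa standard error ≈ 0.006, recovery
  asserted within three standard errors) and $n = 50{,}000$ for ±1%
  marginal fidelity.
* Bisection tolerance for noise calibration is 0.005 on the kappa scale,
  well under the Monte-Carlo noise of the cohorts it serves.

## Known limitations

* Reconstruction from summaries gives point estimates and bounds only;
  published Spearman coefficients and CI widths require the unpublished
  joint table and are deliberately not claimed.
* The latent-trait model is unifactorial; real indicators may disagree for
  structural reasons (e.g. wealthy subjects in cheap housing) that no
  noise scale captures.
* The generator's census aggregation uses equal-sized synthetic tracts;
  real tracts vary in size and internal homogeneity.
* Whether a condominium inside a mixed commercial building should receive
  a commercial adjustment is not decidable from assessment-roll semantics
  alone; such records are taken at face value, and conflicting fields
  (condominium with a recorded unit count other than one) are normalized
  to one unit.
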