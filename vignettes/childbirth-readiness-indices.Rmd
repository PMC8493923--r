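---
title: "Constructing and comparing childbirth service readiness indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and comparing childbirth service readiness indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbready)
```

## The measurement problem

Health authorities in low- and middle-income countries need a single,
interpretable number summarising whether a facility is *ready* to provide
childbirth care: trained staff present, essential equipment functional,
key medicines in stock, referral and information systems in place. There
is no consensus construction. In practice an index is defined by two
choices:

1. **Item selection.** Which observable tracer items enter the index. The
   package ships three framework definitions: a short SARA-style obstetric
   tracer list (15 items for health centres/clinics, 22 for hospitals,
   three domains), a DHS-style obstetric and newborn indicator list
   (30/33 items, five scored domains plus a guidelines/training/
   supervision domain), and a longer selection mapped to the WHO quality
   of maternal and newborn care standards (44/52 items, four domains
   spanning five standards).
2. **Aggregation.** How the 0/1 item responses become a score in [0, 1]:
   *simple addition* (available items over applicable items, equal item
   weights), *domain-weighted addition* (mean of per-domain availability
   proportions, equal domain weights), or *principal components analysis*
   (projection on the first component of the item correlation matrix,
   min–max rescaled).

Crossing the two gives nine indices per facility tier. Hospitals are
scored on an expanded item list covering comprehensive emergency obstetric
and newborn care, so scores are comparable within a tier but not across
tiers.

## Response coding

Raw survey responses are `yes`, `no`, `dont_know`, `missing` or
`not_applicable` (some items are asked only of a subset, e.g.
government-managed facilities). Before aggregation:

- `yes` codes to 1; `no`, `dont_know` and `missing` code to 0.
- `not_applicable` is excluded and the denominator adjusted for the
  additive methods, so a facility is never penalised for an item it was
  not asked; for PCA, which needs a complete matrix, `not_applicable`
  codes to 0 before aggregation.

Under these rules additive scores are exact rationals; the package
exploits this when grouping tied scores (exact equality, no floating-point
fuzz).

Domain-weighted scores drop a domain from the composite mean when every
item in it is inapplicable for a facility, mirroring the item-level rule.
The DHS guidelines/training/supervision domain is represented but flagged
as excluded from the weighted composite (its items still count under
simple addition), reflecting the limited availability of those items in
the emulated survey instrument.

## The PCA aggregation

`fit_pca()` eigendecomposes the item **correlation** matrix, i.e. items
are standardised before aggregation. The main open design point here was
correlation versus covariance; we use correlation because reported
first-component variance shares in comparable analyses equal the first
eigenvalue divided by the item count, which is the correlation-matrix
identity (the eigenvalues of a correlation matrix sum to the number of
items). The first component's sign is fixed by requiring a positive
loading sum, so a higher score always means greater readiness.

Scores are the standardised item vector projected on the first component,
min–max rescaled **within the scored cohort**: the least-ready facility in
the cohort scores exactly 0 and the most-ready exactly 1. This makes PCA
scores cohort-relative — adding or removing facilities changes everyone's
score — which is worth stating prominently when reporting results.

Zero-variance items make the correlation undefined; `fit_pca()` refuses by
default and lists the offending items, with an explicit
`drop_degenerate = TRUE` mode (used by the high-level
`readiness_index()`) that drops them with a warning. Silent handling
would hide data problems; on real cohorts near-universal items are
routinely constant within a tier.

## Item diagnostics and the 2PL model

The standards-based selection procedure screens candidate items and
characterises the survivors:

- **Availability** per item, with the applicable-only denominator.
- **Near-universal screening**: items available in strictly more than 97%
  of facilities are excluded — they cannot differentiate facilities.
  The bound is strict, so 0.97 exactly is retained.
- **Item variation** for reporting: *rare* items are available in under
  40% of facilities (strict), *widely available* items in at least 90%
  (inclusive; the operational table convention), percentages reported to
  integer precision.
- **Two-parameter logistic IRT** per readiness domain:
  \(P(y_{ij} = 1 \mid \theta_j) = \mathrm{logit}^{-1}\{a_i(\theta_j - b_i)\}\)
  with latent readiness \(\theta_j \sim N(0,1)\). Discrimination \(a_i\)
  measures how sharply availability separates facilities of different
  readiness; difficulty \(b_i\) is the readiness level at which
  availability crosses 50%.

`fit_2pl()` maximises the marginal likelihood by EM with Gauss–Hermite
quadrature. Numerical choices, all tunable: 21 quadrature nodes;
convergence when the largest absolute parameter change falls below 1e-4;
a 500-iteration cap; box constraints \(a \in (0.05, 10)\),
\(b \in (-6, 6)\) to keep estimates identified on small or
quasi-degenerate samples. The M-step is one weighted logistic regression
per item on the node locations, so each EM iteration increases the
marginal likelihood; all-constant items are rejected up front. A default
retention flag of \(a \ge 0.65\) is exposed on `item_diagnostics()`; it is
an editorial default — real selection procedures pair statistical
properties with conceptual alignment rather than a single cutoff.

Internal consistency uses Cronbach's
\(\alpha = \tfrac{K}{K-1}(1 - \sum_i s_i^2 / s_{\mathrm{tot}}^2)\) with
sample variances, and interitem correlation is the phi coefficient
(Pearson on 0/1 columns).

## The comparison battery

`compare_all()` reproduces the standard index-evaluation battery:

- Moments: moment-coefficient skewness \(m_3/m_2^{3/2}\) and
  **non-excess** kurtosis \(m_4/m_2^2\) (normal = 3), matching the
  convention of the general-purpose statistics environments these
  analyses are usually run in; coefficient of variation = sample SD /
  mean.
- Floor/ceiling: proportions scoring exactly 0 or 1, with a 1e-9
  tolerance (additive scores are exact; rescaled PCA endpoints are exact
  up to rounding).
- Ties: facilities at the top score and at the **second-largest distinct
  score**, grouped by exact equality.
- Reported percentages are rounded half-to-even at one decimal
  (`round_half_even()`), the convention under which 34/160 prints as
  21.2% and 50/160 as 31.2%.
- Bland–Altman agreement: per-facility differences, limits of agreement
  at the mean ± exactly **2 SD** (not 1.96 SD — the plotting convention
  this mirrors), count outside the limits, plus the Spearman rank
  correlation of the two score sets.
- Spearman correlation with monthly delivery volume: Pearson on average
  ranks (tie-corrected), two-sided p from the t approximation on
  \(n - 2\) df, no multiple-testing adjustment; facilities missing a
  volume are dropped pairwise from this correlation only.

Both dense and ordinal ranks are emitted by `rank_with_ties()`, since
ranking-figure conventions vary.

## The synthetic cohort generator

The study data this package is designed around are access-restricted, so
`generate_cohort()` draws cohorts with the statistical structure the
analysis assumes: a unidimensional latent readiness trait per facility,
\(\theta \sim N(\mu_{tier}, 1)\) with hospitals centred above health
centres; item responses through the 2PL; sparse don't-know/missing
responses overlaid completely at random (0.5% each, matching a "<1%"
regime); five conditional items not applicable outside government
management (private shares 3.8% of hospitals, 6.1% of health centres, so
conditional items are inapplicable for roughly 3–8% of facilities); and
log-linear delivery volume
\(\log V = \beta_0 + \beta_1 \theta + \varepsilon\), which reproduces a
positive but modest rank correlation between readiness and volume.
Defaults are 160 hospitals and 246 health centres/clinics, the cohort
sizes of the survey the generator emulates.

`preset_observed_regime()` sets framework difficulty shifts (SARA −1.2,
DHS −0.8, WHO-standards −0.3, difficulty SD 0.8, discriminations
U(0.8, 2)) chosen so the generated regime matches the qualitative
findings such comparisons report: the short, easy SARA list shows
hospital ceiling percentages in the tens of percent and frequent top-two
ties, the long WHO-standards list stays below a 10% ceiling, and
readiness–volume correlations fall roughly in 0.15–0.40.

What the generator deliberately does **not** emulate: multi-factor domain
structure (a single trait drives all domains, so interdomain correlations
are uniformly positive), informative missingness, cluster sampling
designs, region effects, or item overlap between frameworks (the three
shipped item sets are disjoint; the real overlap map is not public).
Passing tests on synthetic cohorts therefore demonstrate that the
*pipeline* computes the intended quantities under a known generative
model — not that any particular real-world cohort will show these
patterns.

## A worked run

```{r, eval = FALSE}
cohort <- generate_cohort(preset_observed_regime(seed = 1))
hosp <- subset(cohort, tier == "hospital")
class(hosp) <- class(cohort)

battery <- readiness_battery(hosp)
report <- compare_all(battery, hosp)
print(report)

spec <- index_spec("WHO_standards", "hospital")
diag <- item_diagnostics(hosp, spec)
head(diag)
```

## Problem sizes and test design

The package's own checks run at sizes chosen to make their statistical
assertions sharp but quick: oracle-equivalence fixtures use at most 12
facilities (closed-form statistics are compared at 1e-12, eigenpairs at
1e-8); 2PL parameter recovery uses 10 items at n = 2000, where truth
correlations above 0.9 and a median absolute difficulty error under 0.2
are attainable; qualitative-regime checks use 20 replicate cohorts at the
default 160 + 246 size with majority voting, which is robust to the
sampling noise of individual seeds; Monte-Carlo checks of the generator
use single items at n = 20000 against the logistic–normal integral
computed by quadrature.

## Known limitations

- Shipped item registries reproduce the per-framework totals, domain
  structure, tier nesting and conditional-applicability pattern of the
  frameworks they model, but item identities are placeholders; analyses
  of real surveys should supply their own registry CSV.
- PCA scores are cohort-relative (min–max over the scored tier) and
  single-component only; no rotation, no polychoric correlations.
- The 2PL assumes unidimensional readiness within a domain and a standard
  normal trait; no 3PL, graded, or differential-item-functioning
  extensions.
- CV comparisons across indices are descriptive; no inferential
  comparison or bootstrap intervals are provided.
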