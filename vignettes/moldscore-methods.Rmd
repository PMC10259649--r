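---
title: "Methods: qPCR-based indoor mold assessment with moldscore"
author: "moldscore maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qPCR-based indoor mold assessment with moldscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moldscore)
```

# The measurement problem

Dust in a home integrates the fungal aerosol of the indoor environment over
months. The Environmental Relative Moldiness Index (ERMI) standardizes the
assessment of that burden: a fixed panel of 36 indicator molds is quantified
by species-specific qPCR assays, split into 26 *group-1* species associated
with indoor water damage and 10 *group-2* species that primarily enter from
outdoors (phylloplane and soil fungi such as *Alternaria alternata* and the
*Cladosporium cladosporioides* types). The group-2 species act as a
background correction: a home full of outdoor-origin spores is dusty, not
moldy.

`moldscore` implements the full analysis chain for a two-year, multi-region
cohort of homes: qPCR quantification with extraction QC, per-home scoring,
and the between-year/between-region statistical battery, together with a
ground-truth synthetic cohort generator used to validate every stage.

# From cycle thresholds to concentrations

Each assay is modelled by the standard linear calibration
$C_t = b + m\,\log_{10}(\mathrm{CE})$, with slope $m < 0$ (more template
amplifies earlier) and intercept $b$ the cycle at which a single cell
equivalent (CE) crosses the threshold. `ctToCellEquivalents()` inverts this:
$\mathrm{CE} = 10^{(C_t - b)/m}$. Defaults assume a perfectly efficient
assay, $m = -1/\log_{10} 2 \approx -3.3219$ (one doubling per cycle) and
$b = 40$ at the final cycle; real per-assay curves are loaded through the
panel registry (JSON or `panelAssays()`), nothing is hard-coded.

Decisions that matter here:

* **Replicates are averaged on the CE scale**, not the $C_t$ scale, because
  CE is the linear-scale quantity that enters the downstream log-sums.
* **Per-mass normalization before flooring.** Concentrations are CE per mg
  of analyzed dust (5 mg by default, matching the extraction protocol).
  `floorConcentrations()` then raises every value below 1 CE/mg to 1. The
  order is load-bearing: flooring first and dividing later would shift
  censored values off the floor. A test asserts the pipeline floors last.
* **The floor of 1 CE/mg** makes every $\log_{10}$ term of the index
  defined and non-negative, and a fully non-detected group contributes
  exactly 0 to its log-sum. Published panel tables print 1 as their minimum
  average, consistent with this convention.
* **Spike-in QC**: every extraction carries a known *Geotrichum candidum*
  spike. If the observed spike $C_t$ deviates from its reference by more
  than 3 cycles (roughly an 8-fold recovery loss; configurable), the sample
  is flagged FAIL. Values are still reported — flagging, not censoring, is
  the QC contract.

# Per-home scores

**Moldiness index.** For a floored concentration row,
$$\mathrm{ERMI} = \sum_{i=1}^{26}\log_{10}(s_{1i}) -
\sum_{j=1}^{10}\log_{10}(s_{2j}),$$
computed by `ermiScores()`. The score is linear in the per-home log-sums, so
the cohort mean index equals the mean group-1 log-sum minus the mean group-2
log-sum *exactly* when (as here) scores are computed per home first and
averaged second. `cohortSummary()` documents that averaging order; it is
what makes the summary table internally consistent to the last digit.

**Diversity.** `shannonDiversity()` treats the floored CE/mg values of the
full panel as abundances: $p_i = v_i / \sum v$, $H = -\sum p_i \ln p_i$
(nats). Three choices were genuinely open and are resolved as follows:

* The headline "Shannon Diversity Index" is $H$ in natural-log units, the
  convention of the common alpha-diversity plotting workflows; the
  *equitability* $H/\ln 36$ (normalized by the full panel size, not by
  observed richness) and the *richness* are reported alongside, so either
  convention can be read off the same table.
* Abundances, not presence/absence: the study design quantifies, so
  diversity should too.
* Species sitting at the floor are censoring artifacts: they stay in the
  proportions (otherwise an all-floor home would have undefined $H$; with
  them it is uniform, $H = \ln 36$) but do not count toward richness.

# The statistical battery

`compareYears()` reproduces the published analysis layout: per-species
two-sided Wilcoxon rank-sum tests between years, Holm-adjusted; Student's
t-tests (pooled, $df = n_1+n_2-2$) on the per-home group log-sums and on the
index itself, reported unadjusted as in the published table.

* **Ties are the rule, not the exception** — flooring puts many homes at
  exactly 1 CE/mg. The exact mode of `wilcoxonRankSum()` therefore
  enumerates the permutation distribution of the rank sum over the observed
  mid-rank multiset (a generating-function count over all
  $\binom{n_1+n_2}{n_1}$ assignments; doubled mid-ranks keep the arithmetic
  integral), rather than using no-tie closed forms. The normal mode uses the
  tie-corrected normal approximation with continuity correction. `auto`
  switches to the approximation above $n_1+n_2 = 12$; at the study's
  20 + 20 homes the approximation is used.
* **The Holm family** is, by default, all *testable* species across both
  groups — the most conservative reading of "corrected for multiple
  comparisons". Species constant at the same value in both years carry no
  information; they are reported as `NM` (no meaning) and excluded from the
  family (`family = "per_group"` switches to within-group families).
* **Paired option.** The same homes were sampled in both years, yet the
  published analysis names unpaired tests; the battery is unpaired by
  default and `paired = TRUE` switches to signed-rank/paired-t on the homes
  present in both years.
* **Tukey HSD.** `anovaTukey()` computes Tukey–Kramer studentized-range
  comparisons on the one-way ANOVA mean square,
  $q = |\bar y_a - \bar y_b| / \sqrt{\tfrac{MSE}{2}(1/n_a + 1/n_b)}$, with
  p-values from `stats::ptukey()` (cross-checked in the test suite against
  `stats::TukeyHSD()` and, for $k=2$, against the pooled t-test through the
  $q = |t|\sqrt2$ identity). The compact letter display uses the
  insert-and-absorb algorithm and satisfies the biconditional exactly: two
  groups share a letter *iff* their adjusted p exceeds $\alpha$. Groups with
  $n < 3$ are flagged in the report — with two homes per region in the
  smallest regions, region-level letters lean on very little data.

Numerical edge cases are resolved by convention, not by error: identical
samples give $p = 1$; two constant samples with different means give
$p = 0$ with a `degenerate` flag; an ANOVA residual mean square that is zero
up to rounding noise (relative tolerance $10^{-12}$) marks the result
degenerate rather than feeding a numerically meaningless $q$ into the range
distribution.

# The synthetic cohort generator

`simulateCohort()` generates the data structure the analysis assumes, with
known ground truth:

* **Design**: 20 homes in five regions (6, 5, 2, 5, 2), each sampled in two
  consecutive years; water damage in two region-2 homes and one home each in
  regions 3 and 5; materials, ventilation and pets follow the published
  per-region characteristics. Damaged homes in regions 2 and 5 are marked
  remediated between the years; the damaged wood home in region 3 is not.
* **Abundance model**: per species, $\log_{10}$-normal concentrations,
  $\log_{10} X \sim N(\mu_s + \log_{10}(\text{effects}), \sigma_s)$ with
  $\sigma_s = 0.5$ by default. Baselines $\mu_s$ are calibrated from the
  published panel averages, clamped below at 1, so species medians span
  roughly 1–4.6 on the $\log_{10}$ scale — the spread real panels show. A
  lognormal is the simplest model consistent with a log-scale analysis; the
  generator's ground-truth table makes explicit that it is a stand-in, not
  an estimate of the real cohort.
* **Effects are multiplicative** (additive on $\log_{10}$): a 10-fold
  group-1 elevation in water-damaged homes, removed in year 2 for
  remediated homes in proportion to `remediation_recovery`, and a 3-fold
  group-2 elevation in year 2 emulating the post-hurricane phylloplane
  bloom. Additivity on the log scale gives closed-form expected shifts —
  the 3-fold bloom moves the expected group-2 log-sum by
  $10\log_{10} 3 \approx 4.77$ — which the tests and the acceptance script
  verify against the realized simulations.
* **Draws below 1 CE/mg become non-detects** (value 0, flag off), so the
  generator exercises the flooring path with the closed-form censoring rate
  $\Phi((\log_{10}\mathrm{floor}-\mu_s)/\sigma_s)$.
* **Randomness** flows from a single seed through a fixed
  species-by-home-by-year draw order. A keyed splittable stream per cell was
  considered and rejected: base R provides no splittable generator, a
  hand-rolled per-cell seeding scheme would weaken the randomness guarantees
  the calibration tests rely on, and the panel is a closed 36-species
  vocabulary, so insertion-stability is not a real use case. Identical
  configurations are bit-reproducible.

`simulateOutdoorSeries()` draws yearly outdoor spore-count series (log10
counts, normal per year) for the ANOVA/Tukey stage; its default means echo
the published three-year series with an elevated post-hurricane middle year.

What the generator does **not** emulate: spatial structure within or between
regions, within-home room effects, temporal dynamics beyond the two-year
design, between-species correlation (draws are independent given the
design), or assay cross-reactivity. Passing tests therefore demonstrate that
the pipeline recovers known effects under a clean lognormal world — not that
the model captures every feature of field data.

# What the validation runs show

The suite validates each stage against independent oracles: brute-force
subset enumeration for the exact rank-sum distribution, spreadsheet-style
recomputation of the scores, `stats::TukeyHSD()` for the range tests, and
the generator's closed forms for the simulated effects. Stochastic
calibration checks use 20 fixed-seed replicate cohorts of the default
20-home design (the size the study itself used; small enough that the whole
suite runs in about a minute): the null configuration yields zero
Holm-significant species in ≥ 18/20 cohorts (family-wise control), the
default 3-fold bloom is detected in ≥ 18/20, and the realized group-2
log-sum shift matches $10\log_{10}3$ within the generator's Monte-Carlo
spread.

One reproducibility caveat worth stating plainly: with the three published
yearly outdoor means (4.68, 4.86, 4.73), the two outer years differ by about
one within-year standard deviation, so any simulation faithful to those
means at realistic sample sizes separates 2017 from 2019 as reliably as it
separates 2018 from both — the a/b/a letter pattern of the published series
is a borderline single-dataset outcome, not a reproducible event. The letter
machinery is therefore validated on designs whose truth *is* a/b/a (outer
years equal), where it recovers the pattern in 20/20 seeds, and on the null
(a/a/a).

# Limitations

* Standard-curve parameters are inputs; the package does not estimate
  amplification efficiency from dilution series.
* No mixed-effects modelling of the repeated sampling of homes; the paired
  option is the only concession to the longitudinal design.
* The multiplicity control spans the species family only; the three
  group-level t-tests and the region-level Tukey layer are not jointly
  corrected.
* The index is reported on its natural scale; no national reference
  percentile (RVPS) comparison is attempted, as that reference distribution
  is not part of this package.
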