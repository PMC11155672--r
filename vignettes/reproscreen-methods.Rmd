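---
title: "Methods: Z-score screening, lethality statistics, and target-family enrichment"
author: "ReproScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Z-score screening, lethality statistics, and target-family enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ReproScreen)
```

# The assay and its readout

The *Green Eggs and HIM* screen detects X-chromosome segregation errors in
*C. elegans*. Hermaphrodite mothers carry a GFP reporter under a
male-specific promoter (*Pxol-1::GFP*); an embryo that received an
aberrant X complement lights up inside the mother. Because spontaneous
males are rare (< 0.2%), the fraction of worms carrying at least one GFP+
embryo is a sensitive readout of chemically induced meiotic aneuploidy.
The scored unit is the **worm**, not the embryo: a well's readout is

$$r = \frac{\#\{\text{worms with} \ge 1\ \text{GFP+ embryo}\}}{\#\{\text{worms in the well}\}}.$$

Each chemical is tested at up to four nominal concentrations (10, 30, 50,
100 µM), in 4–5 biological repeats, each as two technical replicates laid
out on two distinct plate maps so that a chemical never sits at the same
well position twice (mitigating edge effects).

# Quality control

A well is excluded when its dead-worm fraction exceeds 10% or when the
reporter is expressed ectopically (pharynx, spermatheca), both signatures
of readings that cannot be scored reliably. `qcFilter()` applies exactly
this rule — strictly greater than the threshold; a well at exactly 10%
dead is kept — and logs each exclusion with its reason. Exclusions are
the audit-relevant events of a screen, so the log is record-level while
other stages log only counts.

# Z-scores and classification

Per (chemical, concentration), technical replicates are averaged within
each biological repeat, then repeat means are averaged, unweighted, into
$x$. Averaging in this order treats each biological repeat as one
independent observation regardless of how many of its duplicates survived
QC; for balanced designs it equals pooling all wells. Within each
concentration group, over the chemicals with data,

$$z = \frac{x - \mu}{\sigma},$$

with $\mu$ the group mean and $\sigma$ its standard deviation.
Which denominator $\sigma$ uses (n−1 or n) is not determinable from the
published description, so `computeZScores()` exposes both and defaults to
the **sample** (n−1) convention; the choice is recorded in the object and
the normalization identity (non-missing $z$ per concentration have mean 0,
sd 1 under the recorded convention, tolerance 1e-9) is enforced by the
class validity method on every computed matrix.

Missing cells are typed: `NT` (never tested — many chemicals were run at
two of the four concentrations) versus `NDA` (tested, but no well survived
QC). Both are ignored by downstream rules, but they answer different
questions and are kept distinct in every export.

Classification: a chemical is **high** when any non-missing $z$ strictly
exceeds the threshold (default 1), **low** when all are strictly below it.
A maximum exactly at the threshold satisfies neither strict inequality and
is reported `unclassified` rather than silently promoted. A chemical whose
entries are all missing is `unclassified` with a warning.

```{r}
zmat <- publishedZScores()
table(classifyChemicals(zmat)$label)
countAbove(zmat, 1, minConcentrations = 2)
```

Two numerical notes. First, the Z-score is not monotone in a chemical's
own counts without qualification: under the sample convention
$\partial z_i / \partial x_i \propto 1 - z_i^2/(n-1)$, so pushing an
already extreme outlier ($z^2 > n-1$) further up can *lower* its Z-score
by inflating $\sigma$. With 133 chemicals and $|z| \le 8$ the screen is
far inside the monotone regime, and the property test exercises it there.
Second, a concentration group needs at least 3 chemicals and non-zero
spread; degenerate groups raise errors rather than returning infinities.

# Embryonic lethality

The confirmation assay exposes worms at 100 µM, lets ~100 embryos be laid
per plate, and counts hatched larvae two days later; per plate,
lethality $= 1 - \text{hatched}/\text{embryos}$. The analysis unit is the
**plate** (9 per chemical: 3 experiments × 3 plates), not the worm.

Group comparisons follow the heteroscedastic convention of common
graphing software: Welch's ANOVA F with Satterthwaite denominator degrees
of freedom, with the Brown–Forsythe F* variant computed alongside
(`welchAnova()`; both are hand-implemented — Brown–Forsythe ANOVA is in
no installed package — and Welch is cross-checked against
`stats::oneway.test`, Brown–Forsythe against its exact balanced-design
identity with the classic ANOVA F). A group with zero variance makes the
robust statistics undefined; the function falls back to ordinary ANOVA
with a warning, and errors when all observations are identical.

"Dunnett's correction" after a Welch ANOVA names a family of procedures,
not one formula. Exact Dunnett-type quantiles (studentized maximum
modulus with the control correlation) require multivariate-t machinery
not available in this environment, so `dunnettVsControl()` provides:

* `sidak` (default): per-comparison Welch t against the control, adjusted
  as $1-(1-p)^k$, computed as `-expm1(k * log1p(-p))` to avoid
  cancellation for small $p$, with a guard keeping adjusted ≥ raw;
* `bonferroni`: $\min(1, kp)$;
* `mc`: a seeded Monte Carlo estimate of the null max-|t| distribution
  that resamples the shared control group, the refinement standing in for
  the exact studentized-maximum-modulus adjustment.

Šidák is slightly conservative under the positive dependence induced by
the shared control, which is the safe direction for a confirmation assay;
the simulation suite verifies family-wise error ≤ 0.06 at k = 10 over
10,000 global-null draws. Lethality fractions are analyzed untransformed:
no arcsine or logit transform is applied by default, since the published
description mentions none and the effect sizes of interest (2% vs 20%)
are far from the boundary.

# ToxCast-style integration

For each chemical, the **bioactivity ratio** is active hit calls over
total assays tested; it is kept at full precision and rounded to 3
decimals only for display, matching the published tables. A chemical with
no assay coverage is a missing-data marker, not a zero. AC50 values (µM)
of active assays are log10-transformed; an active assay lacking an AC50 is
assigned 3.0 on the log10 scale (i.e. 1000 µM, beyond the tested range) —
the literal published convention. Group bioactivity is compared with an
unpaired two-tailed Welch t-test.

The "channel 1"/"channel 2" pseudo-families are fluorescence-readout
categories carrying no target information: they stay in bioactivity and
AC50 summaries but are excluded from family-level analysis, so a chemical
active only in channel categories drops out of the enrichment (as
methylene chloride does in the published data).

## The per-family Fisher construction

The published analysis states only that contingency tables were created
per target family and tested with `fisher.test()` at defaults. Two
constructions of the 2×2 table from the per-family counts are
implemented and documented (`familyEnrichment()`):

* `vs_rest` (default): family counts vs the remaining active counts per
  group — the standard enrichment contrast;
* `vs_total`: family counts vs the groups' total active counts.

Neither reproduces the published per-family p-values from the published
counts. This was checked exhaustively: no pair of common group margins —
two-sided or one-sided, with or without the channel categories, allowing
for an unprinted 43rd family — yields the published values for even the
four most significant families simultaneously. Two published rows
(neurodevelopment, 226 vs 125; malformation, 74 vs 28) are reported as
p = 1 although any common-margin two-sided test finds them extremely
depleted in the top group. The inescapable conclusion is that the
original per-family tables used margins not present in the published
counts (most plausibly each family's own tested-assay totals, i.e.
active-vs-inactive within family, which were not published). `vs_rest`
is the closer construction on the published rows and is the default; the
choice is recorded in the result's `construction` attribute, and the gap
is asserted — not hidden — in the acceptance tests.

FDR control is Benjamini–Hochberg with family size m equal to the number
of families tested (the published top-family adjusted value equals
p × 42). Note BH is *not* idempotent on already-adjusted values (raw
(0.25, 0.6) adjusts to (0.5, 0.6), which re-adjusts to (0.6, 0.6)); the
suite asserts monotonicity and adjusted ≥ raw instead. The overall
association uses the chi-square test of independence on the full
families × groups table, without continuity correction; given the
table's dimensions its p-value is reported but not interpreted beyond
"significant".

# The synthetic-data generator

No raw well-level data were deposited, so `simConfig()` +
`simulateScreen()`/`simulateLethality()`/`simulateAssays()` generate a
screen with the statistical structure the analysis assumes, and a single
integer seed fully determines all three tables. Defaults encode the
emulated design: 133 chemicals × 4 concentrations × 4 biological repeats
× 2 technical replicates, 100 worms per well, baseline GFP+ worm
probability 0.002, and 13 active chemicals cycling through six fixed
per-concentration shapes (strong monotonic, strong erratic, non-monotonic
low-dose, mid-dose-only, high-dose-only, mild) expressed as multiples of
baseline — non-monotonic profiles are arbitrary probability vectors, not
parametric curves, because the observed non-monotonicity has no accepted
model. GFP+ events are simulated at worm level (binomial among survivors),
matching the scored ratio; per-embryo counts are deliberately not modeled.

Where the original study quantifies nothing, defaults were chosen once
and documented: dead-worm fraction ~ Beta(1.5, 30) (mean ≈ 4.8%, ~9% of
wells beyond the 10% cutoff, so the QC filter is genuinely exercised);
ectopic-expression probability 0.02; an optional additive dead-rate shift
for edge wells, default 0 (the design motivates layout swapping but gives
no magnitude); lethality truth 0.02 baseline with the two strongest
actives at 0.20 (the reported effect size of the two quaternary ammonium
hits); assay counts per chemical uniform on 250–1250 (the range of the
published tables), per-chemical hit rate ~ Beta(2, 6) (mean 0.25, near
the reported group means), 10% of active rows missing their AC50, AC50 ~
10^N(0.5, 1) µM, and target families drawn with the published marginal
frequencies plus two channel pseudo-families.

What the generator does **not** emulate — and therefore what a green test
does not establish: image acquisition and scorer behaviour,
autofluorescence and its confusability with true signal, solubility
limits that pushed 21 chemicals below nominal concentrations,
plate-position effects beyond the optional uniform edge shift, and any
chemistry-based relationship between a structure and its effect. Green
recovery tests mean the *statistical pipeline* finds what the stated
observation model hides, nothing more.

Configuration files are JSON (`readSimConfig()`/`writeSimConfig()`); no
YAML parser is available in the supported environment.

# Design choices made where the design was open

* **σ convention**: sample (n−1) by default, switchable; unverifiable
  from the published description, so exposed rather than buried.
* **Averaging order**: technical replicates first, then biological
  repeats, both unweighted; identical to pooling for balanced designs.
* **Ties at the threshold**: `unclassified`, never `high` — the
  published rule uses strict inequalities on both sides.
* **Nominal concentration groups**: chemicals tested below nominal
  concentration (solubility) stay in their nominal group; actual
  concentration is metadata.
* **Chemical-level exclusions** (e.g. a chemical causing background
  fluorescence that defeats scoring) are an input flag
  (`excludeChemicals`) removing the chemical before Z-scoring.
* **Fisher construction**: `vs_rest` default, both exposed, choice
  recorded in output metadata (see above).
* **Dunnett post-hoc**: Šidák default with a Monte Carlo max-|t|
  refinement; exact multivariate-t quantiles unavailable here.

# Known limitations

* The published per-family Fisher p-values are not recoverable from the
  published counts (see above); the package reproduces the published
  *counts*, *totals*, and the BH arithmetic, and documents the
  construction gap.
* The published group-mean bioactivities (0.249/0.234) do not equal the
  means of the published per-chemical ratios (0.272/0.224 recomputed);
  the original inclusion set for that t-test is unclear, so those means
  are reported by the package but not asserted.
* Potency estimation (EC50 from the screen), dose–response curve fitting,
  brood-size modeling and image analysis are out of scope.
* The Fisher-vs-enumeration agreement check runs exhaustively over all
  2×2 tables with margins ≤ 16 and over seeded random tables with
  margins up to 30; the full ≤ 30 enumeration (~10^5.5 tests) is scaled
  down only for test-suite runtime.
* The Monte Carlo Dunnett refinement estimates variances from the data;
  with 9 plates per group its adjusted p-values carry simulation and
  estimation noise and the default remains Šidák.
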