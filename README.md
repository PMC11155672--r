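# ReproScreen

Analysis toolkit for a high-throughput *C. elegans* reproductive-toxicity
screen, built around the *Green Eggs and HIM* aneuploidy assay: a
*Pxol-1::GFP* reporter strain lights up male (X-segregation-error)
embryos inside exposed mothers, and the fraction of worms carrying at
least one GFP+ embryo per well is the primary readout. The package is for
toxicologists and screen analysts who need the full path from well-level
counts to ranked chemicals, confirmation statistics, and in vitro
(ToxCast-style) context — plus a seeded simulator so every stage is
testable without raw data.

## What it computes

* **Quality control** — wells with > 10% dead worms or ectopic reporter
  expression are excluded, with a per-well exclusion log
  (`qcFilter()`).
* **Z-score ranking** — per (chemical, concentration), technical
  replicates then biological repeats are averaged into a GFP+ worm ratio
  *x*, and within each concentration group *z = (x − μ)/σ* across
  chemicals (`computeZScores()`, an S4 `ZScoreMatrix` with `NT`/`NDA`
  missing-cell markers). A chemical is **high** when *z* > 1 at any
  tested concentration, **low** when *z* < 1 at all
  (`classifyChemicals()`).
* **Embryonic lethality** — per-plate lethality
  1 − hatched/embryos, Welch + Brown–Forsythe heteroscedastic ANOVA and
  control-wise Welch-t comparisons with multiplicity adjustment
  (`welchAnova()`, `dunnettVsControl()`, `lethalityAnalysis()`).
* **ToxCast integration** — per-chemical bioactivity ratio
  (active hit calls / assays tested), log10 AC50 with the missing-value
  convention log10 AC50 = 3, and per-target-family Fisher exact
  enrichment between high and low chemicals with Benjamini–Hochberg FDR
  (`bioactivitySummary()`, `log10AC50()`, `familyEnrichment()`).
* **Synthetic screens** — a validated `SimConfig` drives seeded
  generators for well, lethality, and assay tables that emulate the
  133-chemical screen's structure (`simConfig()`, `simulateScreen()`,
  `simulateLethality()`, `simulateAssays()`).
* **Published fixtures** — the published summary tables (25-chemical
  Z-score matrices, bioactivity counts, 42 target-family counts) ship as
  plain CSV and are re-analyzed by `reproducePublished()`.

## Worked example

Re-analyzing the published summary tables:

```r
library(ReproScreen)
rep <- reproducePublished()
rep$counts
#>      any atLeast2 atLeast3
#>       13        5        2
```

13 chemicals exceed Z = 1 at some concentration (the screen's 13
reported reproductive toxicants), 5 do so at two or more concentrations
and 2 — both quaternary ammonium compounds — at three or more.

A fully synthetic end-to-end run:

```r
r <- runPipeline(simConfig = simConfig(nChemicals = 20, seed = 5))
r
#> Screen pipeline run
#>   wells: 640 in, 557 kept, 83 excluded
#>   chemicals: 20 (5 high, 15 low, 0 unclassified at Z > 1)
#>   lethality: 2/20 comparisons significant
#>   enrichment: 42 families, top: Neuroactivity (p = 0.00711)

subset(r$lethality$comparisons, significant,
       select = c(group, mean, control_mean, p_adj))
#>     group      mean control_mean        p_adj
#> 1 chem001 0.2206078   0.01885781 7.089704e-06
#> 7 chem007 0.2024237   0.01885781 3.084348e-10
```

Of 640 simulated wells, 83 fail QC (dead fraction or ectopic
expression); 5 of the 13 simulated actives clear Z > 1 in this small
20-chemical run, and exactly the two chemicals simulated at 20%
embryonic lethality are flagged against the 2% DMSO control.

Enrichment from the published per-family counts (default `vs_rest`
construction; see the methods vignette for why the published per-family
p-values are not recoverable from the published counts):

```r
head(reproducePublished()$enrichment[, 1:5], 3)
#>             family count_bottom count_top     fisher_p        fdr_p
#> 1 Neurodevelopment          226       125 1.996185e-10 8.383975e-09
#> 2     Malformation           74        28 5.698460e-07 1.196677e-05
#> 3  Steroid hormone           11        37 4.157202e-04 5.820082e-03
```

## Acceptance script

`scripts/acceptance.R` recomputes, from the installed package and its
packaged fixtures, the headline classification counts of the published
screen — the number of high Z-score chemicals under the Z > 1 any-
concentration rule, and the number of chemicals above Z = 1 at two or
more concentrations — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/reproscreen-methods.Rmd`) documents the
model and its assumptions, every tunable parameter with units and
defaults, what the simulator does and does not emulate, the numerical
choices (σ convention, tie handling, degenerate inputs, the Fisher
2×2 construction question), and known limitations.
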