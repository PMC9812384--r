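# midflux

Stable-isotope tracing and bioenergetics analysis for muscle metabolism
studies.

## What it is for

In vivo steady-state tracer infusions are the workhorse for asking where a
tissue's carbon comes from. A muscle that has lost electron-transport-chain
function may stop making its own lactate from glucose and instead import
circulating lactate — a question answered by infusing labeled nutrients,
measuring mass-isotopolog distributions (MIDs) of tissue and plasma
metabolites by GC-MS, and pushing the corrected enrichments through small
steady-state models. `midflux` implements that pipeline end to end for
analysts working from integrated peak areas:

* **Natural-abundance correction.** For a derivatized fragment with known
  elemental formula, the observed envelope is `M x`, where column *j* of
  the correction matrix `M` is the convolution of the natural-isotope
  mass-shift distributions of all non-labeled atoms, shifted by *j*.
  `correct_mid()` recovers `x ≥ 0` by non-negative least squares.
* **Deuterium-lactate mixing model.** During a [2-²H]lactate infusion the
  C2 deuterium is lost on every lactate→pyruvate exchange, so tissue
  lactate m+1 reports direct import:
  `f_import = E_tissue(m+1) / E_plasma(m+1)` per animal, complement
  attributed to intramuscular pyruvate.
* **Circulatory turnover flux.** `Fcirc = R (1 − E)/E` from the tracer mass
  infusion rate and steady-state plasma enrichment (total-turnover
  convention `R/E` available).
* **Bioenergetics.** Respirometry states and the respiratory control ratio
  from plate traces with blank subtraction; adenylate energy charge;
  internal-standard quantification and ex vivo production rates; 2^−ΔΔCt;
  enzyme-activity slopes over the longest linear prefix.
* **Group statistics.** The Shapiro-Wilk → log → nonparametric decision
  cascade, multiple t tests with Bonferroni correction, altered-feature
  counts, z-score matrices, PCA summaries with 95% group ellipses.
* **Synthetic cohorts.** Generators that emulate the infusion arms, plate
  traces and metabolome tables the pipeline consumes, so every estimator is
  validated by parameter recovery from known ground truth.

## Worked example

Simulate a wild-type [2-²H]lactate infusion arm (8 animals, enrichment
noise SD 0.005), correct for natural abundance, and estimate the source
partition of tissue lactate:

```r
library(midflux)

pt  <- simulate_deuterium_lactate_arm(arm_preset("wt"), seed = 1)
est <- estimate_import_fractions(pt)
est$summary
#>   arm_label mean_import  sd_import mean_intramuscular sd_intramuscular n
#> 1        wt    0.437622 0.02409148           0.562378       0.02409148 8
```

About 44% of tissue lactate is attributed to import from the circulation
and 56% to intramuscular pyruvate — the generating preset's truth (0.44)
recovered through the full correction + mixing-model path. The same run on
the `mfn12` preset recovers ~94% import, the signature of a muscle living
off circulating lactate.

Turnover flux from an infusion:

```r
rate <- infusion_mass_rate(200, 0.1, 180.16)  # 200 mM at 0.1 ul/min/g
rate
#> [1] 3.6032
fcirc(rate, plasma_enrichment = 0.2)
#> [1] 14.4128
```

A metabolome screen with the multiple-t-test + Bonferroni convention:

```r
tab <- simulate_metabolome(n_features = 187, n_altered = 64,
                           effect_sd = 5, n_per_group = 10, seed = 7)
st  <- run_feature_stats(tab, method = "multiple_t")
count_altered(st)
#> $n_significant
#> [1] 64
#> $n_total
#> [1] 187
#> $percent
#> [1] 34
```

## Package layout

* `R/` — registry and peak-table I/O, MID math, tracer inference,
  bioenergetics, statistics workflow, synthetic cohort generators
* `inst/extdata/default_registry.csv` — editable default fragment registry
* `vignettes/tracing-methods.Rmd` — models, assumptions, parameter
  defaults, numerical choices and limitations
* `tests/testthat/` — unit, property and end-to-end recovery tests
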