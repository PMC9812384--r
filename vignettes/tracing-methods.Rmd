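---
title: "Isotope tracing and bioenergetics methods in midflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope tracing and bioenergetics methods in midflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midflux)
```

# Scope

`midflux` analyzes steady-state stable-isotope infusion experiments and
tissue bioenergetics measurements of the kind used to characterize muscle
metabolism in mitochondrial disease models: GC-MS isotopolog peak tables
from plasma, tissue and incubation medium; oxygen-consumption plate traces
from isolated mitochondria; nucleotide pools; Ct tables; and enzyme-assay
absorbance series. The package starts from integrated peak areas — it does
not read vendor raw files or integrate chromatograms — and ends at the
estimator level: source partitions, turnover fluxes, rates, ratios and
group statistics.

# Natural-abundance correction

## Model

A metabolite measured by GC-MS as a derivatized fragment (methoxime-TBDMS
adducts here) produces an isotopolog envelope M0..Mk in which mass shifts
arise from two sources: tracer atoms and naturally occurring heavy isotopes
(chiefly ¹³C at 0.0107, but also ²⁹/³⁰Si from TBDMS groups, ¹⁵N, ¹⁷/¹⁸O,
³³/³⁴S and ²H). For a fragment with elemental composition known from its
formula, the probability that a molecule carrying exactly *j* tracer atoms
is observed at shift *i* is the convolution of the single-atom mass-shift
distributions of all atoms that are not tracer-labeled, shifted by *j*.
These probabilities form the columns of a lower-triangular correction
matrix **M**; the observed envelope is **M x** for the true label
distribution **x**.

`build_na_matrix()` constructs **M** by per-element convolution;
`convolve_mid()` applies the forward model; `correct_mid()` inverts it.
The same matrix serves both directions, so the synthetic-data generators
and the correction stage share one model by construction and the
round trip is exact at zero noise (verified to 1e-8 in the tests, and the
matrix itself is checked against a brute-force enumeration of isotope
placements for small formulas).

## Numerical choices

* **Non-negative least squares, not inversion.** Plain `solve(M, b)` sends
  noisy low-abundance channels negative. `correct_mid()` solves
  `min ||M x − b||` subject to `x ≥ 0`, posed as a strictly convex
  quadratic program (`quadprog::solve.QP`), then renormalizes the first
  `n + 1` channels to a fractional MID. The problem is scaled to unit total
  signal before solving.
* **Condition-number guard.** Matrices with condition number above 1e10
  are rejected with a diagnostic rather than silently producing garbage.
* **Quality warning, not failure.** If the NNLS residual exceeds 10% of
  total signal the record is flagged with a warning; a distorted envelope
  is a QC problem, not necessarily a pipeline failure.
* **Truncation.** `max_shift` defaults to `n_tracer_atoms + 3`, enough to
  capture the Si/S isotope tail of TBDMS fragments; column sums may then be
  slightly below 1, which the renormalization step absorbs.
* **Deuterium tracers.** H natural abundance is tiny (1.15e-4) but modeled
  explicitly, because for a [2-²H]lactate infusion the m+1 channel *is* the
  readout and must be separated from the ¹³C background of an 11-carbon
  fragment.
* **Tracer purity.** An optional `purity` argument models incompletely
  labeled infusate (each nominal label heavy with probability `purity`).
  The default 1.0 assumes a pure tracer; published correction methods often
  make the same assumption implicitly, and we document rather than guess an
  impurity.

## The fragment registry

The paper trail for GC-MS corrections runs through the fragment formula,
and published studies rarely state which fragment ion was integrated. The
packaged registry (`load_registry()`) therefore ships *conventional* M-57
fragments of methoxime-TBDMS derivatives for the central-carbon set and is
explicitly user-replaceable: any CSV with
`metabolite,fragment_formula,n_tracer_atoms,pathway_tag` can be supplied.
Corrected ratios of enrichments are insensitive to moderate errors in the
non-tracer part of the formula, since those isotope contributions appear in
both numerator and denominator envelopes.

# The deuterium-lactate mixing model

At isotopic steady state during a [2-²H]lactate infusion, the C2 deuterium
is removed whenever lactate is oxidized to pyruvate, because that hydride
leaves with NADH. Lactate regenerated from pyruvate outside (or inside) the
tissue is therefore unlabeled. Tissue lactate m+1 can only come from direct
import of circulating labeled lactate, which makes the two-source mixing
model exact at steady state:

E_tissue = f_import × E_plasma + (1 − f_import) × 0

so `f_import = E_tissue(m+1) / E_plasma(m+1)` per animal
(`import_fraction_deuterium()`), and the complement is attributed to
intramuscular pyruvate reduction. Group values are means of per-animal
ratios (`arm_summary()`), not ratios of group means; each animal's plasma
enrichment is its own denominator, so animal-to-animal variation in
achieved plasma labeling cancels.

Noise can push a measured ratio above 1. The raw ratio is preserved and
flagged; only the reported fractions are clipped to [0, 1]. Denominators at
or below 0.001 enrichment — below routine GC-MS precision — are errors, not
numbers.

# Pathway-normalized enrichments and Fcirc

`normalized_enrichment()` expresses one metabolite's labeling relative to a
reference intermediate (TCA m+2 over glucose m+6; pyruvate m+3 over PEP
m+3), the standard device for separating direct from indirect pathway
contributions when absolute enrichments differ between groups.

`fcirc()` computes whole-body circulatory turnover flux from the infusion
rate and steady-state plasma enrichment. Two conventions circulate in the
tracer literature: endogenous appearance `R (1 − E)/E` and total turnover
`R / E`. The package defaults to the endogenous-appearance form and exposes
the other via `convention = "total"`; results state which was used.
`infusion_mass_rate()` converts a solution concentration and body-mass
scaled pump rate into the mass rate `R` (a 200 mM glucose solution at
0.1 µl min⁻¹ g⁻¹ is 3.6 mg min⁻¹ kg⁻¹).

# Bioenergetics

* `ocr_states()` computes basal, state 3 (post-ADP), state 4o
  (post-oligomycin), maximal (post-CCCP) and non-mitochondrial
  (post-antimycin A) respiration as window means of sample wells minus
  blank wells over the same window. The first measurement cycle after each
  injection is excluded by default: plate protocols mix for ~3 minutes
  after injecting, and that cycle straddles the transition.
  `respiratory_control_ratio()` is state 3 over state 4o.
* `energy_charge()` is `(ATP + ADP/2)/(ATP + ADP + AMP)`.
* `production_rate()` quantifies a medium time course against a spiked
  internal standard (`quantify_internal_standard()`, e.g. 200 nmol of
  fully labeled lactate) and fits an OLS line of nanomoles versus time.
  The intercept is fitted rather than forced through the origin because
  time-zero medium may carry label; `force_origin = TRUE` is available.
* `linear_activity_slope()` fits the longest initial window of an
  absorbance series with prefix R² ≥ 0.98, because enzyme assays plateau as
  substrate depletes and a global fit underestimates the initial rate.
* `relative_quantity_ddct()` assumes amplification efficiency exactly 2;
  efficiency correction is out of scope.

# Group statistics

`normality_route()` implements the decision cascade: Shapiro-Wilk per
group; if any group fails, log-transform (only if all values are positive)
and retest; if still failing, nonparametric (Mann-Whitney for two groups,
Kruskal-Wallis with Dunn's post hoc for more). Design choices where the
procedure is usually left unstated:

* *All* groups must pass for the parametric route — the conservative
  reading of per-group testing.
* Groups with n < 3 cannot be Shapiro-tested and route nonparametric with a
  warning.
* Post hoc is Tukey all-pairs by default and Dunnett when a control group
  is named.
* Degenerate (zero) within-group variance under a parametric decision
  falls back to the nonparametric test with a warning.

For abundance screens (metabolomics/proteomics) the convention is multiple
t tests with Bonferroni correction; `run_feature_stats(method =
"multiple_t")` implements exactly `min(1, m p)` and `count_altered()`
reports the significant count and nearest-integer percentage.
`zscore_matrix()` and `pca_summary()` provide the reporting summaries
(z-score heatmap input; PC scores with percent variance and
chi-square-scaled 95% group ellipses). Under the null the full cascade
holds its nominal type-I error (checked at 10,000 features in the test
suite).

# The synthetic cohort

The generators exist so that every estimator can be validated by parameter
recovery without animal data. They draw *true* enrichments from an arm
preset, forward-convolve them with the same natural-abundance matrices the
correction stage uses, and scale to ion counts.

## Presets

Four arms mirror the study conditions: `wt`, `mfn12` (double knockout),
`mfn12_hif1a_dpa` (knockout with stabilized Hif1α) and `mfn12_azd3965`
(knockout under MCT1 inhibition), with true import fractions 0.44, 0.94,
0.53 and 0.26. Plasma steady-state enrichments default to 0.10 (lactate
m+1 and m+3) and 0.15 (glucose m+6); these are plausible infusion-scale
values, and because every estimator in the package is a ratio they cancel
and carry no weight in recovery results. Default cohort size is n = 8 with
enrichment noise SD 0.005.

Two structural parameters deserve explanation because the observable
directions constrain them jointly:

* **`pyruvate_dilution`.** In the glucose arm, 3PG labeling rises in
  mutants (glycogenolysis, which dilutes 3PG with unlabeled glucosyl
  units, is impaired: `glycogen_dilution` 0.40 wt vs 0.10 mutant), yet the
  tissue lactate/pyruvate enrichment ratio must also be *higher* in
  mutants. With pyruvate labeled identically to 3PG those two directions
  are algebraically incompatible at plausible plasma lactate enrichments,
  so the generator dilutes pyruvate labeling relative to 3PG by a preset
  fraction — larger in mutants (0.50 vs 0.10), reflecting glycolytic flux
  that is small relative to pyruvate pool turnover. This is a modeling
  choice of the generator, stated here rather than hidden.
* **`glycolytic_transmission`.** In the ¹³C-lactate arm the indirect route
  (lactate → hepatic gluconeogenesis → glucose m+3 → glycolysis) must
  deliver *less* label to 3PG/PEP in mutants even though their glycogen
  dilution is lower; a transmission factor (0.60 wt vs 0.25 mutant) scales
  glucose-to-3PG label transfer to represent suppressed glycolysis.

Deuterium loss on lactate–pyruvate exchange is modeled as total, so
simulated pyruvate and alanine m+1 are zero by construction; malate
receives a `malate_transfer` fraction of the tissue lactate label to
represent deuterium transit through NADH.

## Noise model

The noise model is additive Gaussian on true enrichments, applied at each
measured node using the realized values of upstream nodes (tissue lactate
is `f_import` times the *realized* plasma enrichment, plus its own noise),
truncated to [0, 1]; ion counts get a multiplicative log-normal factor per
(sample, metabolite) that rescales a whole envelope without distorting it.
Per-isotopolog area noise would add enrichment noise on top of the stated
SD and change the stated conditions, so it is deliberately not applied.
Generators are pure functions of (preset, seed).

## What the synthetic data do not capture

Real GC-MS data carry chromatographic co-elution, detector saturation,
drifting response factors and imperfect tracer purity; the infusions
themselves have wash-in kinetics that these steady-state snapshots ignore,
and the ex vivo time course is simulated only in its linear regime. Passing
recovery tests therefore demonstrates that the estimators are correct for
the stated model, not that any instrument artifact is handled.

# Problem sizes and determinism

The packaged analyses are deliberately desk scale: arms of 8 animals,
5-metabolite panels, 187-feature metabolomes with 10 samples per group,
20-seed recovery sweeps and a 10,000-feature null calibration. Every
stochastic function takes an explicit seed, and `write_results()` emits
byte-identical output for identical configuration and seed.

# Known limitations

* The mixing model is two-source and steady state; transient label
  exchange, partial deuterium retention, and multi-tissue flux balancing
  (full ¹³C-MFA) are out of scope.
* The registry's default fragment formulas are conventions, not
  instrument-verified assignments.
* ΔΔCt assumes perfect doubling per cycle.
* OCR analysis assumes piecewise-constant states between injections; no
  kinetic fitting is attempted.
* The statistics cascade tests normality per group at fixed alpha and
  inherits the usual caveats of pretest-then-test procedures; it is
  implemented because it is the field's reporting convention, and its
  aggregate type-I behavior is verified empirically in the test suite.
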