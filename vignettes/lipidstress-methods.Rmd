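---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistics it
implements, the assumptions behind them, the defaults of the synthetic
study generator, and the design decisions taken where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The study and its data

Six treatment arms — unstressed control; corticosterone 40 mg/kg; and
corticosterone co-treated with Ze 117 at 30, 90 or 180 mg/kg or with
escitalopram at 10 mg/kg — with eight animals per arm. Two tissues are
profiled by shotgun lipidomics (direct-infusion MS): plasma (~696
species) and hippocampus (~953 species), yielding pmol amounts per
species per sample. Behavior is read out by the forced swim test: total
immobility and latency to first immobility over a 600 s session.

All analyses operate on amounts standardized within each sample to mol%
per total lipids, after values below the limit of detection (LOD) have
been replaced by zero. Zeros remain in the mol% denominator: a censored
species contributes nothing to the total, and no pseudo-counts are
introduced anywhere.

## Structural statistics

For a set of species with per-species mol% weights $w_i$, total
double-bond counts $DB_i$ and total acyl carbon counts $C_i$,

$$DB_{av} = \frac{\sum_i DB_i\, w_i}{\sum_i w_i}, \qquad
  CL_{av} = \frac{\sum_i C_i\, w_i}{\sum_i w_i}.$$

Both are mol%-weighted arithmetic means. The weighted mean is invariant
to the normalization constant of the weights, so the same formula serves
the all-lipids scope and any within-class scope without renormalizing;
per-total-lipid mol% weights are used throughout. An alternative reading
of an "all analyzed lipids" average — averaging per-class values rather
than weighting species directly — is noted but not implemented; the
species-weighted form is the one consistent with plasma values around
$DB_{av} \approx 2.7$ and $CL_{av} \approx 33$ at this composition.

The saturation partition of a class splits its per-sample class total
into the summed mol% of species with $DB = 0$ (saturated) and $DB \ge 1$
(unsaturated); the two parts add exactly to the class total.

Arm-level comparisons of these statistics use one-way ANOVA
(between/within mean squares on $k-1$ and $N-k$ degrees of freedom; the
degenerate all-equal case is defined as $F = 0$, $p = 1$) followed by
t-tests of each arm against a reference arm using the pooled
within-group variance, adjusted by the Holm–Šídák step-down rule
$\tilde p_{(i)} = \max_{j \le i}\,[1 - (1 - p_{(j)})^{m-j+1}]$, capped
at 1. Group summaries are reported as mean ± SEM (sample SD / $\sqrt n$).

## Per-lipid contrasts

For each lipid, a single one-factor cell-means linear model of mol% on
treatment arm is fit jointly over all six arms. Each of the five
contrasts of interest (corticosterone vs control; each co-treatment arm
vs corticosterone) is the difference of two arm means, tested with

$$t = \frac{\bar y_a - \bar y_b}
          {\sqrt{s^2 (1/n_a + 1/n_b)}},$$

where $s^2$ is the residual mean square pooled across *all* arms
(df $= N - k$), two-sided. Pooling is the behaviour of standard
least-squares contrast machinery on a one-factor fit; whether the
original analysis pooled variance across arms or used per-contrast
variances is not recoverable, so pooling is used and, with only two arms
present, the procedure reduces exactly to the classical pooled
two-sample t-test (a tested invariant). Fold changes are
$\log_2(\bar y_a / \bar y_b)$; a zero group mean makes the fold change
undefined and it is reported as missing with a flag rather than offset.

A lipid enters a contrast only if each condition has at least one value
above the LOD; excluded lipids keep an auditable `included = FALSE` row.
Benjamini–Hochberg FDR ($q_{(i)} = \min_{j\ge i} p_{(j)} m / j$) is
applied separately for each contrast across all included lipids of one
tissue. Volcano tables report $\log_2$ fold change against
$-\log_{10} p$ with an FDR < 0.05 significance flag; QQ tables pair the
sorted observed $-\log_{10} p$ with uniform plotting positions
$(i - 0.5)/n$.

## Behavior coupling

Species–behavior association uses Spearman rank correlation: average
ranks for ties, $\rho$ as the Pearson correlation of ranks, and a
two-sided p from the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$, appropriate at the subset sizes here
(32–48 animals). For $n \le 10$ without preference an exact permutation
p-value is available; $|\rho| = 1$ is reported at a continuity floor
rather than exactly zero. Two subsets are computed: all arms, and the
corticosterone arm together with the three Ze 117 co-treatment arms
(the escitalopram-including variant is available but not the default).
Because ranks are invariant to monotone transforms, the correlations are
unaffected by the pmol/mol% choice within a subset of one tissue.

Subgroup selection ("excluding top and bottom outliers") is made
reproducible as symmetric alternating extreme-trimming on latency: drop
the current maximum, then the current minimum, until $k$ animals remain,
ties broken by animal id. The exact rule used originally is not
recoverable; this deterministic variant never increases an arm's
variance and keeps $k$ animals per arm.

## The synthetic study generator

The generator produces the statistical structure the analysis assumes,
with known ground truth. Its defaults are the study conditions; they are
fixed once and the test suite runs against them.

**Abundance model.** Per tissue, a fixed species catalog assigns each
species a baseline share of total abundance: class shares reflecting a
plasma-like (CE/TAG/PC-dominated) or brain-like (PE/PS/plasmalogen-rich)
composition, within-class shares decaying with double-bond count and
distance from a modal carbon number, with lognormal scatter — overall
spanning roughly four orders of magnitude. Amounts are drawn as
`baseline × arm multiplier × mean-one lognormal noise` at a within-arm
coefficient of variation of 0.20 (the between-animal variance is not
recoverable from group summaries; 20% is a typical shotgun-lipidomics
figure and is a documented free knob). The mean-one parameterisation
keeps arm means calibrated, so injected $\log_2$ fold changes are
unbiased targets for recovery. The catalog and effect-target subsets are
drawn under a fixed internal structure seed, separate from the user
seed: different seeds redraw noise, never the ground truth.

**Effects.** Every arm except the unstressed control receives
corticosterone, so stress effects apply to all five
corticosterone-containing arms: a broad random-subset plasma upshift
(log2fc 0.8 on 40% of species) plus a stronger TAG upshift (0.9), which
raises the plasma $CL_{av}$ from ~34.5 to ~36 while leaving $DB_{av}$
in the 2.4–3.0 band; and a mild hippocampal PE O- subset upshift (0.6).
The treatment signal proper is a dose-ordered increase of every
unsaturated hippocampal LPE species — log2fc 0.25, 0.45, 0.70 for
Ze 117 at 30/90/180 mg/kg and 0.80 for escitalopram — on a baseline
unsaturated-LPE class total of ~0.20 mol%, so the class rises to
~0.32 mol% (Ze 180) and ~0.35 mol% (escitalopram). These numbers were
chosen once from the class-total anchors (~0.22 to ~0.29/0.31 mol%),
within their tolerance, such that per-species effects are large enough
to surface as FDR hits the way the study's LPE species do. At these
conditions the Ze-180 per-species detection rate sits near 0.8 — the
design's marginal power — while the escitalopram contrast is detected
more comfortably; the reported detection rates are measured, not
asserted.

The plasma mol% redistribution deserves a note: because mol% sums to
100, a pmol-scale upshift of many species necessarily depresses the
mol% of the remainder; the ground-truth table records pmol-scale
effects. One observed plasma pattern — a small *decrease* of $DB_{av}$
under high-dose co-treatment relative to corticosterone alone — is not
emulated: no default effect distinguishes co-treated plasma from
corticosterone plasma, which also reproduces the null co-treatment
volcano panels.

**LOD.** The limit of detection is the 2% quantile of each tissue's
generated amounts (the study's LODs are unpublished); censoring is
performed downstream by the same zero-replacement path real data take,
so the inclusion rule is exercised end to end. At the default
composition the LPE species sit well above this LOD, as they must for a
class the study quantified with tight SEMs.

**Behavior.** Latency to first immobility is
`intercept + slope × (hippocampal unsaturated-LPE mol%) + offset × I(control) + N(0, sd)`,
truncated to [0, 600] s, with defaults intercept −5 s, slope
360 s/mol%, sd 18 s, control offset +45 s. The slope and intercept put
the corticosterone arm near 69 s and the Ze-180 arm near 115 s. The
control offset encodes that the unstressed arm has *unshifted* LPE but
*high* latency — it sits off the stress axis. That term is what makes
the all-arms correlation weaker than the co-treated-subset correlation,
the qualitative behavior pattern the analysis must reproduce; without
it, a single global line through all arms would leave the all-arms
subset as well correlated as the co-treated one. Total immobility is
arm-mean Gaussian noise (SD 60 s) around plausible arm levels and
carries no lipid coupling.

**What the generator does not emulate.** Correlated noise between
species (co-regulated lipid classes), heavier-than-lognormal tails,
instrument drift and batch structure, isotope/adduct artifacts, missing
not-at-random censoring beyond a global quantile, and any
plasma–hippocampus within-animal correlation. Passing tests therefore
certify the statistical machinery under a clean version of the design,
not robustness to those real-data pathologies.

## Numerical choices and degenerate inputs

* Identification filters are strict inequalities (`> 5` and `> 5×
  blank`), matching the stated thresholds; values exactly at a
  threshold fail.
* LOD replacement is strictly `< lod`; a value exactly at the LOD
  survives.
* mol% is carried on the 0–100 scale; a sample with no positive amount
  is an error naming the sample.
* Zero pooled variance in a contrast: p = 1 when the estimate is also
  zero, else p = 0, flagged `degenerate`.
* An all-equal one-way ANOVA is $F = 0$, $p = 1$.
* Holm–Šídák and BH adjustments are capped at 1; both are tested
  against independent step-definition loops.
* Structure vs noise randomness: catalogs/effect subsets under a fixed
  internal seed, draws under the user seed; both restore the caller's
  RNG state.

## Problem sizes used by the tests

The test suite and acceptance script run the full default design (six
arms × 8, 696 + 953 species) for single-study checks; effect-recovery
and correlation properties average 10–20 replicate seeds; type-I control
uses 50 null studies of 200 species; oracle equivalences use 100–500
random instances. These sizes give stable averages for every property
checked while keeping a complete run in the low minutes on one CPU.

## Known limitations

Pooled-variance contrasts assume homoscedasticity across arms on the
mol% scale; under the generator's multiplicative noise, arms with larger
means have larger variance, so contrasts on strongly shifted species are
mildly anti-conservative — visible, if at all, in the null-simulation
false-positive fraction, which the suite checks stays at or below
nominal. The inclusion rule is the only missing-data treatment; no
imputation is offered. The parser covers sum-composition shorthand only
(class + total carbons:double bonds), not fatty-acyl-resolved or
sn-resolved names, isotope labels or adducts.
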