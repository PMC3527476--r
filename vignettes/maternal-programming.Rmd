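---
title: "Two-stage Bayesian estimation of maternal-lactation effects on dairy cow performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage Bayesian estimation of maternal-lactation effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the estimand

Most dairy cows are conceived while their mother is lactating. Early
embryogenesis then happens inside a cow in negative energy balance, where
nutrients are partitioned between the mammary gland and the conceptus, a
plausible window for prenatal programming of the daughter's adult phenotype.
`matlact` estimates the long-term association between the maternal
circumstance at conception and three adult traits of the daughter:

* **MY** — 305-d standardized milk yield of the first lactation (kg),
* **FP** — milk fat/protein ratio of the first lactation (percent), an
  indicator of metabolic strain (elevated values accompany energy deficit
  and ketosis risk),
* **DIM** — lifetime days in milk (d), a functional-longevity proxy once
  the cow's own production level is adjusted for.

Three maternal exposures are coded per cow from ordinary milk-recording
data: the **lactation-concurrence group** (0 = conceived in a non-lactating
heifer; 1, 2, 3+ = conceived during the dam's first, second, third-or-later
lactation), the **dam yield decile** (daily milk of the dam on the
conception day, classified against population decile boundaries; level 0
for heifer dams), and **mastitis exposure** (any dam somatic-cell test
above 400,000 cells/ml within 220 d after conception).

## The two-stage model

**Stage 1** is a univariate Bayesian animal model per trait,

$$y = Xb + Zu + e, \qquad u \sim N(0,\, A\,\sigma^2_u), \qquad
  e \sim N(0,\, I\,\sigma^2_e),$$

where $b$ collects the fixed environmental effects — age at first parity in
1-month classes, year-region of birth, herd-year of first calving, and (for
DIM only) the first-lactation milk yield as a centered covariate absorbing
culling-for-low-production — and $u$ is the additive genetic merit with the
pedigree numerator relationship matrix $A$. Fixed effects take flat priors
through a full-rank treatment-contrast design; variance components take
scaled-inverse-chi-square priors with $\nu = 4$ and scales from a paternal
half-sib ANOVA moment estimate (see *Numerical choices*). A single-site
Gibbs sampler (compiled, sparse) draws every location parameter from its
normal full conditional and each variance from its scaled-inverse-chi-square
conditional; $A^{-1}$ is assembled directly by Henderson's rules with
inbreeding-corrected Mendelian-sampling variances, never by inverting $A$.

Stage 1 returns posterior-mean residuals
$\hat e_i = y_i - x_i^\top E(b) - z_i^\top E(u)$: the cow's performance free
of the modelled environmental and genetic effects.

**Stage 2** regresses those residuals on one maternal factor at a time,

$$\hat e = \mu\,\mathbf{1} + m_{g(i)} + \varepsilon,$$

with an effectively flat normal prior (variance $10^{10}$) on $\mu$ and on
every level effect $m_g$ (including the reference), and a
scaled-inverse-chi-square prior on the residual variance. Individual level
effects are not identified under this parameterisation — only contrasts are,
and only contrasts are reported: for each level the posterior of
$m_g - m_0$ is summarised by its mean, a batch-means Monte-Carlo standard
error, the 2.5th–97.5th sample-quantile interval ("HPD95" in the original
report's usage; it is an equal-tail interval and we implement exactly that
definition), and the posterior probability of each sign. Residuals keep
trait units, so contrasts read directly as kg, d or percentage points.

A complementary analysis refits the concurrence question inside the top and
bottom deciles of the posterior-mean breeding values: within each stratum an
ordinary linear model `residual ~ concurrence` gives the coefficient and
standard error.

The chain default is the routine-evaluation setting: one chain of 10,000
iterations, 1,000 discarded. The verification runs below use 5,000/500,
which diagnostics (batch-means MCSE a few % of the posterior sd) show is
ample for these conjugate samplers.

## The synthetic herd generator

National milk-recording data are proprietary, so every claim the package
makes is verified by parameter recovery on synthetic herds
(`simulate_herd()`). The generator reproduces the structural features the
two-stage analysis relies on:

* a discrete-generation pedigree with a small sire pool (large paternal
  half-sib families, as under AI breeding) and founders treated as
  unrelated and non-inbred;
* breeding values simulated down the pedigree with Mendelian-sampling
  variance $\sigma^2_u(0.5 - 0.25(F_s + F_d))$;
* each female's reproductive timeline: age at first conception
  $\sim N(17.2, 1.2^2)$ months, four parities chained by gestation (282 d)
  plus a conception-DIM draw;
* conception DIM from a log-normal calibrated numerically so the mode is
  73 d and 80% of mass lies in 54–160 d — the only two summaries available
  for the breed (the calibration solves one equation in the log-sd after
  substituting the mode constraint);
* dam daily milk on the conception day interpolated from the open
  lactation's 305-d total with a normalized Wood curve
  $t^{0.2}e^{-0.004t}$ (peak near 50 DIM);
* herd-year and year-region effects drawn Normal with configurable spread
  (the source analysis gives no distributional detail; this is a documented
  modelling choice, not an inference);
* mastitis episodes: a planted somatic-cell test above the threshold inside
  the gestation window, at 13% incidence among analysis cows; baseline
  tests are truncated just below the threshold so exposure is exactly
  recoverable from the test table (a deliberate simplification — real SCC
  baselines occasionally cross the threshold);
* planted maternal effects per trait: lactation-group effects, dam-decile
  effects, a mastitis effect, and an optional merit-by-concurrence
  interaction applied to concurrent cows in the true top merit decile;
* lifetime DIM built as a Gaussian trait whose mean is linear in the cow's
  first-lactation milk (0.05 d/kg), exercising the functional-longevity
  covariate. (A heavier-tailed exponential culling process is a
  plausible alternative; the Gaussian choice keeps the stage-1 adjustment
  exactly specified, so recovery tests measure pipeline correctness rather
  than robustness to misspecification.)

Birth-order composition (36/31/20/13% for groups 0/1/2/3+) follows the
published group counts. Recorded daughters are a *random subset* of each
dam's four parities rather than a nested first-$K$ block: only part of a
cow's calves are female and retained, and — importantly for verification —
nesting would make family size predict the family-mean maternal effect,
letting the animal model absorb maternal signal into breeding values.

### What the generator deliberately controls

A recovery harness must keep the planted exposure orthogonal to everything
stage 1 adjusts for; three design features do this, and they are the main
difference between the `recovery` and `paper_scale` presets:

1. **Overlapping cohorts.** Founders enter over 20 years and the analysis
   keeps only cows calving in the central 80% of years. Birth order is
   mechanically confounded with calendar time *within* a dam (each later
   parity is ~380 d later), so with synchronized cohorts the year-linked
   fixed effects absorb 10–25% of any planted group contrast.
2. **Rotation herd allocation.** Within each calving year, analysis cows
   are dealt to herds in rotation ordered by exposure group, so every
   herd-year cell holds a near-proportional group mix. With $p$ flat-prior
   fixed-effect levels and $n$ records, randomly composed cells absorb an
   $O(p/n)$ share (~3% here) of any unmodelled group signal — the
   Gauss–Markov projection loss. `paper_scale` instead uses realistic herd
   inheritance (daughters mostly stay in the dam's herd).
3. **Small genetic shrinkage leak.** A cow's residual loses a fraction
   $\approx 1/(1 + 2\lambda)$, $\lambda = \sigma^2_e/\sigma^2_u$, of her own
   unmodelled maternal effect into her breeding value. The recovery preset
   sets heritability to 0.01 so this leak stays below ~1.5%, while other
   tests exercise the sampler at heritability 0.3. With the preset's
   shrunken residual sds (100 kg MY, 0.15 points FP, 30 d DIM) the planted
   contrasts of tens of units are estimable from ~10,000 cows.

After these choices the measured recovery bias for the planted MY contrasts
(−18/−47/−91 kg) is +0.5/+1.9/+1.7 kg over 12 replicate seeds; what remains
per run is the generator's own sampling noise (the group-3+ contrast has a
data-level standard error of ~3.3 kg at these sizes, so even a perfect
estimator misses a ±5 kg band on roughly one seed in eight).

## Verification protocol and problem sizes

The test suite asserts, among others: exact pedigree algebra
($A^{-1}A = I$ against the dense tabular recursion on pedigrees of a few
hundred; inbreeding against a gene-dropping Monte-Carlo oracle with $10^5$
allele drops; $\mathrm{diag}(A) = 1 + F$); closed-form conjugate posteriors
and the mixed-model-equation solutions at fixed variances; heritability
recovery (0.3 ± 0.08 at ~3,000 cows); 95% equal-tail interval calibration
over 120 replicate stage-2 simulations; flat-prior convergence to OLS group
means at two prior magnitudes; null recovery (all contrasts within three
data standard errors of zero when nothing is planted); and full-pipeline
recovery of the published effect sizes, asserted on the mean over three
fixed seeds of recovery runs with ~12,000 simulated cows (~9,800 analysed
after the window and filters), pedigrees of ~13,600, and 5,000-iteration
chains. These sizes keep the full suite within a few minutes on one CPU
while leaving the Monte-Carlo error well inside every asserted tolerance.

## The merit-stratified analysis attenuates, necessarily

One published quantity cannot be recovered at its printed size by this
design, and the package reports that honestly. The merit-stratified model
selects the top decile of *estimated* breeding values. At heritability 0.3
the reliability of an EBV built from one own record plus half-sib family
information is ~0.45 ($r \approx 0.67$), which caps the overlap between the
estimated and true top deciles near 35% (bivariate-normal tail
concordance). A concurrence penalty planted only for true-top-decile cows
is therefore diluted ~3× in the estimated stratum; worse, affected cows
have their breeding values dragged down by the penalty itself and are
preferentially selected *out* of the top stratum. Planting the published
−90 kg yields a measured top-stratum coefficient of −15 to −24 kg across
seeds (bottom stratum compatible with zero, as published). No admissible
generator reproduces −90 under honest selection on estimated merit; the
corresponding acceptance check is left failing with this analysis as the
explanation.

## Numerical choices

* **Variance priors.** $\nu = 4$; scales from an unbalanced one-way
  paternal half-sib ANOVA: $S^2_u = 4\,\hat\sigma^2_{sire}$ (clipped to
  $[0.005, 0.9]\cdot\widehat{var}(y)$), $S^2_e = MS_W - 0.75\,S^2_u$. At
  low heritability $\sigma^2_u$ is weakly identified and an arbitrary
  scale (e.g. $0.25\,\widehat{var}(y)$) measurably inflates the posterior
  and with it the shrinkage leak above.
* **Sampler hygiene.** The cached products $W^\top W\theta$ and
  $A^{-1}u$ are updated incrementally and recomputed exactly every 200
  sweeps to cancel round-off drift; full-conditional precisions are checked
  positive; a non-positive Mendelian-sampling variance (corrupt inbreeding
  input) is a hard error.
* **Quantiles and ties.** Decile boundaries use linear-interpolation
  quantiles; groups are left-open/right-closed, so a dam exactly on a
  boundary falls in the lower group; with heavy ties groups are unequal and
  may collapse. Merit percentile sets break ties by cow id, making set
  sizes exact and runs reproducible.
* **Degenerate inputs.** Cycles and duplicate ids in pedigrees, zero-count
  factor levels, single-level strata, conceptions before the dam's birth,
  non-positive lactation lengths, and infeasible conception-DIM
  calibrations all raise immediate, named errors.
* **Dates** are integer days from an arbitrary origin; herd-year and
  year-region labels derive deterministically from them, so the generator
  and the preprocessing step can never disagree on level coding.

## Limitations

* Stage 2 treats stage-1 posterior-mean residuals as data; the stage-1
  posterior uncertainty is not propagated (by design, mirroring the
  two-stage scheme it implements).
* Maternal factors are fitted one at a time; joint modelling of concurrence
  with yield level, and any interaction between them, is out of scope.
* Unknown parents are unrelated founders; no genetic groups, no genomic or
  dominance relationships.
* Passing recovery tests demonstrates correctness *under the generator's
  assumptions* (Gaussian effects, exact model for stage 1, exactly coded
  exposures). Real recording data have misclassified exposures, selection,
  and heterogeneous variances that the generator does not emulate — except
  optionally via the `paper_scale` preset, which restores realistic herd
  inheritance, heritability 0.3 and full-scale noise, and is the honest
  setting for method-behaviour studies rather than correctness checks.
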