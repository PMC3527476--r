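# matlact

Two-stage Bayesian analysis of how the concurrence of early gestation with
the dam's lactation shapes the adult performance of dairy cows.

Most dairy cows are conceived while their mother is still milking, i.e.
during a period of strong metabolic load and negative energy balance — a
plausible window for prenatal programming. Given ordinary milk-recording
data (a pedigree plus longitudinal lactation records), `matlact` estimates
the association between the maternal circumstance at conception and three
adult traits of the daughter: 305-d standardized milk yield (MY, kg), milk
fat/protein ratio (FP, %; a metabolic-strain indicator) and lifetime days
in milk (DIM, d; a functional-longevity proxy).

The method is a two-stage scheme used in quantitative genetics:

1. **Stage 1 — animal model.** Each trait is adjusted by a Gibbs-sampled
   Bayesian animal model `y = Xb + Zu + e`, with fixed environmental
   effects (age at first parity, year-region of birth, herd-year of first
   calving, and a milk covariate for the longevity trait), additive genetic
   merit `u ~ N(0, A σ²_u)` structured by the pedigree numerator
   relationship matrix, flat priors on `b` and scaled-inverse-chi-square
   priors on the variances. The sparse `A⁻¹` is built by Henderson's rules
   from Meuwissen–Luo inbreeding coefficients.
2. **Stage 2 — maternal circumstance.** The posterior-mean residuals are
   regressed on one maternal factor at a time (lactation-concurrence group
   0/1/2/3+, dam yield decile 0–10, mastitis exposure 0/1) under
   effectively flat priors. Each contrast against the heifer-dam reference
   is summarised by its posterior mean, batch-means Monte-Carlo standard
   error, equal-tail 95% interval and sign probability. A complementary
   model refits the concurrence effect inside the top and bottom deciles of
   estimated genetic merit.

Because national milk-recording data are proprietary, the package includes
a synthetic herd generator (`simulate_herd()`) that emulates the relevant
structure — overlapping cohorts, half-sib pedigrees, conception timing
calibrated to a mode of 73 days in milk with 80% of conceptions in 54–160
DIM, dam lactation curves, somatic-cell tests, record filters — and plants
known maternal effects, so the entire pipeline is verifiable by parameter
recovery. See the methods vignette
(`vignettes/maternal-programming.Rmd`) for the model, the generator design
and its limitations.

## Worked example

Simulate a herd with the published lactation-concurrence effects planted on
milk yield (−18, −47, −91 kg for concurrence with the dam's first, second,
third-or-later lactation), then recover them with the two-stage pipeline:

```r
library(matlact)

cfg  <- plant_effects(sim_config("recovery"), factors = "lact")
herd <- simulate_herd(cfg, seed = 20)

flt   <- apply_filters(herd$cows, herd$lactations, herd$pedigree)
pheno <- derive_traits(flt$cows)
circ  <- assign_circumstance(flt$cows, herd$lactations, herd$scc,
                             herd$pedigree, wood = cfg$wood)

fit <- fit_animal_model(stage1_model(pheno, herd$pedigree, "my"),
                        gibbs_config(5000, 500, seed = 21))
s2  <- fit_maternal_model(unname(fit$residuals), circ$lact_group,
                          gibbs_config(5000, 500, seed = 22))
all_contrasts(s2)
#>   level reference  mean   mcse hpd_low hpd_high prob_neg prob_pos
#> 1     1         0 -17.0 0.0411   -21.6    -12.3        1        0
#> 2     2         0 -45.6 0.0418   -51.0    -40.4        1        0
#> 3     3         0 -82.4 0.0528   -88.6    -76.2        1        0
```

Reading: cows conceived during their dam's first lactation produced on
average 17 kg less milk in their own first lactation than cows conceived in
a non-lactating heifer (planted: 18 kg), with the penalty growing with the
dam's lactation number; every 95% interval excludes zero and the
Monte-Carlo error of each posterior mean is well below a tenth of a
kilogram. `run_pipeline(pipeline_config(...))` orchestrates the same steps
for all traits and factors from files, writing every intermediate artifact,
metadata sidecars and a Markdown report
(`inst/scripts/run_pipeline.R` is a thin command-line wrapper).

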