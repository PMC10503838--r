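# photogam

Analysis of larval-fish locomotor photoadaptation assays: per-second
distance traces recorded in multiwell plates under programmable dark-light
regimens, modelled with penalized-spline additive models and summarized as
per-second group contrasts and per-photoperiod proportions of significance.

Larvae barely move in darkness, burst in light, and — after the lights go
out — transiently move *more* in the dark the longer they were illuminated
(a dark rebound whose onset efficiency differs between genotypes). Raw
per-fish data are zero-inflated and severely right-skewed, so classical
linear models on individual fish are inappropriate. The pipeline
implemented here instead:

1. computes the **rolling sum** response: distance summed over the trailing
   60 s at every second (mm/min), averaged across the fish of each group
   within each assay — the assay-level group mean is the analysis unit;
2. fits an identity-link Gaussian **additive model** with a penalized
   smooth of time per group and an assay-level random intercept,

   `rsums ~ geno + s(time_s, k, by = geno) + (1 | assay)`

   using cubic P-splines (second-order difference penalty) with REML or GCV
   smoothness selection, plus Wald term tests, a basis-dimension adequacy
   check and AIC comparison;
3. evaluates **estimated marginal means** per group and all pairwise
   differences at every analysed second, with Tukey adjustment from the
   studentized range distribution;
4. collapses the trajectory into the **proportion of significance**: the
   fraction of seconds in a set of photo periods where one group moved
   significantly more than another in a fixed direction;
5. compares proportions across assay regimens with the **two-proportion z
   test with Yates' continuity correction**.

A zero-inflated Gamma simulator generates complete synthetic studies
(photoperiod-locked dynamics, duration-dependent dark rebound, between-assay
variability) with known ground truth, so the entire pipeline is testable
without any recorded data. See `vignettes/photogam-methods.Rmd` for the
models, parameter choices and known limitations.

## Worked example

Simulate a reduced dark-light repeat study (two cycles of 7.5-min dark +
2-min light) with wild-type and homozygous-mutant groups, fit the model, and
summarize the dark-phase contrast:

```r
library(photogam)

regimen <- build_repeat_regimen(acclim_min = 10, n_cycles = 2,
                                dark_min = 7.5, light_min = 2,
                                final_dark_min = 5)
cfg <- sim_config(regimen = regimen, n_assays = 6, n_fish_per_group = 12,
                  groups = default_genotypes()[c("WT", "HM")], seed = 42)
study <- simulate_study(cfg)

series <- aggregate_group_mean(study$traces, stride_s = 1, start_s = 600)
spec <- model_spec("rsums", parametric = "geno",
                   smooths = list(smooth_term("time_s", k = 20, by = "geno")),
                   random = "assay_id")
fit <- fit_gam(build_design(spec, series))
fit
#> <pgam> n = 17280, total edf = 44.90, deviance explained = 95.2%
#> terms:
#>   parametric                   edf    2.000
#>   s(time_s):genoWT             edf   18.938
#>   s(time_s):genoHM             edf   18.968
#>   s(assay_id)                  edf    4.996

traj <- pairwise_trajectory(fit, "geno",
          times = unlist(lapply(c("dark2", "dark3"), period_seconds,
                                regimen = regimen)))
proportion_significant(traj, regimen, c("dark2", "dark3"),
                       pair = c("WT", "HM"), direction = "WT")
#> WT > HM over dark2 u dark3: 750 / 750 analyzed seconds = 100.00%
```

The fit explains 95% of the variation in the group-mean trajectories; the
genotype main effect and both time smooths are overwhelmingly significant;
and in every analysed dark-phase second after illumination the wild types
moved significantly more than their mutant siblings — the mutants' rebound
half-saturation (6 min vs 1 min) leaves them far below wild-type dark
locomotion after only 2 min of light.

`run_pipeline()` chains all stages (simulate/ingest → aggregate → fit →
contrasts → proportions → regimen comparison) with artifacts persisted per
arm and a machine-readable report; `inst/cli/photogam` is a thin command-line
wrapper over the same functions.

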