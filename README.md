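# rubiflux

Rubisco-coupled strain design and ¹³C flux partitioning in R.

Heterotrophs such as *E. coli* do not need rubisco. To select for and study
CO₂-fixation machinery in such a host — for instance a transplanted
CO₂-concentrating mechanism — one engineers a strain whose growth *requires*
rubisco carboxylation, then measures how much carbon fixation actually
happens in vivo. `rubiflux` implements the computational workflow around
that idea, for metabolic engineers and systems biologists:

- **Flux balance analysis** on stoichiometric models (JSON, or an SBML
  subset): maximize biomass flux *c*ᵀ*v* subject to *S v* = 0 and bounds,
  plus flux variability analysis. Solved by an in-package two-phase simplex
  with Bland's anti-cycling rule, verified against mass balance on every
  solve.
- **OptSlope-style knockout screen**: enumerate deletion sets that abolish
  growth unless a heterologous detour — phosphoribulokinase
  (Ru5P → RuBP) plus rubisco (RuBP + CO₂ → 2 × 3PG) — is present, and
  quantify coupling as the slope of minimum rubisco flux against biomass.
- **Rubisco kinetics** under competitive O₂ inhibition:
  v_C = kcat_C·[CO₂]/([CO₂] + K_C·(1 + [O₂]/K_O)) and its oxygenation
  mirror image, with the exact specificity identity
  v_C/v_O = S_C/O·[CO₂]/[O₂].
- **Isotope inference**: from ¹³C isotopologue distributions of
  protein-bound serine (and MRM fragment integrals resolving its carboxyl
  carbon within the M+2 population), estimate the fraction *x* of
  3-phosphoglycerate synthesis due to rubisco via a two-source mixture
  model, f12C_cbx = b + x·d·(c − b), with the background *b* measured from a
  rubisco-independent control.
- **Growth statistics**: endpoint t-intervals and a percentile bootstrap
  (resampling replicate curves) for the growth effect at an evaluation time.
- **Synthetic data** with known ground truth for every stage: a 9-reaction
  carbon-balanced toy network where deleting the ribose-phosphate isomerase
  strands Ru5P, seeded labeling tables, and replicate growth curves.

All user-facing functions take and return tibbles where the data are
tabular, chain with the pipe, and expose `tidy()`/`glance()`/`autoplot()`
methods for fitted objects.

## Worked example

Screen the toy network for rubisco-coupled knockouts, predict rubisco's
share of 3PG synthesis, and compare with a labeling-based estimate:

```r
library(rubiflux)

toy <- make_toy_model()
het <- toy_heterologous_spec()

scan_knockouts(toy, het, sources = "EX_glyc")
#> # A tibble: 1 × 7
#>   deleted_ids n_deleted source  growth_without growth_with slope intercept
#>   <chr>           <int> <chr>            <dbl>       <dbl> <dbl>     <dbl>
#> 1 T5_rpi              1 EX_glyc              0           5  2.00  3.43e-15
```

Only the isomerase deletion qualifies: it cannot grow without the detour
(`growth_without` 0), grows at biomass flux 5 with it, and every unit of
biomass then forces 2 units of rubisco flux (`slope` 2). The FBA-predicted
rubisco share of 3PG production in that strain:

```r
rescued <- apply_knockouts(make_toy_model(include_heterologous = TRUE),
                           "T5_rpi")
predicted_rubisco_3pg_fraction(rescued, het)
#> # A tibble: 1 × 4
#>   point    lo    hi accounting
#>   <dbl> <dbl> <dbl> <chr>
#> 1  66.7  66.7  66.7 molecules
```

66.7% of 3PG molecules are rubisco-derived (20 of 30 per 10 glycerol taken
up), and the FVA range collapses because rubisco flux is fully coupled.
Now simulate a labeling experiment with a known ground truth of 14% and
recover it from the serine M+2 MRM channel:

```r
sim <- simulate_labeling(x_true = 0.14, n_replicates = 4, depth = 1e5,
                         seed = 2)
estimate_rubisco_fraction(sim$iso, sim$mrm, mode = "carboxyl_mrm")
#> <flux_fraction_estimate> mode: carboxyl_mrm, 4 replicates
#>   mean x = 0.1358, min x = 0.1297, background b = 0.009844
```

Finally, the growth effect of an intervention at 80 h with its 99.9%
bootstrap confidence interval:

```r
curves <- simulate_growth_curves(effect = 0.6, noise_sd = 0.02,
                                 n_replicates = 3, seed = 3)
bootstrap_effect_ci(curves, t_eval = 80, seed = 4)
#> <bootstrap_ci> effect = 0.6221 OD, 99.9% CI [0.5906, 0.6405]  (10000 resamples, seed 4)
```

The methods vignette (`vignettes/rubisco-coupling.Rmd`) documents the
models, conventions (3PG accounting, MRM conditioning, bootstrap resampling
unit) and numerical choices in detail. A thin CLI over the same functions
ships in `inst/cli/rubiflux.R`.

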