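---
title: "Designing and quantifying rubisco-coupled growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and quantifying rubisco-coupled growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rubiflux)
```

# The problem

A heterotroph like *E. coli* has no use for rubisco. To study CO~2~ fixation
machinery in it — for example a transplanted CO~2~-concentrating mechanism —
one first needs a strain whose *growth* depends on rubisco carboxylation, so
that selection and phenotyping report on carboxylation activity. This package
implements the computational side of that program:

1. **Strain design.** Find knockouts of a stoichiometric model whose growth
   becomes impossible without a heterologous detour (phosphoribulokinase,
   Ru5P + ATP &rarr; RuBP; rubisco, RuBP + CO~2~ &rarr; 2 &times; 3PG) and
   quantify how tightly rubisco flux is then coupled to biomass.
2. **Kinetics.** Compute carboxylation/oxygenation rates versus CO~2~ under
   competitive O~2~ inhibition, the quantitative rationale for concentrating
   CO~2~ around the enzyme.
3. **Flux partitioning from labeling.** Infer, from ^13^C isotopologue data
   of protein-bound serine, what fraction of 3-phosphoglycerate (3PG)
   synthesis is due to rubisco *in vivo*.
4. **Growth statistics.** Summarize endpoint phenotyping and bootstrap the
   effect size of a growth intervention on replicate OD~600~ curves.

A synthetic-data layer generates every input with known ground truth, so the
whole pipeline is testable without any external download.

# Flux balance analysis and the knockout screen

A model is a stoichiometric matrix $S$ with flux bounds; FBA solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; lb \le v \le ub,$$

with $c$ selecting the biomass reaction. Uptake is a negative flux through an
`EX_*` exchange; `set_carbon_source()` opens exactly one organic source at a
time, which mirrors single-carbon-source growth experiments.

The screen (`scan_knockouts()`) enumerates deletion sets of size one or two
over a caller-chosen candidate list, keeps those where growth is impossible
without the detour (optimum $< 10^{-6}$, the "no growth" threshold — LP
solvers return tiny nonzeros) but possible with it, and measures coupling:
biomass is pinned at `n_grid = 5` evenly spaced values in $(0, \mu_{max}]$,
the minimum rubisco flux is found at each, and the slope and intercept of
that line summarize how much carboxylation every unit of growth *requires*.
The grid itself is retained in the result so that any other functional of
the coupling curve can be recomputed later; we deliberately do not commit to
a single scalar score beyond the fitted slope and intercept.

## The toy network

`make_toy_model()` builds a deterministic 9-reaction, carbon-balanced
caricature of pentose phosphate metabolism on glycerol in which ribose
5-phosphate (Ri5P) synthesis forces co-production of ribulose 5-phosphate
(Ru5P). Deleting the isomerase `T5_rpi` strands Ru5P, and only the prk +
rubisco detour can drain it:

```{r toy}
toy <- make_toy_model()
fba(toy)$objective_value                              # wild type: 3.75
fba(apply_knockouts(toy, "T5_rpi"))$objective_value   # dead end: 0
rescued <- apply_knockouts(make_toy_model(include_heterologous = TRUE),
                           "T5_rpi")
fba(rescued)$objective_value                          # rescued: 5.0
coupling_slope(rescued, toy_heterologous_spec())
```

All of these optima are hand-derivable (per unit biomass the wild type needs
8/3 G3P; the rescued strain nets 2 G3P and exactly two carboxylations), and
the test suite locks them against both the hand values and an exhaustive
grid-search LP oracle.

## Numerical choices

No linear-programming package is available to this package's dependency set,
so the solver is an in-package dense two-phase primal simplex (`R/lp.R`)
using **Bland's smallest-index rule**. The choice is deliberate: knockout
models are heavily degenerate (zero-pinned fluxes, alternate optima, FVA on
the optimal face), which is exactly where naive pivoting stalls or cycles;
Bland's rule is provably finite, and dense tableau arithmetic is irrelevant
at tens of reactions. Further conventions:

* pivot/feasibility tolerance $10^{-9}$; every reported optimum is verified
  post hoc against $\max |S v| < 10^{-6}$ and the bounds before it is
  accepted — solver failure is reported as a status, never as silent zeros;
* infinite bounds are boxed at $\pm 10^4$ mmol gDW^-1^ h^-1^ (far above any
  flux a bounded model here can carry); an optimum pinned at that cap on an
  unbounded direction is reported as `unbounded`;
* documents omitting bounds get $(-1000, 1000)$ if reversible, $(0, 1000)$
  otherwise;
* when biomass is pinned (coupling grid) or the objective is constrained
  (flux variability), the constraint is backed off by a relative $10^{-9}$
  so that the optimum's own float round-off cannot render the face empty;
* alternate optima are handled by `flux_variability()`, never by relying on
  which vertex the simplex happens to return.

## The predicted rubisco share of 3PG synthesis

`predicted_rubisco_3pg_fraction()` reports rubisco's share of the gross
production flux into the 3PG pool, counting only positive contributions.
Because one carboxylation makes *two* 3PG molecules, two accountings exist
and the package exposes both. `"molecules"` (default) counts $2 v_{rub}$ in
numerator and denominator; it is the convention consistent with the labeling
mixture model below, where the pool-dilution parameter $d = 1/2$ separately
tracks which of the two molecules carries the CO~2~-derived carbon — so the
FBA prediction and the labeling estimate are comparable like for like.
`"events"` counts one unit per carboxylation event instead. On the toy
network at glycerol uptake 10 the two give 66.7% (20 of 30 molecules) and
50% (10 of 20 units). The FVA-derived range is evaluated on the full flux
vectors at the extremes of $v_{rub}$, not by scaling the point estimate.

# Rubisco kinetics under competitive O~2~ inhibition

CO~2~ and O~2~ compete for the same reaction intermediate, so each gas is a
competitive inhibitor of the other:

$$v_C = \frac{k_{cat}^C\,[\mathrm{CO_2}]}{[\mathrm{CO_2}] + K_C\,(1 + [\mathrm{O_2}]/K_O)},
\qquad
v_O = \frac{k_{cat}^O\,[\mathrm{O_2}]}{[\mathrm{O_2}] + K_O\,(1 + [\mathrm{CO_2}]/K_C)}.$$

Raising CO~2~ increases $v_C$ toward an unchanged $v_{max}$ and strictly
suppresses $v_O$ — the entire quantitative benefit of a CO~2~-concentrating
mechanism in two formulas. The identity
$v_C / v_O = S_{C/O} \,[\mathrm{CO_2}]/[\mathrm{O_2}]$ with
$S_{C/O} = (k_{cat}^C/K_C)/(k_{cat}^O/K_O)$ holds exactly and is asserted to
$10^{-12}$ in the tests. Kinetic constants vary several-fold across rubisco
forms, so they are required arguments with no silent defaults; the
documentation uses a representative Form IA-like set
($k_{cat}^C = 10\,s^{-1}$, $K_C = 150\,\mu M$, $k_{cat}^O = 1\,s^{-1}$,
$K_O = 200\,\mu M$). Concentrations are dissolved-phase micromolar
throughout ($270\,\mu M$ O~2~ is air-equilibrated water); Henry-law
conversions from gas phase are out of scope.

# Inferring the rubisco flux share from ^13^C labeling

Cells grown on 99% ^13^C glycerol make almost fully ^13^C-labeled
glycolytic 3PG, while ambient ^12^CO~2~ is the dominant source of ^12^C.
Serine is synthesized from 3PG carbon-for-carbon, so excess ^12^C on serine
— and specifically on its carboxyl carbon, which maps to the carbon rubisco
fixes — reports the balance of rubisco versus glycolytic 3PG production.

## The mixture model

Let $b$ be the per-carbon ^12^C probability of glycolytic 3PG, $c$ the
^12^C fraction of intracellular CO~2~ (default 0.989, natural abundance),
$d$ the fraction of rubisco-derived 3PG molecules carrying the CO~2~ carbon
(default 1/2), and $x$ the rubisco share of 3PG production. Then

* total serine: $f_{12C} = b + x\,d\,(c - b)/3$ (the excess is diluted over
  serine's three carbons), giving
  $\hat x = 3 (f_{12C}^{exp} - b) / (d (c - b))$;
* carboxyl carbon: $f_{12C}^{cbx} = b + x\,d\,(c - b)$, giving
  $\hat x = (f_{12C}^{cbx,exp} - b) / (d (c - b))$.

$b$ is *measured* from a rubisco-independent control strain rather than
computed from substrate purity plus natural abundance: the control captures
every systematic effect (amino-acid turnover, media carryover) that a purity
calculation would miss. Purity-based expectations remain available in the
simulator. If $c \le b$ there is no isotopic contrast and the estimator
refuses to run. Estimates are clipped to $[0, 1]$ with an explicit flag;
replicates are aggregated as an unweighted mean, with the minimum also
reported as a conservative "at least" bound.

## MRM conditioning

The carboxyl channel is measured by multiple reaction monitoring on the
serine **M+2** parent ion: channel A (61.1 m/z) collects ions whose carboxyl
carbon is ^13^C, channel B (62.1 m/z) those where it is ^12^C. This is a
fraction *conditional on M+2*, not the marginal carboxyl fraction: with
serine mostly ^13^C, M+2 means exactly one ^12^C among three carbons, and
for the control the conditional fraction is $1/3$ *regardless of* $b$.
Writing $u = B/(A+B)$ and assuming positions label independently, the exact
inversion to the marginal probability $p$ is the odds relation

$$\frac{p}{1-p} = \frac{2\,b\,u}{(1-b)(1-u)},$$

which the estimator applies before the mixture formula ($b$ itself comes
from the control's total serine ^12^C, since the control MRM channel is
uninformative about it). The simulator generates MRM pairs from the M+2
subpopulation exactly as the instrument does, and round-trip tests confirm
the estimator recovers the true $x$ from such data — a check that fails
conspicuously (control "fraction" 1/3) if the conditioning is ignored.

## What the simulator does and does not emulate

`simulate_labeling()` draws, per replicate, a multinomial sample of serine
molecules over the $2^3$ per-position label configurations: non-carboxyl
positions are ^12^C with probability $b = (1-\text{purity})(1-0.011)$ (the
unlabeled impurity of the substrate itself carries natural-abundance ^13^C),
the carboxyl position with probability $b + x_{true}\,d\,(c-b)$ in the
experiment arm and $b$ in the control. Defaults mirror the experimental
design: quadruplicate cultures, 99% ^13^C substrate, ambient-air CO~2~.
It does **not** emulate position-dependent backgrounds (e.g. serine
interconversion with glycine), natural-abundance corrections for O/N/H
isotopes, peak-integration noise, or between-replicate biological variance
beyond counting noise — so passing recovery tests show estimator
correctness under the stated model, not robustness to violations of it.
Estimator recovery is tested at $x_{true} \in \{0.05, 0.14, 0.3\}$,
multinomial depth $10^5$ and 4 replicates, requiring mean bias below 0.01.

# Growth statistics

`endpoint_summary()` is the classical $t$-interval on replicate endpoint
densities. `effect_at_time()` interpolates each replicate curve linearly at
the evaluation time and differences the arm means. `bootstrap_effect_ci()`
resamples **replicate curves** with replacement within each arm — the
biological replicate is the exchangeable unit; resampling time points or
residuals would require modeling the autocorrelation of a growth curve —
and reports the percentile interval (simplest method consistent with a
plain "bootstrapped CI"; BCa would need acceleration estimates that are
meaningless at 3–4 replicates). `n_boot = 10000` and the seed are echoed in
the result; identical inputs and seed give identical intervals.

A caveat worth stating: with 3 replicates per arm, a 99.9% percentile
interval is the full resample range, and the chance that the true effect
falls outside it is $2/\binom{6}{3} = 10\%$ — small-sample percentile
bootstrap under-covers at extreme levels no matter how many resamples are
drawn. The package's coverage experiment therefore uses quadruplicate arms
(miss probability $2/\binom{8}{4} \approx 2.9\%$), matching the
quadruplicate endpoint design, and requires empirical coverage over 200
regenerations within 5 points of nominal. The growth simulator itself
defaults to triplicate, matching the bioreactor time-course design it
emulates; its experiment arm adds the configured effect scaled by a logistic
ramp normalized to 1 at `t_eval`, so the zero-noise effect at the evaluation
time is exact by construction.

# Pipeline and reproducibility

`run_pipeline()` executes the stages from one (optionally YAML) config in
dependency order and returns a schema-versioned report whose echoed config
and seed reproduce it exactly; `write_run_report()` serializes it
atomically, omitting stages that did not run. One global seed is fanned out
to the stochastic stages by fixed offsets so any stage can be re-run in
isolation. A thin command-line wrapper over these functions ships in
`inst/cli/rubiflux.R`; the package functions are the primary interface.

Problem sizes used throughout the examples, tests and the acceptance script
— a 9-reaction toy model, $\le 6$-subset knockout scans, multinomial depth
$10^5$, 10000 bootstrap resamples, 200 coverage regenerations — were chosen
as the smallest sizes at which every quantity of interest is resolved well
inside its test tolerance.

# Known limitations

* The screen enumerates exhaustively; genome-scale models would need the
  pruning heuristics of dedicated bilevel methods, which are out of scope.
* The toy network omits energy cofactors by design; prk's ATP consumption
  must be present in any real model supplied by the user.
* The labeling estimator assumes a two-source mixture for 3PG and
  independent per-position labeling; pathways that scramble serine carbons
  would bias it.
* Percentile bootstrap intervals at extreme confidence levels are only as
  good as the replicate count allows (see above).
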