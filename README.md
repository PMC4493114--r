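# trendcp

Hierarchical Bayesian detection of shared change points in population
trends from breeding-bird-survey-style route counts.

## The problem

Large-scale bird surveys count birds each year along fixed roadside routes,
by volunteer observers, across spatial strata.  Two questions follow: what
is each species' abundance trajectory per stratum, and do *changes in
trend* happen at the same time across whole species groups — which would
point at broad common causes (climate, prey, land use) rather than
species-specific ones?

`trendcp` implements a two-stage pipeline:

1. **Annual-index model.**  Counts from observer-route pair *j*, stratum
   *i*, year *t* are overdispersed Poisson with
   `log λ = s_i + μ_t + γ_{i,t} + ω_{i,j} + ζ I(j,t) + ε_{i,j,t}`,
   where the spatial year effects `γ` carry a first-order intrinsic
   conditional autoregressive (CAR) prior across neighbouring strata within
   each year, `ω` are route-by-observer effects, and `ζ` is the first-year
   observer effect.  A Metropolis-within-Gibbs sampler produces annual
   abundance indices
   `η_{i,t} = π_i exp(s_i + β_i t + γ_{i,t} + μ_t + σ_ω²/2 + σ_ε²/2)`
   with log-scale uncertainties (`π_i` is the detection proportion; the
   half-variances correct retransformation bias).
2. **Change-point model.**  Log indices, centred on the mid-year, are data
   for piecewise-linear regression splines
   `f(t) = β₁ t + Σ_j β_{j+1} I(t ≥ θ_j)(t − θ_j)` with an unknown number
   of knots (change points), fitted by reversible-jump MCMC.  Five model
   structures — species-only (`M_s`), one shared group trajectory
   (`M_AllAI`), separate flycatcher/swallow-swift-nightjar group
   trajectories (`M_FC,SSN`), or one group only (`M_FC`, `M_SSN`) — are
   compared by DIC per stratum.  Change points are reported by their
   posterior-to-prior odds ratio (ratio > 3 = strong evidence), timing,
   direction (downturn/upturn), summed support, and the trends flanking
   them in %/yr.

A synthetic-data generator produces surveys with exactly the generative
structure both stages assume, so the whole pipeline is testable offline,
and an exact enumeration oracle validates the reversible-jump sampler on
small instances.

## Worked example

Five species sharing a group-level downturn (slope increment −0.06 at year
20 of 41, i.e. 1989, on a +0.02 base slope):

```r
library(trendcp)

cfg <- sim_config(grid_rows = 1, grid_cols = 1, n_years = 41,
                  species = data.frame(species = paste0("SP", 1:5),
                                       group = "SSN"),
                  group_traj = list(SSN = traj_spec(0.02, 20, -0.06)),
                  sigma_gamma = 0, seed = 2)
g    <- build_stratum_graph(1, 1)
traj <- simulate_trajectories(cfg, g)
idx  <- simulate_annual_indices(traj, cfg, strata = "S01_01",
                                sigma_eta = 0.05, seed = 4)
cen  <- prepare_inputs(idx, cfg$species)
fit  <- rjmcmc_sample(cen, cp_model_spec("M_AllAI", cfg$species, 41),
                      cp_config(n_iterations = 20000, burn_in = 4000,
                                seed = 9))
cp   <- changepoint_probability(fit)
summarize_changepoints(cp)[1, 1:6]
#>   trajectory direction modal_year run_start run_end summed_support
#> 1      AllAI  negative       1989      1989    1989              1

segment_trends(fit, "AllAI", 1989)
#> before  after
#>   1.34  -4.61
```

The group trajectory concentrates essentially all change-point mass on
1989 (posterior probability 1 of a knot there), the direction is negative
(a downturn), and the flanking slopes convert to about +1.3 %/yr before
and −4.6 %/yr after — recovering the simulated +2 %/yr-to−4 %/yr break
within posterior uncertainty.  For count-level data the same pipeline
starts from
`simulate_counts()` and `fit_index_model()`; `run_pipeline()` chains every
stage, and `compare_models()` produces the per-stratum DIC table and
support classification.

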