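---
title: "Detecting shared changes in population trends: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting shared changes in population trends: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trendcp)
```

## The problem

Breeding-bird-survey data are roadside route counts collected each year by
volunteer observers across spatial strata (province/state by Bird
Conservation Region intersections).  Two questions drive this package: what
is each species' abundance trajectory in each stratum, and do changes in
trend — *change points* — occur at the same time across whole species
groups (e.g. all aerial insectivores, or flycatchers versus
swallows/swifts/nightjars), which would point at broad-scale common causes
rather than species-specific ones?

The analysis is a two-stage hierarchical Bayesian pipeline.  Stage one
turns raw route counts into annual abundance indices with uncertainties.
Stage two treats those indices as data and locates change points in
piecewise-linear log-scale trend models, separating group-level from
species-specific changes.  Running the stages separately keeps each
tractable, and the stage-one indices are not smoothed over time by any
trend assumption, which is exactly what a change-point analysis needs.

## Stage one: the spatial CAR annual-index model

Counts from observer-route pair $j$ in stratum $i$ and year $t$ are
Poisson with

$$\log \lambda_{i,j,t} = s_i + \mu_t + \gamma_{i,t} + \omega_{i,j}
  + \zeta\, I(j,t) + \varepsilon_{i,j,t},$$

where $s_i$ is the log mean observed count in the stratum (a fixed data
offset, so year effects model annual variation rather than abundance
differences among strata), $\mu_t$ a year mean, $\gamma_{i,t}$ a spatial
year effect, $\omega_{i,j}$ a route-by-observer random effect,
$I(j,t)$ flags an observer's first year on a route (first-year observers
systematically count fewer birds), and $\varepsilon$ is log-normal
overdispersion.  The $\gamma_{\cdot,t}$ follow a first-order intrinsic
conditional autoregressive (CAR) prior within each year: each stratum's
effect is Normal around the mean of its neighbours with conditional
standard deviation $\sigma_t/\sqrt{N}$ for $N$ neighbours.  Strata sharing
a border are neighbours; a stratum isolated by data exclusions is
reconnected to included strata of its BCR, or failing that to the nearest
stratum by centroid distance.

Priors are the standard diffuse choices: inverse gamma (0.001, 0.001) on
all variances, Normal(0, $10^6$) on $\zeta$, and a flat prior on $\mu_t$
implemented as Normal(0, $10^6$) for propriety.  The intrinsic CAR is
improper, so the sampler re-centres $\gamma$ to sum to zero within every
year at every iteration and absorbs the subtracted mean into $\mu_t$ — the
standard sum-to-zero treatment.  Sampling is Metropolis-within-Gibbs:
conjugate inverse-gamma draws for the variances, vectorised adaptive
random-walk Metropolis for the Poisson-likelihood blocks, with adaptation
(targeting roughly 44% acceptance) frozen at the end of burn-in so the
retained chain is a valid time-homogeneous Markov chain.  Convergence is
monitored by split-$\hat R$ (flagged above 1.1) and effective sample
sizes.

Annual indices apply the detection scaling and the retransformation
correction:

$$\eta_{i,t} = \pi_i \exp\!\big(s_i + \beta_i t + \gamma_{i,t} + \mu_t
  + \tfrac12\sigma_\omega^2 + \tfrac12\sigma_\varepsilon^2\big),$$

with $\pi_i$ the proportion of routes in the stratum on which the species
was ever observed.  The half-variance terms make the index target the
arithmetic-scale mean (the mean of a log-normal is
$\exp(\sigma^2/2)$ times its median).  Two resolutions of ambiguities are
worth stating plainly.  First, the count model contains no stratum trend
term, so $\beta_i$ is unidentified and is fixed at zero; the symbol is
retained in the output container for fidelity to the index definition.
Second, $\sigma_\omega$ is pooled across strata, matching the single
distribution the count model places on $\omega$.  The index reported per
stratum and year is the posterior mean of $\eta$; its log-scale posterior
mean and variance are carried forward as data for stage two.

## Stage two: reversible-jump change-point splines

Annual indices are log-transformed and centred on their value in the
mid-year of the series (ordinal position $\lceil T/2 \rceil$), putting all
species on a common scale.  The centred log index $z_{i,t,s}$ is Normal
around a latent true log abundance $H_{i,t,s}$ with *known* variance
$\sigma^2_{\eta,i,t,s}$ taken from stage one, and $H$ is Normal around a
smooth trajectory with process variance $\sigma_p^2$ (year-to-year
population fluctuation).  We marginalise $H$ analytically — $z$ is then
Normal with variance $\sigma^2_\eta + \sigma_p^2$ — which leaves the
posterior unchanged and mixes better.

Each trajectory is a piecewise-linear regression spline with an unknown
number of knots,

$$f(t) = \beta_1 t + \sum_{j=1}^{k} \beta_{j+1}\, I(t \ge \theta_j)
  (t - \theta_j),$$

continuous everywhere, with slope jumps $\beta_{j+1}$ at change-point
years $\theta_j$.  Five model structures are compared per stratum: species
splines only ($M_s$); plus one group spline shared by all species
($M_{AllAI}$); plus separate flycatcher and swallow/swift/nightjar group
splines, each species receiving only its own group's spline
($M_{FC,SSN}$); or a group spline for one group only ($M_{FC}$,
$M_{SSN}$).  Knot counts have Binomial priors: Binomial(2, 0.5) for group
splines and for species splines accompanied by a group spline,
Binomial(4, 0.5) for species without one — at most four change points per
species either way, chosen to highlight the strongest changes in trend.
With expected count $k_{\max} p$ spread evenly over the candidate years,
the per-year prior probability of a group change point in a 41-year series
is $(2 \cdot 0.5)/41 = 0.024$.

### Design choices the equations leave open

* **Anchoring.**  The spline as written has no intercept, but the data are
  centred at the mid-year, so the raw spline cannot represent a centred
  series (it misses the constant $-f(t_{\text{mid}})$).  Every trajectory
  therefore enters the model mean *anchored*: $f(t) - f(t_{\text{mid}})$.
  Slopes and knots — the quantities of scientific interest — are
  untouched; only the arbitrary level is fixed to match the centring.
* **Candidate years.**  Knots live on the interior integer years
  $2..T-1$: change points are reported as years, and an endpoint knot
  would be unidentifiable because its basis vanishes on all observations.
  The sampler's per-year prior probability always uses the actual
  candidate-set size; the printed 0.024 uses the series length 41 as
  denominator and is reproduced by `prior_changepoint_probability()` as a
  pure function.
* **Slope priors.**  $\beta_1$ and all increments are Normal(0, 1) on the
  log scale (configurable).  A fully diffuse slope prior would make the
  across-dimension comparison degenerate (the Lindley–Bartlett
  phenomenon), so a weakly informative default is required; 1 is very wide
  relative to plausible log-scale slopes (|slope| < 0.2).
* **Process-variance prior.**  $\sigma_p^2$ has the same inverse gamma
  (0.001, 0.001) prior as the stage-one variances, and is shared across
  species within a stratum-model, matching the single $\sigma_p^2$
  appearing in every model structure.

### The sampler

The number, location, and increments of knots vary across iterations by
reversible-jump MCMC.  Per trajectory, each iteration proposes one of:
birth of a knot at a uniformly chosen unoccupied candidate year, death of
a uniformly chosen knot, or relocation to a uniformly chosen free year.
Two implementation points matter for mixing:

* **Conditional-posterior proposals.**  A birth increment drawn from its
  prior is almost surely rejected when the data are informative.  Instead
  increments are proposed from their full conditional (Gaussian)
  posterior, whose density enters the acceptance ratio; with equal birth
  and death probabilities the remaining ratio is
  $\exp(\Delta\ell)\, p(k')/p(k)$ times the prior-to-proposal density
  ratio of the increment.
* **Group swap moves.**  The group-plus-species decomposition is additive,
  so a change shared by every member species can sit either as one group
  knot or as a knot in each species — and moving between these states
  requires a coordinated trans-dimensional jump no sequence of
  single-trajectory moves will make at informative noise levels.  A
  dedicated swap move exchanges a knot held simultaneously by all member
  species for a single group knot at the same year (and the reverse),
  again with conditional-posterior proposals on both sides and the full
  prior, proposal, and eligibility-set terms in the acceptance ratio.

Given the knot configuration, all slope parameters across all trajectories
are jointly Gaussian and are refreshed by a conjugate Gibbs draw each
iteration; $\sigma_p$ takes an adaptive random-walk step on the log scale.
The sampler was validated against exact enumeration: on a single-species
instance (T = 12, up to 2 knots, fixed $\sigma_p$) the integrated-slope
marginal likelihood of every knot configuration is computable in closed
form, and the sampler's configuration frequencies agree with the exact
posterior within total variation 0.05; the multi-trajectory machinery with
swaps was additionally checked during development against a full
enumeration of a two-species-plus-group instance.  With the likelihood
switched off the sampler reproduces the per-year prior probability, a
standard prior-recovery check.

### Reporting

The posterior probability $p_1(t)$ of a change point in year $t$ is the
fraction of draws whose state holds a knot there (knots are distinct
years, so $\sum_t p_1(t)$ equals the posterior mean knot count exactly),
split by increment sign into negative (downturn) and positive (upturn)
parts.  Evidence is measured by the posterior-to-prior odds ratio
$[p_1/(1-p_1)]/[p_0/(1-p_0)]$, with ratio $> 3$ in a year counting as
strong evidence.  For each trajectory and direction separately (the
direction split mirrors how negative and positive change points are mapped
separately), maximal runs of consecutive strong-evidence years are
reported with: the modal year (highest probability; ties broken to the
earlier year), the run extent (adjacent strong years index timing
uncertainty), the summed probability over the run (overall support for
the change point), and posterior mean trends immediately before and after
the modal year on the percent-per-year scale,
$100(\mathrm{e}^{\text{slope}} - 1)$, computed from draws that contain the
modal-year knot (the flanking slopes exist only in those draws).  The
direction-specific probability is compared against the shared $p_0$; the
structure of the summed-support metric is per-direction, which we prefer
because opposite-signed change points in nearby years are distinct
events.

### Model comparison

Models are compared within each stratum by DIC, $\bar D + p_D$.  Because
the model dimension varies across draws, the classical plug-in at
posterior-mean parameters is undefined; the plug-in deviance is instead
evaluated at the posterior-mean fitted trajectory values and the
posterior-mean $\sigma_p$ — the fitted mean is the quantity every
dimension shares.  Negative $p_D$ (a known DIC pathology) is flagged, not
hidden.  A stratum enters the comparison only with at least two species of
each group, so both group trajectories are estimable.  The best model's
class is reported (`AllAI`, the `FC`/`SSN`/`FC,SSN` family, or `none` for
the species-only model), with the DIC margin over the best model of any
other class; a margin of at least 4 units is flagged as strong.

## The synthetic-data generator

The generator produces data with exactly the structure the two stages
assume: Poisson counts with log-normal overdispersion, route-by-observer
effects, a first-year observer effect, per-year spatially correlated
stratum effects, and piecewise-linear log-scale group and species
trajectories built by the same spline formula the model fits.  Strata form
a rectangular grid with rook adjacency ("share a border" without GIS
machinery), BCR labels by column blocks, and centroids at grid
coordinates.  The spatial field is drawn i.i.d. Normal$(0, \sigma_t)$ per
stratum and centred to zero within each year: the intrinsic CAR is
improper, so any proper centred field is valid ground truth for recovery
testing.  Observer tenure is geometric (mean 7 years by default), and
`first_year` flags an observer's first year *on that route*, the pairing
the count model uses.  A route lies outside the species' range with
configurable probability and then records structural zeros; such routes
can be kept or excluded, since survey zero-handling conventions differ and
neither choice is canonical.

Defaults describe a moderately common aerial insectivore: 41 years
labelled 1970–2010 (matching the 41-year prior denominator), mean count
10 per route, first-year effect $-0.15$, overdispersion SD 0.15,
route-observer SD 0.25, spatial year-effect SD 0.1.  A separate helper
simulates stage-two inputs (annual indices with known log-scale variance)
directly from the true trajectories, which is how the change-point stage
is tested without paying for a full stage-one fit.  Its observation noise
is anchored at the mid-year (no error there): the change-point stage
centres every series on its mid-year value, and without the anchor the
centring would inject a common `-eps(mid)` offset into all other years of
the series — a correlated-error structure the change-point model does not
assume, which flexible spline fits can absorb and rigid ones cannot,
silently biasing model comparisons.  With the anchor, the generator emits
exactly the independent-error observation model stage two assumes.  Note
that centred indices from a *real* stage-one fit do carry this offset;
that is a property of the centring convention itself and is worth keeping
in mind when DIC margins are small.

What the generator does *not* emulate: real surveys have missing
route-years, observer ability drifts, detection varies with habitat and
traffic noise, and abundance changes are not exactly piecewise linear.
Passing recovery tests therefore shows the inference machinery is correct
and well calibrated under the model's own assumptions — it does not show
the model is adequate for any particular real dataset.

## Validation conditions and problem sizes

The shipped tests run at sizes chosen to give clear statistical signal
quickly: the enumeration-oracle comparison uses T = 12 with up to 2 knots
and $2\times 10^5$ iterations; group change-point recovery uses 5 species
over 41 years with a shared downturn (slope increment $-0.06$ at year 20)
and index SD 0.05; the stage-one recovery run uses a $3\times 3$ grid,
25 years, and 10 routes per stratum.  Model-class recovery uses ten
replicate strata per scenario of four species (two per group) over 25
years: the shared-knot scenario gives both groups a $-0.08$ downturn at
year 13; the species-only scenario gives each species its own moderate
change point ($\pm 0.05$) at distinct years with flat group trajectories.
The five-model comparison needs enough iterations per fit (8000 here)
because an early-inflated $\sigma_p$ can flatten the likelihood and hide
true knots for many hundreds of iterations.

Two findings from this simulation study deserve emphasis.  First,
strongly-signalled species-specific change points whose realised group
average is non-zero create *genuine* group-level structure that the
group-bearing models correctly absorb — "species-specific" and
"group-level" are properties of the realised curves, not labels on the
generator.  Second, under species-only generation the five structures
approach DIC equivalence: a group trajectory that the data do not support
collapses to nearly zero at negligible deviance and complexity cost, so
the best-of-five choice behaves like a draw among near-ties and the
species-only structure wins only at roughly the chance rate, with margins
of a few units at most.  (Pairwise, the species-only model does beat the
single-shared-trajectory model systematically on such data; it is the
four-against-one class comparison that washes out.)  DIC model choice in
this family is therefore informative about the *presence* of shared
structure but weakly informative about its absence — absence claims
should lean on the strength margin, not the class label alone.

## Known limitations

* The stage-one sampler is plain R (vectorised); very large surveys (say
  hundreds of strata with decades of data) would want a compiled sampler
  or integrated-Laplace machinery.
* DIC on reversible-jump posteriors depends on the plug-in convention;
  ours focuses on fitted trajectories and is documented, but other
  conventions would shift DIC by a few units — margins under ~4 should
  not be over-read, which is also why the support classification carries
  an explicit strength flag.
* The pipeline estimates change points in trend, not their causes; the
  covariate extensions that would test causal hypotheses are out of scope.
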