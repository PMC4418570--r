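---
title: "zebrapop: model description and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{zebrapop: model description and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zebrapop)
```

zebrapop simulates a zebrafish (*Danio rerio*) population in a small,
well-vegetated monsoon-climate pond by nesting a dynamic energy budget
(DEB) model of each fish inside a spatial individual-based model (IBM)
coupled to a pond food web. This vignette describes the model, its
assumptions, the numerical choices, and what the synthetic-data generators
and tests do and do not demonstrate.

## The organism model

Each fish is described by a scaled reserve density $e$ (dimensionless), a
scaled length $l = L / L_\infty$, and, for females, an egg buffer $R$
(cumulative unspawned eggs). Energy assimilated from food enters the
reserve; a fixed fraction $\kappa$ of mobilised reserve maintains and grows
the soma, the remainder funds reproduction once the fish passes a fixed
scaled length at puberty $l_p$.

The state equations are

$$s_f(l) = \alpha\,\frac{l_f^3}{l^3 + l_f^3},$$

$$\frac{de}{dt} = \frac{\dot k_M\,g}{l}\left[(1 - s_f)\,f - e\right],
\qquad
\frac{dl}{dt} = r_B\,(e - l),\quad
r_B = \frac{\dot k_M\,g}{3\,(e + g)},$$

$$\frac{dR}{dt} = \frac{R_M}{1 - l_p^3}
\left[\frac{g + l}{g + e}\,e\,l^2 - l_p^3\right]^+ ,$$

with $f = 0$ before first feeding ($l < l_b$) and $dR/dt = 0$ before
puberty ($l < l_p$). Here $f \in [0,1]$ is the scaled functional response
(realised over maximal ingestion), and $s_f$ is a size-dependent ingestion
reduction: small larvae can only access a fraction of their potential food
intake, rising to full access as they grow. This mechanism, not metabolic
acceleration, produces the sigmoid length-at-age curve of zebrafish: at
$(e,l) = (1,1)$ the reproduction bracket collapses to $1 - l_p^3$, so the
equation returns exactly the maximum reproduction rate $R_M$.

Compound parameters follow the standard DEB definitions:
$E_m = \{\dot p_{Am}\}/\dot v$, $g = [E_G]/(\kappa E_m)$,
$\dot k_M = [\dot p_M]/[E_G]$, $L_m = \kappa\{\dot p_{Am}\}/[\dot p_M]$ and
$L_\infty = L_m/\delta$. With the default parameters
(`deb_params()`) this gives $L_\infty \approx 37.5$ mm — consistent with
the largest wild-type females.

Rates are corrected for temperature by the Arrhenius factor
$\exp(T_A/T_R - T_A/T)$ applied to $\{\dot p_{Am}\}$, $\dot v$ and
$[\dot p_M]$; the compound ratios $g$ and $E_m$ are therefore
temperature-invariant, while every rate (including $dR/dt$, which is a
rate with the same dimensions) carries the factor. A useful consequence,
exercised by the test suite, is that simulating at any temperature is
equivalent to rescaling time at the reference temperature.

Males differ from females only after puberty, when an appetite factor
$f_{lim} = 0.92$ multiplies their functional response, reproducing their
smaller adult size. Allometry converts standard length (mm) to wet mass
(mg) by $W = \exp(W_a \ln L + W_b)$ with $W_a = 3.205$, $W_b = -5.193$
(natural logarithms; this is the only convention that places a 30 mm fish
near 0.3 g).

### Integration

The organism model is advanced by forward Euler with ten sub-steps per day
(`step_deb()`, `simulate_deb()`), the model's native resolution; the scaled
length is floored at $10^{-6}$ and the reserve at 0. Shrinking
($dl/dt < 0$) is permitted and starvation is not lethal — adult zebrafish
survive weeks of food deprivation — so no starvation mortality is modelled.
The test suite compares the fixed-step trajectories against an adaptive
high-accuracy solver (deSolve) over 400 days and against the closed-form
von Bertalanffy limit ($s_f \equiv 0$, $e = 1$); agreement is better than
0.1 mm in physical length at the native step, with empirical convergence of
first order as the step shrinks.

## The population model

The pond is a 30 × 30 grid of 20 × 20 cm patches (36 m², 0.5 m deep):
207 vegetation-cover patches, 207 breeding-ground patches, the rest open
water, assigned uniformly at random at initialisation. The founding
population is 300 juveniles, 35 males and 35 females placed uniformly at
random; founders draw scaled lengths uniformly between first feeding and
puberty (juveniles) or above puberty (adults), start at reserve density
0.9, and ages are drawn from ranges consistent with their stages (30–100
and 200–500 days). Each fish carries a lognormal energy-acquisition
multiplier (median 1, log-sd $\sigma = 0.235$) expressing persistent
inter-individual differences in competitive ability.

Each simulated day executes, in order:

1. **Environment**: temperature and photoperiod are interpolated from the
   forcing series; the food web advances one day using yesterday's fish
   consumption; the population functional response
   $f = F/(F + s\,B)$ is computed from total food energy $F$ and fish
   biomass $B$ (in kcal) — the paralleling feeding assumption: one shared
   $f$, food divided in proportion to need.
2. **Movement** (uniformly random order): juveniles seek a vegetation
   patch in their Moore neighbourhood and stay once on vegetation;
   territory-less males claim a free breeding patch in their neighbourhood
   (one owner per patch, first claimant in random order wins) or move
   randomly; females whose egg buffer is full move to a neighbouring patch
   holding a territorial male when reproduction is environmentally
   permitted; everyone else steps to a random Moore neighbour. Movement
   is restricted to the Moore neighbourhood as the minimal assumption
   consistent with territory-scale behaviour.
3. **Survival**: each fish dies with daily probability
   $\pi_a \pi_c W^{\pi_b}$ (a Lorenzen-type allometric size term, $W$ in
   mg), plus $\pi_d D$ for juveniles ($D$ = total fish biomass density in
   g m⁻³ — the density-dependent recruitment bottleneck), plus linear
   senescence $\pi_e(\mathrm{age} - \pi_g)$ beyond 550 days; the sum is
   clamped to $[0,1]$. Juveniles receive no vegetation survival bonus:
   with no carrying capacity on vegetated patches all juveniles
   concentrate there, so location adds no information.
4. **Growth**: survivors advance their energy budget by one day (ten
   sub-steps) at their individual effective response
   $\min(1, \mathrm{scatter} \times f \times f_{lim}^{[\text{adult male}]})$;
   the day's assimilated energy, converted to kcal, is the consumption
   removed from the food pools tomorrow.
5. **Reproduction**: egg broods lose eggs to predation
   (binomial, $\pi_p = 0.025\,d^{-1}$), accumulate degree-days above
   10.3 °C and hatch at 60.9 degree-days into juveniles at $l = l_b$ with
   hatching success $H_{max} H_{0.5}/(H_{0.5} + D_f)$ declining with
   female biomass density; juveniles reaching $l_p$ become male or female
   according to a latent sex fixed at hatching from the brood's male
   fraction $\mathrm{clamp}_0^1(G/100 + SR_a (T - SR_b))$,
   $G \sim N(50, 23.1)$ truncated to $[0,100]$ — temperature acts during
   incubation, warm broods skewing female-poor male fractions downward.
   Inside the reproduction window (photoperiod ≥ 12 h **and** temperature
   ≥ 22.5 °C) each territorial male may receive one ready female
   ($R \geq R_\tau = 263$) co-located on his territory per day; she spawns
   a fixed clutch of exactly $R_\tau$ eggs (the observed mean clutch the
   threshold was set from), keeping the remainder of her buffer.
6. **Book-keeping**: a census identity (today's count = yesterday's +
   hatched − died) is asserted every day, and a daily summary row is
   recorded.

All randomness flows from one seed; identical seeds give bitwise-identical
runs. The per-fish survival/growth pipeline and the juvenile relocation
are implemented in compiled code for speed, drawing from R's RNG stream so
reproducibility is preserved.

## The pond food web

Two energy pools — autotrophic food $A$ and heterotrophic food $H$ (kcal
per pond) — are coupled to dissolved and sediment nitrogen and phosphorus,
following the classic pond-aquaculture structure. Phytoplankton grows at
$\lambda_{max} \min(\text{light}, \text{nutrient}) \times
\text{temperature} \times A$, where light is solar input (proportional to
photoperiod, saturating at the reference radiation) attenuated by
self-shading $\exp(-(Ir_a A + Ir_b H))$, nutrient limitation is the Liebig
minimum of two Monod terms, and the temperature response is a Gaussian
around 30 °C. Losses are respiration, transfer into the heterotrophic
pool, and fish consumption; the heterotrophic pool sediments and
decomposes. The N budget closes over fixation, phytoplankton uptake,
sediment release, decomposition return, fish excretion and atmospheric
loss; the P budget is analogous with area-scaled sediment exchange
velocities. Every rate constant drives exactly one flux, and
`step_food_day()` returns the full flux ledger so the tests can verify the
budget to machine precision.

Two numerical safeguards matter. First, one day's phytoplankton uptake is
hard-capped at the nutrients available in the water column (a strict
Liebig quota), preventing the explicit day-step from overshooting the
dissolved pools and silently creating mass. Second, all pools are floored
at zero, with a warning if flooring ever exceeds numerical tolerance.

The closed-system check used by the tests disables the monsoon inputs
*and* atmospheric N fixation — both are external sources — and verifies
that total N and P inventories never increase. With the monsoon active,
each day in the June–September window (days-of-year 152–273) delivers
`F_inputs` of the reference stocks (1000 g N, 100 g P, a ~10:1 N:P mass
ratio typical of terrestrial runoff) to the water column, the external
subsidy that sustains the annual production cycle.

Initial pool sizes (A = 20000, H = 10000 kcal; 0.5 mg N L⁻¹,
0.05 mg P L⁻¹ dissolved; 2000 g N, 5000 g P in sediment) describe a
moderately eutrophic tropical pond. The pools relax within weeks to an
internally determined equilibrium set by the light/shading balance, so
these choices fix the starting transient, not the long-run behaviour.

## Environmental forcing

`generate_monsoon_scenario()` produces a deterministic Kolkata-like
climate: water temperature
$25 + 6\cos(2\pi(\mathrm{doy} - 140)/365)$ °C (19–31 °C, peaking in late
May) and the astronomical day length for 22.57° N from the standard solar
declination formula. Scenario files (day, temperature, photoperiod;
whitespace-separated, `#` comments) can replace the generator; series
spanning at most one year are extended periodically. The reproduction
window and the monsoon input window emerge from this forcing: photoperiod
crosses 12 h around the equinoxes, so day length — not temperature — is
the binding constraint on the breeding season, and the model's juvenile
pulse follows it.

## Sensitivity analysis

Two standard global methods are provided with a *dummy parameter* appended
to every design as a negative control: a coordinate that no model output
depends on, whose indices therefore estimate the analysis' noise floor.

- **Morris elementary effects** (`morris_design()`, `morris_effects()`):
  randomised one-at-a-time trajectories on an even-level grid with the
  standard step $\Delta = p/(2(p-1))$; per parameter the mean $\mu$, mean
  absolute $\mu^*$ and standard deviation $\sigma$ of the elementary
  effects, plus a composite global index $\sqrt{\mu^{*2} + \sigma^2}$ used
  only for ranking (a standard composite; large $\sigma$ flags
  non-linearity or interaction).
- **Sobol variance decomposition** (`sobol_design()`, `sobol_indices()`):
  Saltelli paired matrices with Jansen estimators for first-order and
  total indices. Under this estimator the dummy's total index is exactly
  zero, a sharp control. Small designs (N < 100) trigger bootstrap
  confidence intervals and a warning.

Screening ranges default to ±20 % around the nominal values
(`deb_sensitivity_ranges()`), including the experimental and reference
temperatures and the functional response; `deb_batch_output()` pushes
whole designs through the organism model in one vectorised pass,
evaluating length at 25–400 dpf or cumulative eggs. Because the reference
temperature enters the Arrhenius exponent, a ±20 % range on it dominates
every output — the expected and observed leading rank — followed by the
assimilation/maintenance/allocation set that fixes $L_\infty$.

## Calibration

**Energy-budget layer (Bayesian MCMC).** The likelihood treats observed
mean lengths (standard error $sd/\sqrt{n}$ from the data) and cumulative
egg counts (fixed sd, default 30 eggs) as independent Gaussians around the
simulated trajectories; each observation group carries its own latent
functional response $f$, fitted jointly — feeding conditions differ
between experiments and carry no prior information, so the $f$ coordinates
get a nearly flat logit-normal(0, 1.75) prior on (0, 1). The fitted set is
$\delta, \{\dot p_{Am}\}, \dot v, \kappa, \alpha, l_b, l_f, [\dot p_M],
[E_G], E_0, R_M, f_{lim}$ plus the per-group $f$; $l_p$ and $L_0$ stay
fixed. Structural parameters get weakly informative priors on the internal
scale (log for positive quantities, logit for fractions): normal with
sd 0.2 (≈ ±20 %) and 0.5 respectively, centred at the defaults.

The sampler is built for the geometry this likelihood has: strong curved
compensation ridges (e.g. raising assimilation while lowering $f$) and,
with nearly flat $f$ priors, genuinely separated posterior regions that a
plain random-walk chain cannot bridge. The pipeline is: per-group $f$
coordinates initialised by a coordinate-wise grid search; posterior mode
located by multi-start Nelder–Mead; the local inverse Hessian seeds a
single adaptive pilot Metropolis chain (Haario covariance re-estimation,
scale tuned towards 23 % acceptance) whose thinned trajectory becomes the
shared proposal history; then each reporting chain is an independent
differential-evolution Metropolis population of four members, proposing
scaled differences of sampled history states with occasional unit-factor
jumps — the move that lets chains hop between posterior regions. The
first half of every chain is discarded as burn-in, convergence is judged
by the classic Gelman–Rubin potential scale reduction with the criterion
R-hat < 1.2 for every parameter, and central credible intervals pool
chains on the natural scale.

**Population layer (genetic algorithm).** Three parameters lack any prior
information — the mortality scale $\pi_a$, the density-dependent constant
$\pi_d$ and the monsoon input fraction `F_inputs` — and are fitted by a
generational genetic algorithm (population 50, tournament selection of 3,
crossover 0.7, per-gene mutation 0.01, elitism) minimising the sum of
squared differences between simulated and observed censored length
histograms (1-mm bins, fish > 18.4 mm, simulation day 1110). Because one
objective evaluation is a full multi-year pond simulation, the optimiser
takes a pluggable simulator function: the default runs the real model
(`default_ibm_simulator()`), while the test suite verifies the GA
machinery — self-recovery, elitist monotonicity, degenerate populations,
failure handling — on an analytic surrogate histogram and separately
smoke-tests the real simulator path at short horizon. Extinct simulations
score an infinite distance.

## Synthetic data

The generators in `synthetic_spec()` / `make_growth_data()` /
`make_fecundity_data()` / `make_field_histogram()` emulate the three data
streams a calibration needs, without reproducing any real measurements:

- juvenile growth: three feeding regimes ($f$ = 0.93, 0.81, 0.70) at
  27 °C, 15 fish per group, measured at 49–107 dpf on an 8-day schedule,
  with 0.5 mm Gaussian measurement noise per individual (the order of
  instrument precision plus biological scatter);
- fecundity: daily cumulative egg counts of mature females over 21 days
  at 29 °C ($f$ = 0.93) and 11 days at 26 °C ($f$ = 0.48), noise sd 20
  eggs, kept non-decreasing as a cumulative count must be;
- field-style histograms: a full pond run sampled for 120 fish above a
  length cutoff (field gear misses small fish), binned at 1 mm.

All generators are seed-deterministic and their tables round-trip the
calibration readers. Because the synthetic data are generated by the same
model that is fitted, passing calibration tests demonstrates correctness
of the machinery (self-consistency, convergence, interval calibration) —
not that the model describes real zebrafish ponds, and not that real data
would be this well-behaved: real observations carry model misspecification
the fixtures cannot emulate.

## Problem sizes used by the checks

The automated checks run at desk scale, chosen to exercise the full
machinery: 30 replicate 4-year pond simulations for the seasonal cycle of
the censored fraction; three chains of 6000 iterations for the reference
calibration; twenty 2-chain refits (3000 iterations, re-run at 8000 when
the convergence diagnostic fails — an unconverged sampler does not yield a
credible interval) for interval calibration; Sobol designs of N = 1024 on
the organism layer and N = 8192 for the Ishigami oracle.

## Known limitations

- The pond food web is a structural reconstruction: its parameter values
  and flux forms are principled, but absolute pool magnitudes (and hence
  the equilibrium functional response, near 0.65–0.75 under the defaults)
  are not anchored to measurements. Population-level quantities that
  depend on absolute food availability — notably how severely winter
  growth stalls, and thus how many fish remain below field sampling
  cutoffs off-season — inherit this uncertainty. In the default pond the
  breeding-season recruitment pulse is massive and the off-season small-
  fish fraction can fall to zero, because food is plentiful enough that
  survivors grow through the cutoff within months.
- Survival is the least constrained process: the Lorenzen-type
  composition reproduces the intended roles of the constants, not a
  measured mortality schedule.
- No cannibalism, predators, migration, dominance hierarchies, oxygen or
  water-level dynamics; energy allocation does not change between
  breeding and non-breeding seasons.
- The incubation clock is purely thermal (degree-days); egg energetics
  are not tracked, and hatchlings start fully provisioned ($e = 1$).
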