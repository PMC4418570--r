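# zebrapop

Energy-budget driven population dynamics of zebrafish (*Danio rerio*) in a
monsoon-climate pond.

Ecological risk assessment needs population-level predictions, but almost
all zebrafish toxicity data describe individuals under laboratory
conditions. zebrapop bridges that gap for modellers and ecotoxicologists:
it nests a dynamic energy budget (DEB) model of individual growth and
reproduction inside a spatial individual-based model (IBM) of a 36 m²
vegetated pond, forced by a Kolkata-like tropical climate (temperature and
photoperiod) and fed by a two-pool pond food web with nitrogen and
phosphorus cycling. Effects measured on individuals (growth, fecundity,
survival) can then be propagated to abundance, stage structure and length
distributions.

## The model in brief

Each fish carries a scaled reserve density *e*, a scaled length
*l* = *L*/*L*∞ and an egg buffer *R*:

    s_f(l)  = α · l_f³ / (l³ + l_f³)                      (size-dependent ingestion reduction)
    de/dt   = (k_M g / l) · [(1 − s_f) f − e]             (reserve dynamics)
    dl/dt   = r_B (e − l),  r_B = k_M g / (3 (e + g))     (von Bertalanffy growth)
    dR/dt   = R_M/(1 − l_p³) · [(g+l)/(g+e) · e l² − l_p³]⁺  (reproduction, 0 below l_p)

with the functional response *f* shared by the whole pond each day
(*f* = *F*/(*F* + *s·B*), food over scaled fish biomass), an Arrhenius
temperature correction exp(T_A/T_R − T_A/T) on all rates, and a male
appetite factor *f*<sub>lim</sub> after puberty. The ingestion reduction
*s_f* — small larvae cannot access their full ration — produces the
species' sigmoid growth curve without invoking metabolic acceleration.

The IBM adds space (vegetation, breeding grounds, open water), movement,
territorial males, photoperiod- and temperature-gated spawning with fixed
clutches of 263 eggs, degree-day egg incubation with density-dependent
hatching, temperature-influenced sex determination, and Lorenzen-type
size-dependent mortality with a juvenile density term and senescence.

The analysis layer provides Morris elementary-effects screening and Sobol
variance decomposition (with a dummy-parameter control), adaptive
Metropolis MCMC calibration of the energy-budget parameters with
Gelman-Rubin diagnostics, a genetic-algorithm search for the three
population-level parameters against censored length histograms, and
seed-deterministic synthetic data generators for every calibration path.

## Worked example

```r
library(zebrapop)

p <- deb_params()                 # zebrafish defaults
compound_params(p)$L_inf
#> [1] 37.54545

# an individual at near-ad-libitum feeding (f = 0.93) at 27 degC
sim <- simulate_deb(times = c(49, 107, 400), f = 0.93, T_c = 27)
round(data.frame(dpf = sim$times, length_mm = sim$L[, 1]), 1)
#>   dpf length_mm
#> 1  49      23.6
#> 2 107      32.1
#> 3 400      34.8

# two years of the coupled pond model
out <- run_ibm(days = 730, seed = 1)
out[c(365, 540, 730), c("day", "n_fish", "n_juvenile", "f",
                        "mean_length", "frac_le15")]
#>     day n_fish n_juvenile     f mean_length frac_le15
#> 365 365    422          0 0.744       32.97      0.00
#> 540 540  93251      92830 0.699        4.99      0.99
#> 730 730    387          0 0.748       33.84      0.00
```

A 23.6 mm juvenile at 49 dpf and ~35 mm adults match well-fed laboratory
zebrafish. The pond shows the model's strong annual cycle: day 540 falls
in the breeding season (a recruitment pulse of tens of thousands of ~5 mm
larvae, 99 % of fish at or below the 15 mm field-sampling cutoff), while
days 365 and 730 fall in the non-breeding season, when the population has
collapsed back to a few hundred adults. `length_histogram()` converts any
population to the censored 1-mm length distributions used for comparison
with field samples, and `run_simulation()` / `inst/cli/zebrapop.R` wrap
replicate runs, CSV output and YAML configuration.

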