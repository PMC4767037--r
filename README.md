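# gutsim

Mechanistic simulation of gastric emptying, luminal mass transfer and
starch digestion in the human gut.

## The problem

How fast a meal's glucose reaches the blood is set by a competition between
three rates: how fast the stomach delivers chyme to the duodenum, how fast
dissolved glucose crosses the luminal boundary layer to the intestinal
wall, and (for starch) how fast amylase produces glucose in the first
place. Food formulation mostly moves one dial — chyme viscosity — and
`gutsim` exists to quantify when that dial matters: it is aimed at food
scientists and digestion modellers who want a transparent,
mass-conserving, fully verified implementation of the classic
reactor-network picture of the upper gut rather than a black-box
physiological simulator.

## The model

The stomach is a well-mixed reservoir emptying exponentially
(γ = ln 2 / t<sub>1/2</sub>); the small intestine is a plug-flow tube in
which concentration G(z, t) obeys

    ∂G/∂t = −ū ∂G/∂z − (2f/r_m) K G   (+ γ G_s δ(z − l0) when stomach-fed)

with absorption through a viscosity-dependent mass-transfer coefficient
from the laminar Sherwood correlation and Stokes–Einstein diffusivity:

    Sh = 1.62 (Re Sc d/L)^(1/3)  ⇒  K = 1.62 (ū D² / (L d))^(1/3),
    D = k_B T / (6π μ r₀)        ⇒  K ∝ μ^(−2/3).

Model 3 adds a starch balance with Michaelis–Menten hydrolysis
V<sub>max</sub> S/(K<sub>m</sub> + S) feeding the glucose equation.
Scaling by the residence time L/ū gives the characteristic times
τ_transfer = (2fK/r_m)(L/ū), τ_emptying = γL/ū and τ_R =
(L/ū)V<sub>max</sub>/G<sub>s0</sub> that organise the regime maps. The
PDEs are solved by method of lines (first-order upwind, `deSolve::lsoda`)
with absorbed/exited mass carried as states, so every run closes its mass
balance to integrator tolerance; independent closed-form, quadrature and
method-of-characteristics oracles verify each model. See the methods
vignette (`vignettes/gut-absorption-model.Rmd`) for assumptions, closures
and numerical choices.

## Worked example

A 50 g glucose drink (watery, 1 mPa s) emptying with a 30 min half-time:

```r
library(gutsim)
em  <- gut_emptying(half_time = "30 min")
sim <- simulate_model2(mass = 50, emptying = em)
sim
#> Gut simulation (Model 2)
#>   horizon: 10800 s   grid: 285 cells   input: 50 g
#>   fraction absorbed at horizon: 0.7472
#>   max mass-balance residual: 1.42e-15

characteristic_times(gut_geometry(), gut_fluid(0.001), gut_solute(), em)
#> Transport chain:
#>   D   = 5.975e-10 m2/s   K = 1.36e-07 m/s   k_a = 2fK/r_m = 0.0001813 1/s
#>   Re  = 6.12   Sc = 1674   Sh = 8.193
#> Characteristic times (residence time 16765 s):
#>   tau_transfer = 3.04   tau_emptying = 6.456
```

Reading: glucose diffuses at 6.0e-10 m²/s, crosses the boundary layer at
K = 1.4e-7 m/s, and 74.7 % of the dose is absorbed within the 3 h
glycaemic-index window. τ_emptying > τ_transfer > 1 places this meal in
the regime where neither emptying nor transfer is strongly limiting —
thicken the drink to 0.2 Pa s and `simulate_model1` shows absorption
collapsing below 6 % as τ_transfer falls to 0.09. Sweep drivers
(`viscosity_sweep()`, `emptying_sweep()`, `regime_map()`,
`reaction_regime_map()`) regenerate the full result surfaces, and
`literature_meals()` provides published liquid-meal half-times for
overlays.

A thin command-line wrapper is installed with the package:

```sh
Rscript inst/cli/gutsim.R props --viscosity 0.001 --format json
Rscript inst/cli/gutsim.R simulate --config run.yaml --out-dir out/
Rscript inst/cli/gutsim.R verify --config run.yaml
```

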