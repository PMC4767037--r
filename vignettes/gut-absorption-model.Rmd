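---
title: "A compartmental reactor model of glucose absorption in the gut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compartmental reactor model of glucose absorption in the gut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutsim)
```

## The model

`gutsim` treats the upper gastrointestinal tract as two ideal reactors: the
stomach is a perfectly mixed reservoir (CSTR) that only meters delivery, and
the small intestine is a plug-flow tube (PFR) in which dissolved nutrients
advect at a constant mean velocity $\bar{u}$ while being absorbed through
the wall and, for starch, hydrolysed to glucose. Three nested variants are
provided:

* **Model 1** — a glucose bolus placed directly in the proximal intestine:
  $$\partial_t G = -\bar{u}\,\partial_z G - \frac{2f}{r_m} K\, G$$
  with $G(z,0) = G_0$ on $[0, l_0]$ and zero elsewhere. $2/r_m$ is the
  surface-to-volume ratio of a cylinder, $f$ the mucosal amplification
  factor, $K$ the luminal mass-transfer coefficient.
* **Model 2** — the same tube fed by exponential gastric emptying
  $\dot G_s = -\gamma G_s$, the flux $\gamma G_s$ entering at $z = l_0$.
* **Model 3** — starch empties instead, is hydrolysed by
  Michaelis–Menten kinetics $V_{max} S/(K_m + S)$ (amylase in excess,
  substrate bioaccessibility limiting), and the glucose produced is
  absorbed as in Model 2.

The transport closure is the only place food properties enter: the laminar
tube correlation $\mathrm{Sh} = 1.62\,(\mathrm{Re}\,\mathrm{Sc}\,d/L)^{1/3}$
gives $K = 1.62\,(\bar{u} D^2 / (L d))^{1/3}$ with the Stokes–Einstein
diffusivity $D = k_B T / (6\pi\mu r_0)$, so $K \propto \mu^{-2/3}$: chyme
viscosity controls absorption. Epithelial and blood-side resistances are
assumed fast and are not modelled; bulk flow is laminar with constant
$\bar{u}$ and constant viscosity (no secretions, no motility-driven mixing,
no nutrient feedback on emptying). Those idealisations mean the simulator
speaks to *relative* control — which of emptying, transfer and hydrolysis
limits absorption — rather than to absolute postprandial curves.

Scaling time by the residence time $L/\bar{u}$ yields the characteristic
times that organise all results:
$\tau_{transfer} = (2fK/r_m)(L/\bar{u})$,
$\tau_{emptying} = \gamma L/\bar{u}$,
$\tau_R = (L/\bar{u})\,V_{max}/G_{s0}$, and the scaled Michaelis constant
$K_m'' = K_m/G_{s0}$.

## Parameters, units and defaults

| parameter | default | meaning |
|---|---|---|
| $L$, $r_m$ | 2.85 m, 1.8 cm | intestinal length and radius |
| $d$ | $2 r_m$ = 3.6 cm | diameter in the Sherwood correlation |
| $f$ | 12 | mucosal surface amplification |
| $\bar{u}$ | 1.7e-4 m/s | mean axial velocity (residence ≈ 4.7 h) |
| $\mu$ | 1e-3 Pa s | chyme viscosity (sweep range 1e-3–10) |
| $r_0$ | 0.38 nm | glucose hydrodynamic radius |
| $T$ | 310 K | body temperature |
| $t_{1/2}$ | — | emptying half-time, $\gamma = \ln 2 / t_{1/2}$ |
| $V_{max}$, $K_m$ | (1–25) mM/min, 9 mM | hydrolysis kinetics |
| meal | 50 g in 0.5 L | input mass and volume |
| horizon | 10 800 s | 3 h, the glycaemic-index window |

Interfaces accept the literature's units (mPa s, mM, mM/min, min/h) and
convert to SI on ingest; all internal computation is SI. $V_{max}$ is read
as a concentration rate (mM/min) so that the sink in the starch balance
shares units with $S$ — published values quoted as "mmol/min" are ingested
on that basis.

Two conventions deserve comment because the literature leaves them open:

* **Correlation diameter.** Taking the stated radius literally gives
  $d = 2 r_m$ = 3.6 cm and Re ≈ 6 for water; some published numbers for
  this geometry (Re ≈ 3, $\tau_{transfer}$ ≈ 3.4) are instead consistent
  with $d$ = 1.8 cm. Both are honest readings; `gut_geometry()` defaults to
  $d = 2 r_m$ (giving $\tau_{transfer}$ ≈ 3.04 at 1 mPa s) and exposes
  `diameter_d` so the alternative is one argument away, never a silent
  re-tune.
* **Reference concentration $G_{s0}$.** $\tau_R$ and $K_m''$ need the
  "initial input" as a concentration. The package uses the meal's molar
  concentration, $M_0/(M_w V_{meal})$ with $V_{meal}$ = 0.5 L by default
  (typical of the liquid test meals the model targets): 50 g glucose
  equivalents in 0.5 L is 556 mM, so $K_m''$ ≈ 0.016. This is the only
  choice that makes $K_m''$ dimensionless against a $K_m$ quoted in mM.

## Numerics

Space is discretised by a uniform finite-volume grid (default 285 cells,
$\Delta z$ = 1 cm) with first-order upwind (backward) differencing for the
advection term — the scheme's numerical diffusion is accepted as part of
the reference behaviour, and the resolution is configurable with a
convergence check in the test suite (halving $\Delta z$ moves the 3 h
absorbed fraction by well under 0.5 %). The method-of-lines system is
integrated by `deSolve::lsoda` (adaptive, stiff-capable) at `rtol` 1e-8 /
`atol` 1e-12, sampling output every 60 s. Absorbed and exited mass are
carried as auxiliary ODE states, so the discrete balance
stomach + lumen + absorbed + exited = input holds to integrator tolerance;
`mass_balance_report()` audits it at every output time (observed residuals
are at round-off, bounds of 1e-6 for the linear models and 1e-5 for
Model 3 are asserted).

The gastric flux enters the single cell containing $l_0$, divided by that
cell's volume — a discrete delta that conserves mass for any $\Delta z$.
The bolus default $l_0$ is the radius of a sphere holding the meal volume
(4.9 cm for 0.5 L); Models 1–2 are provably invariant to it and to the
input mass (linearity), Model 3 is not. Boundary conditions are zero
advective inflow at $z=0$ and free outflow at $z=L$, with outflowing mass
booked to `exited` — the only reading of zero-gradient ends consistent
with pure upwind advection that still closes the mass balance. Small
negative concentrations from integrator undershoot are counted and clipped
inside the kinetics only (never in the mass accounting); undershoot beyond
a scaled threshold aborts the run. Nothing in the package is stochastic; a
`seed` config key is accepted and recorded for interface uniformity but
unused.

## Verification oracles

Each solver is checked against an independent, grid-free solution sharing
no discretisation code:

* Model 1: exact piecewise closed form along characteristics
  ($1 - e^{-k_a t}$ before any exit, a slug-front integral afterwards);
* Model 2: entry-time superposition — double-exponential closed form while
  no parcel has exited, adaptive quadrature afterwards;
* Model 3: per-parcel ODEs along characteristics, each parcel entering at
  the flux-balance concentration $\gamma S_s/(A\bar{u})$, integrated with a
  hand-written vectorised RK4 (deliberately not `deSolve`).

Agreement at the default grid is ~1e-7 absolute for Models 1–2 and ~1.3 %
for Model 3 (the nonlinear kinetics feel the upwind smearing of the slug).
The same comparison is exposed as the `verify` CLI subcommand.

## The dimensionless solver and the Model 3 closure

`simulate_dimensionless()` integrates the scaled equations on
$\xi \in [0,1]$; a dimensional run mapped through its characteristic times
reproduces the dimensionless run to round-off when resolutions match, and
within 0.5 % across resolutions (the non-dimensionalisation is exact, so
any gap is discretisation). For Model 3 one extra closure is unavoidable:
the scaled equations relate a luminal *concentration* to the stomach's
*mass fraction*, and the link is a meal-to-gut volume ratio
(default 0.5 L / 2.9 L ≈ 0.17). It enters only through an effective
Michaelis constant $K_m''/\!$`volume_ratio`, and the linear models are
invariant to it.

This closure exposes a genuine limitation of the fixed-velocity,
point-injection formulation. Under rapid emptying
($\tau_{emptying} \gg 1/$`volume_ratio`) the injected chyme is compressed
into a slug whose concentration exceeds the meal concentration — physically
the meal would occupy its own volume and distend the gut, which a constant
$\bar{u}$ cannot represent. The Michaelis–Menten term then saturates, and
hydrolysis of the whole slug takes (entry conc$/G_{s0})/\tau_R$ residence
times rather than $1/\tau_R$. Consequence: the $\tau_R = 25$ reaction map
slice approaches the glucose-only regime map closely where transfer is
fast, but lags it by about five percentage points near the
rapid-emptying / slow-transfer corner (the map comparison in the test
suite computes this). The effect strengthens under grid refinement
(sharper slugs) and is insensitive to the volume-ratio convention, so it
is a property of the model equations, not of the discretisation or of the
closure constant. Interpreting that corner of the Model 3 maps calls for
the per-parcel oracle, whose entry concentration is stated explicitly.

## Regime analysis

`regime_map()` evaluates the absorbed fraction after one residence time
($\tau = 1$, matching how the dimensionless sweeps are reported) on a
log–log grid of $\tau_{emptying} \in [0.5, 100]$ and
$\tau_{transfer} \in [0.1, 100]$; dimensional scenario runs instead use the
3 h horizon. Both horizons are explicit arguments because the two
conventions answer different questions. The surface is monotone along both
axes, its transfer-saturated edge equals the emptied fraction
$1 - e^{-\tau_{emptying}}$, and the packaged `literature_meals()` table can
be mapped onto the $\tau_{emptying}$ axis for overlays. The qualitative
four-region reading of such maps (emptying-limited, doubly limited,
transfer-limited, saturated) is left to the analyst: the package emits the
raw surface rather than hard-coding thresholds that were only ever prose.

Default problem sizes — 285 cells for dimensional runs, 100–200 cells for
dimensionless runs, 5×5 to 9×9 map grids, 500 parcels for the
characteristics oracle — were chosen as the coarsest resolutions whose
refinement changes results by less than the tolerances quoted above; the
test suite re-checks the convergence claims rather than trusting them.

## What the defaults do and do not emulate

The default parameter set represents a fasted adult drinking a 0.5 L
liquid glucose or starch meal: no lag phase in emptying, no solid-phase
sieving, single nutrient, constant viscosity. Passing tests therefore
demonstrate internal correctness (conservation, oracle agreement,
convergence, scaling laws) and fidelity to that idealised meal — not
predictive accuracy for real mixed meals, where secretions dilute the
chyme, viscosity evolves, motility augments transfer, and duodenal
nutrient sensing feeds back on $\gamma$. Those mechanisms are outside the
model by design.

## A worked run

```{r example, eval = FALSE}
em <- gut_emptying(half_time = "30 min")
sim <- simulate_model2(mass = 50, emptying = em)
summary(sim)
plot(sim)

# where does this meal sit in regime space?
characteristic_times(gut_geometry(), gut_fluid(0.001), gut_solute(), em)
```
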