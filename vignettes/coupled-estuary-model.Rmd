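---
title: "The coupled estuary model: hydrodynamics, chromium transport, and mangrove uptake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The coupled estuary model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mangroveCr)
```

# The problem

Industrial zones along tidal estuaries discharge chromium-laden wastewater
directly into the river, while the opposite bank often carries mangrove
forest that can immobilize part of that load in its soil and tissue.
`mangroveCr` simulates this system at desk scale so that management options —
keeping the forest, clearing it, or routing wastewater through constructed
mangrove wetlands before discharge — can be compared quantitatively, with a
chromium mass ledger that closes exactly.

The model couples three components on one Cartesian grid:

1. **Depth-averaged shallow-water hydrodynamics.** Continuity and momentum
   for the surface elevation $\zeta$ and velocities $(u, v)$:
   $$\partial_t \zeta + \partial_x\big[(d+\zeta)u\big] +
     \partial_y\big[(d+\zeta)v\big] = 0,$$
   $$\partial_t u + u\,\partial_x u + v\,\partial_y u
     = -g\,\partial_x\zeta + f v - \frac{\tau_{bx}}{\rho_w (d+\zeta)}
       + \frac{F_x}{\rho_w (d+\zeta)} + K\,\nabla^2 u,$$
   and symmetrically for $v$ (with $-fu$ and $g\,\partial_y\zeta$; the
   gradient in the $v$ equation is taken in $y$). Bed friction is the
   quadratic Chézy–Manning law
   $\tau_{bx} = \rho_w g\,|U|\,u / C^2$, $C = h^{1/6}/n$, with the Manning
   roughness $n$ tied to the land class: 0.005 s m$^{-1/3}$ for the riverbed
   and 0.15 s m$^{-1/3}$ for the mangrove floodplain (the calibrated channel
   value is unusually smooth for natural channels but is used as given, and
   is configurable).

2. **Advection–dispersion transport of dissolved Cr** $c$ (g m$^{-3}$ ≡ mg/L):
   $$\partial_t c + u\,\partial_x c + v\,\partial_y c
     = D_x \partial_x^2 c + D_y \partial_y^2 c + F(x,y,t)
       - k_{01} c + k_{10} S_l,$$
   where $F$ collects the industrial point sources and the last two terms
   couple the water column to the soil.

3. **Linear water–soil–plant compartment kinetics** per cell:
   $$\dot S_l = k_{01} c - (k_{12}+k_{13}+k_{10})\,S_l + k_{21} S_s, \qquad
     \dot S_s = k_{12} S_l - k_{21} S_s, \qquad
     \dot P_l = k_{13} S_l,$$
   for Cr in the soil liquid phase, soil solid phase, and plant. The plant is
   one aggregate pool (no organ resolution), it has no loss term, so plant
   chromium is non-decreasing — a property asserted on every run. The uptake
   coefficient $k_{13}$ depends on stand age: $7\times10^{-8}$ s$^{-1}$ for
   young trees (greenhouse estimate), and an order of magnitude less
   ($7\times10^{-9}$ s$^{-1}$, a tunable placeholder) for the mature forest,
   because bark formation reduces the permeability of older root systems.

# Unit closure between water and soil

The pools are concentrations per kg of soil (mg/kg) while the water column
carries g/m$^3$; the literature states the kinetics in these mixed units
without the conversion. We close the balance with a soil context
$(\rho_b, z_s)$ — bulk density (default 1300 kg/m$^3$) and exchanging layer
depth (default 0.3 m) — so that one cell of area $A$ holds
$\rho_b z_s A$ kg of soil, and a pool value $p$ (mg/kg) is an areal mass
$p\,\rho_b z_s A / 10^6$ kg. The water-side exchange is scaled by
$$\gamma = \frac{\rho_b z_s}{1000\,h},$$
applied to *both* exchange terms: $\dot c_{\text{exch}} = \gamma(-k_{01} c +
k_{10} S_l)$. With $\gamma$ on both legs, the gram the soil gains is exactly
the gram the water loses, which is what makes the ledger testable; applying a
conversion to only one leg (as a literal reading of the transport equation
would suggest) cannot conserve mass for general depths. For the same reason
all three pools — including the plant — are accounted against the soil-column
mass $\rho_b z_s A$; the biomass density $B$ (default 10 kg/m$^2$) only
re-expresses the plant pool per kg of biomass for reporting. Both choices are
interpretations (the source material never states the conversions) and every
constant is configurable.

Exchange happens only while a cell is inundated: mangroves take up pollutants
only when exposed to polluted water, so dry cells are inert — we freeze the
internal soil kinetics on dry cells as well, since a half-active dry cell
would be a stronger assumption than the data support.

# Numerics

* **Hydrodynamics.** Arakawa C-grid ($\zeta$ at centers, $u,v$ on faces),
  explicit forward–backward stepping (continuity first, then momentum with
  the new surface), first-order upwind momentum advection, semi-implicit bed
  friction (unconditionally stable as depth vanishes), explicit Coriolis and
  eddy viscosity. Face depths are upwinded with the higher-bed rule
  $h_f = \max(\zeta_L,\zeta_R) + \min(d_L, d_R)$, which lets a wet cell flood
  a dry neighbour; faces close below the drying threshold
  $h_{\text{dry}} = 0.01$ m (common practice for 2D estuarine solvers;
  configurable) and a per-cell limiter caps volume export at 90% of content,
  so depths stay nonnegative without mass clipping. The flux form makes
  closed-basin volume conservation exact to rounding. Time steps respect
  $\Delta t \le \mathrm{CFL}\cdot\min(\Delta x,\Delta y)/(\sqrt{gh}+|U|)$
  with CFL = 0.7. The solver is verified against analytic oracles rather than
  against any reference code: lake-at-rest invariance (machine precision),
  the Merian seiche period $2L/\sqrt{gH}$ (within 2%), and the linear
  standing-wave amplitude profile in a frictionless forced channel (within
  5%, measured by harmonic regression after a smooth two-period start-up ramp
  that suppresses free seiche modes).

* **Transport.** Finite-volume update of the depth-integrated mass
  $m = c\,h$ using the *same* face volume fluxes the continuity step used,
  so a spatially uniform concentration stays exactly uniform under pure flow
  and the Cr ledger closes against the water-volume ledger. Advection is
  first-order upwind (exact at unit Courant number), dispersion central
  across wet interior faces, and a per-cell mass limiter preserves
  nonnegativity without breaking conservation. Open boundaries are
  zero-gradient on outflow and carry a configured concentration (default 0)
  on inflow; every boundary crossing is logged to the export/import ledger.
  The default $D_x = D_y = 10$ m$^2$/s is a typical estuarine magnitude (the
  source material never states transport dispersion); accuracy is verified
  against the 1-D Gaussian plume solution (relative $L^2$ error < 5% at
  4 m resolution, decreasing under refinement), not against the default.

* **Compartments.** The kinetics are linear, so with the water concentration
  frozen over a transport step the pools are advanced *exactly* by the
  matrix exponential of the augmented rate system, precomputed once per
  stand-age class (unconditionally stable for stiff constants). Classical
  RK4 and explicit Euler integrators are kept as independent numerical
  routes; the acceptance suite checks RK4 against the closed form to
  $10^{-8}$ relative over random nonnegative parameter draws. The water-side
  change is bookkept as the exact negative of the pools' areal mass change.

* **Operator splitting.** Each transport/kinetics step spans a fixed number
  of hydrodynamic steps (default 6) and uses the time-averaged face fluxes
  of that window, which keeps the water and tracer budgets consistent by
  construction; the splitting error is $O(\Delta t)$ and controlled by the
  step length. The two compiled kernels (shallow water, transport) have
  vectorized R reference implementations kept in the package, and an
  equivalence test drives both through 500 wetting–drying tidal steps.

# The toy catchment and the scenario engine

All runnable inputs are generated by code. `make_toy_catchment()` builds a
south–north tidal channel (10 km × 400 m, 10 m deep, 100 m cells; about
100 × 20 cells in total) flanked by a mangrove floodplain on the west bank
and bare industrial land on the east bank, both 0.5 m above datum so the
semidiurnal tide (amplitude 2.7 m, the average of the emulated estuary)
floods and drains them twice daily. Freshwater enters from the north at the
dry-season average 580 m$^3$/s. Five point sources sit in the channel along
the east bank with the investigated discharge rates (A2 0.5, A1 1, Cai Mep 1,
Phu My 0.2, Go Dau 2 mg/s), all active only during the daily 12:00–14:00
release window — implemented as a fixed clock window, not a lunar-phase
trigger, since that is how the release regime is described. Two monitoring
stations, M1 (downstream) and M5 (upstream), record water level,
concentration and pools.

Scenarios are templates over this catchment:

* **SC1** — baseline: mature mangroves west, direct discharges east.
* **SC2** — deforestation: every mangrove cell becomes bare ($k_{13}=0$);
  discharges are identical to SC1, since the release regime is described as
  the same across scenarios. The Manning field is deliberately left at its
  baseline values: the scenario isolates the biogeochemical role of the
  forest, and a simultaneous roughness change would confound the
  concentration comparison with hydrodynamic effects whose sign the uptake
  comparison principle does not control.
* **SC3** — constructed wetlands: strips of east-bank cells behind each
  source become young-mangrove wetland, and all wastewater is routed through
  per-source wetland units before discharge.
* **NonEco** — SC1 geometry with the soil–plant exchange switched off; the
  reference against which any ecosystem service is measured.

Because uptake removes mass monotonically from the water column, the
station-mean concentrations obey NonEco ≥ SC2 ≥ SC1 ≥ SC3, with strict
inequalities wherever the forcing differs; this ordering is asserted in the
acceptance suite. Under the shipped placeholder kinetics the SC2–SC1 gap is
small (it scales with $k_{10}\cdot k_{13}$, both order-of-magnitude
placeholders), but it is deterministic and one-signed.

**Constructed wetlands** are modeled as continuously stirred reactors with
residence time $\tau$ (default 24 h) rather than resolving internal wetland
hydraulics, which the scenario description does not specify. Influent raises
the internal concentration $c_w$; uptake removes mass at the effective rate
$r = \gamma_w k_{01}$ (with $\gamma_w$ evaluated at the wetland depth,
default 0.5 m); the effluent $V c_w/\tau$ discharges to the river cell. The
scalar balance is solved exactly per step, giving the closed-form check
effluent/influent $= 1/(1 + r\tau)$ at steady state with uptake as the sole
removal path. Retained mass accumulates in the unit's own pools and appears
in the budget as `wetland_retained`.

**Mass budget.** Every gram is tracked: injected by sources, stored in the
water column (including mass buffered at momentarily dry source cells, which
is held rather than lost, and wetland water), stored per pool, retained in
wetlands, and exported through open boundaries. The residual closes to
rounding ($\lesssim 10^{-13}$ relative) on every scenario; the acceptance
criterion is $10^{-6}$.

# Calibration tools

`nse()`, `index_of_agreement()` and `rmse()` implement the three skill
scores used to judge hydrodynamic calibration; the index of agreement uses
Willmott's classical form with the observed mean in both absolute terms
(the cited definition). `fit_compartment_params()` estimates the five
kinetic constants from greenhouse time series (sampling design: start, month
three, month six) by bounded Levenberg–Marquardt on the closed-form
trajectories, weighting each pool's residuals by its observed standard
deviation so mg/L and mg/kg scales contribute comparably; a sensitivity-rank
check flags non-identifiable designs before fitting, and designs with fewer
observations than free parameters are rejected. `tune_k13()` is the 1-D
field-tuning step for the mature-forest uptake coefficient. Optimizer
tolerances are fixed ($10^{-10}$ on cost, $10^{-8}$ on parameters).

The synthetic greenhouse generator samples the analytic trajectories and
adds multiplicative Gaussian noise from a private seeded stream (the global
RNG is untouched, and the seed is recorded in the dataset). Parameter
recovery is validated on this synthetic route: noiseless data recover every
constant within 5%, and the estimate RMSE across seeded replicates decreases
with the noise level. Real greenhouse data would add features the generator
does not emulate — pot-to-pot heterogeneity, non-constant water
concentration, measurement detection limits — so recovery here demonstrates
the estimator's correctness, not field identifiability.

# Problem sizes and known limitations

The test and acceptance runs use the 100 × 20-cell toy catchment: a 30-day
baseline run for budget closure, 6-day runs for the four-scenario ordering,
and reduced domains (channels of a few hundred cells) for the hydrodynamic
and transport oracles. These sizes were chosen as the smallest domains on
which upstream and downstream stations are dynamically distinct and the
banks wet and dry through full tidal cycles.

What passing tests show — and what they do not: the solvers reproduce
analytic solutions, conserve mass exactly, and order the scenarios as the
ecology dictates on an idealized domain. They do not reproduce any
field-scale numbers (retained kilograms, station concentrations in mg/L,
soil concentrations in mg/kg), which depend on the real bathymetry,
hydrometric records and calibrated kinetics that are outside this package's
scope. The kinetic defaults other than the young-tree $k_{13}$ are
order-of-magnitude placeholders meant to be replaced by fitted values.
Further limits: first-order upwind schemes are diffusive (sharp fronts
smear); the wetland units are zero-dimensional; Cr speciation, sediment
transport, salinity/baroclinic effects and forest growth dynamics are not
modeled.

# A worked example

```{r example, eval = FALSE}
tc <- make_toy_catchment()
runs <- lapply(c("SC1", "SC2", "SC3", "NonEco"), function(nm) {
  run_simulation(build_scenario(nm, tc), duration = 6 * 86400)
})
compare_scenarios(runs)
mass_budget(runs[[1]])
uptake <- uptake_rate_field(runs[[3]], c(0, 6 * 86400)) # mg/kg/day
```
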