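---
title: "Deriving big-leaf ecosystem properties from eddy covariance data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving big-leaf ecosystem properties from eddy covariance data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxleaf)
```

## The model

Eddy covariance (EC) towers measure the turbulent exchange of sensible
heat ($H$), latent heat ($\lambda E$), and CO$_2$ (NEE) between an
ecosystem and the atmosphere, together with the meteorological state at
the measurement height $z_r$. fluxleaf treats the ecosystem below the
sensor as a single uniform source/sink plane at height $d + z_{0h}$ — the
*big leaf* — and derives bulk ecosystem properties *top-down* by inverting
the transfer equations that connect that plane to the instruments.

Everything hinges on two conductances in series:

* the **aerodynamic conductance** $G_{ah}$, composed of a turbulent
  momentum-transfer part $G_{am}$ and a quasi-laminar canopy boundary
  layer part $G_{bh}$, $1/G_{ah} = 1/G_{am} + 1/G_{bh}$;
* the **surface conductance** $G_{sw}$, obtained by inverting the
  Penman-Monteith equation
  $$G_{sw} = \frac{\lambda E \, G_{ah}\gamma}
  {s\,(R_n - G - S) + \rho c_p G_{ah} D_a - \lambda E (s + \gamma)},$$
  which under a dry, closed canopy approximates the canopy-integrated
  stomatal conductance.

$G_{am}$ can be computed from the flux-variance relation
$u_*^2/u(z_r)$ (stability accounted for implicitly) or from the
stability-corrected logarithmic profile
$k u_*/[\ln((z_r-d)/z_{0m}) - \psi_h(\zeta)]$, with $\zeta = (z_r-d)/L$
and $L$ the Monin-Obukhov length. Three $G_{bh}$ models of increasing
physical detail are provided (friction-velocity only; canopy integration
with leaf width and LAI; and a drag-partition model with a bare-soil
Stanton-number term), all exchangeable behind
`aerodynamic_conductance()`.

From the conductances and the measured fluxes follow, by further
inversion: conditions at the big-leaf surface ($T_s$, $e_s$, $D_s$,
$C_s$), the radiometric surface temperature, the decoupling coefficient
$\Omega$, the equilibrium/imposed decomposition of $\lambda E$, potential
ET (Priestley-Taylor or prescribed-$G_{sw}$ Penman-Monteith),
energy-balance diagnostics, water- and light-use efficiencies, the
stomatal slope $G_1$ and VPD sensitivity, bulk intercellular CO$_2$, and
canopy photosynthetic capacity ($V_{cmax,25}$, $J_{max,25}$) from a
per-record Farquhar-model inversion.

## Assumptions and their consequences

The big-leaf inversion assumes a horizontally and vertically homogeneous
source, an energy balance that closes ($R_n - G - S = \lambda E + H$),
and amphistomatous transfer ($G_{ah} = G_{aw}$). None of these holds
exactly at real sites; derived quantities are therefore *bulk diagnostic*
properties: they mix soil and vegetation signals (increasingly so below
LAI of 2–3), and every inversion step propagates the uncertainty of the
previous one — $G_{sw}$ inherits flux errors, $C_i$ inherits $G_{sw}$
errors, and $V_{cmax}$ sits at the end of the chain. Filtering is
correspondingly central, not cosmetic.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `frac_d`, `frac_z0m` | 0.7, 0.1 | of $z_h$ | roughness estimates from canopy height |
| `Sc_CO2` | 1.07 | – | Schmidt-number scaling of $G_b$ to CO$_2$ |
| `alpha_PT` | 1.26 | – | Priestley-Taylor coefficient |
| `emissivity` | 0.98 | – | radiometric temperature inversion |
| `tGPP`, `ws`, `min_int` | 0.5, 15 d, 5 d | – | growing-season delineation |
| `PPFD_c`, `PPFD_j` | 1000, 500 | µmol m⁻² s⁻¹ | Farquhar limitation-state thresholds |
| `Theta`, `f_APPFD` | 0.85, 0.8 | – | electron-transport curvature; PSII absorption |
| `G1` fit protocol | `g0 = 0` | – | see below |

All physical constants live in a single overridable registry,
`flux_constants()`. The Farquhar kinetic constants default to
Bernacchi-type values at 25 °C with Arrhenius temperature responses and a
peaked (modified) Arrhenius normalization of $V_{cmax}$ and $J_{max}$ to
25 °C; all are exposed through the `kinetics` argument and echoed in the
output. The radiation thresholds separating Rubisco- from
RuBP-regeneration-limited records are conventions, not measurements: the
resulting capacities should be compared across sites only under a fixed
threshold choice.

## Design choices made where the design was open

**Stomatal slope fitting with a fixed intercept.** The unified stomatal
optimization model $G_{sw} = G_0 + 1.6(1 + G_1/\sqrt{D})\,\mathrm{GPP}/C$
contains a term with *fixed* unit coefficient that shares GPP with the
$G_1$ term. Under multiplicative noise in GPP (the realistic case — GPP
is itself the output of an NEE partitioning), a fit with free $G_0$ is
badly biased: the intercept absorbs the error correlation and $G_1$ drops
by roughly twice the noise variance ratio (about −20 % at 10 % noise in
our simulations). Fixing $G_0 = 0$ — the same protocol used for
ecosystem-scale $G_1$ reporting in the literature — removes the intercept
degree of freedom and leaves a residual bias of order −1 %. `stomatal_slope()`
supports both (`g0 = "free"` or a fixed value); summaries in this package
use `g0 = 0`.

**Sign conventions.** Fluxes away from the surface are positive
throughout, so net CO$_2$ uptake has negative NEE and the biochemical
energy flux $S_p = 0.422\,\mathrm{NEE}$ (W m⁻² per µmol m⁻² s⁻¹) is
negative under uptake; the energy-use efficiency is reported as
$-S_p/R_n$ so that uptake yields a positive efficiency. The printed unit
of the 0.422 coefficient is treated as J µmol⁻¹, which is what makes the
product a W m⁻² energy flux.

**Longwave radiative conductance.** The conventional printed form
$G_r = 4\sigma T^3 \mathrm{LAI}/c_p$ carries units of kg m⁻² s⁻¹; strict
m s⁻¹ requires division by air density. `longwave_conductance()`
implements the printed form by default and offers `normalize_rho = TRUE`,
rather than silently correcting a formula users will want to compare
against.

**Growing-season normalization.** "Smoothed GPP above a relative
threshold" needs a reference level; we use the 95th percentile of the
smoothed daily series (robust to spikes), with `max` and absolute-value
alternatives. Runs shorter than `min_int` (in either state) adopt the
preceding accepted state in a single chronological scan — deterministic
and order-stable.

**Rain window.** A precipitation record excludes itself (precip > 0
rule) and the half-open window $(t, t+24\,\mathrm{h}]$ after it, so the
boundary record exactly 24 h later is the last one excluded.

**Supersaturation and negative conductances** produced by inversions are
flagged, never clipped or dropped: filtering is an explicit, separate
stage (`filter_data()`), and silent repair would hide diagnostic
information (e.g. energy-balance problems).

## Numerical choices

* Saturation vapor pressure: Magnus form with Sonntag coefficients
  (Alduchov-Eskridge selectable); the slope $s$ is the analytic
  derivative, verified against numerical differentiation.
* Wet-bulb and dew-point temperatures: bisection on $[-100, T_a]$ °C to
  $10^{-6}$ kPa, at most 200 iterations — derivative-free and immune to
  the flat tail of the Magnus curve.
* $\zeta$ is clamped to $[-15, 15]$ before evaluating $\psi$ to stop
  single extreme records (near-zero $u_*$) from producing infinities.
* $\zeta = 0$ belongs to the neutral branch of the stability functions,
  keeping $\psi$ continuous at the stable/unstable tie.
* Nonlinear fits (stomatal slope, light response) use Levenberg-Marquardt
  least squares (`minpack.lm`); the VPD-sensitivity model is linear in
  $\ln D$ and uses ordinary least squares.
* $J_{max}$ follows from $J$ by the exact closed-form inversion of the
  non-rectangular hyperbola, not by iteration; records with
  $J \ge \mathrm{APPFD}$ or $C_i \le \Gamma^*$ are excluded and counted.
* Missing values propagate everywhere; no silent imputation.

## The synthetic generator: what it emulates and what it does not

`synthetic_fluxes()` builds met + flux series *forward* through the same
physics the package inverts: diurnal radiation/temperature/VPD cycles
with day-to-day cloudiness and temperature variability; wind and $u_*$
consistent with a neutral logarithmic profile over a canopy of known
$d$ and $z_{0m}$; GPP from a rectangular-hyperbola light response
(defaults $\alpha = 0.05$, $\mathrm{GPP_{ref}} = 30$ µmol m⁻² s⁻¹ at
2000 µmol m⁻² s⁻¹, $R_{eco} = 3$ µmol m⁻² s⁻¹); $G_{sw}$ from the USO
model ($G_1 = 2.0$ kPa$^{0.5}$, $G_0 = 0$); $\lambda E$ from the forward
Penman-Monteith equation; and $H$ as the energy-balance residual, so
closure is exact unless a closure factor below one is requested. Noise is
mean-one multiplicative lognormal on the fluxes (default sdlog 0.1) and
additive Gaussian on met variables (default off), mimicking the
multiplicative character of EC random error in the simplest way. Default
span: 105 days of half-hourly records (5040), a typical single growing
season.

Because $H$ is derived by closure, the Penman-Monteith inversion is an
*exact* inverse on noise-free output — which is what makes the round-trip
tests sharp. The generator deliberately does **not** simulate stratified
boundary layers (wind follows the neutral profile, so wind-profile
roughness recovery is tested with the stability correction disabled),
storage fluxes, advection, low-LAI soil evaporation, or seasonal
phenology. Passing recovery tests therefore demonstrate the correctness
and numerical health of the inversion chain, not the realism of any
particular site; the biases the big-leaf assumptions introduce at real
sites (see above) are outside what these tests can show.

## Verification strategy and problem sizes

Three layers of tests, all seeded and desk-scale:

1. **Algebraic identities** on $10^4$-point random valid parameter grids:
   Penman-Monteith forward/inverse round trip; the $\Omega$-weighted
   decomposition $\Omega \lambda E_{eq} + (1-\Omega)\lambda E_{imp}$
   against the forward equation (to $10^{-9}$ relative); flux-variance vs
   profile $G_{am}$ under neutral profile-generated wind; the radiative
   decoupling form at $G_r = 0$; the electron-transport round trip; all
   unit-conversion round trips.
2. **Scalar hand-oracles**: every worked example is recomputed from the
   printed formula by independent inline arithmetic and compared at
   $10^{-6}$ relative.
3. **Parameter recovery** from the generator: exact on noise-free data;
   under 10 % flux noise at 5040 records, $G_1$ within ±2 % and the
   light-response parameters within ±5 %; VPD-sensitivity $m, b$ within
   ±5 % at 2000 records; wind-profile $z_{0m}$ within ±5 % (noise-free).

These sizes keep the whole suite under ten seconds on one CPU while
leaving the recovery margins far from their tolerances.

## Known limitations

Single-level, single-big-leaf only (two-level sites are handled by
running the toolkit per level and differencing upstream); no NEE
partitioning, $u_*$-threshold estimation, gap-filling, or footprint
modeling — these are assumed done upstream; no mesophyll conductance
(infinite assumed) and no solar-elevation-dependent PSII absorption;
hypostomatous canopies are not supported by the Penman-Monteith
inversion. Physiological outputs are per ground area and must not be
compared directly to leaf-level measurements.
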