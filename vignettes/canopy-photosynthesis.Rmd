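---
title: "Multiscale canopy photosynthesis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale canopy photosynthesis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Canopy photosynthesis (`A_c`, mol CO2 per m2 ground per day) — not single-leaf
photosynthesis — is what correlates with crop biomass.  In a dense stand, top
leaves absorb more light than they can use and dissipate the excess as heat,
while lower leaves starve.  One proposed engineering route is to reduce leaf
chlorophyll by truncating the photosystem light-harvesting antenna: paler
upper leaves transmit more light downward, each PSII runs closer to its
photochemical optimum, and the nitrogen no longer spent on antenna protein can
be reinvested in Rubisco and electron-transport capacity.

`canophot` implements the full chain needed to evaluate that idea: a
parametric 3D stand, forward Monte-Carlo ray tracing of the diurnal light
field, a light-driven vertical nitrogen profile, per-leaf photo-acclimation of
nitrogen partitioning, a mechanistic leaf model, and canopy integration with
a scenario engine for chlorophyll multipliers, nitrogen strategies,
architectures and latitudes.

# Model chain

## Canopy (`build_canopy`)

Plants sit on a rectangular grid (defaults: 3 x 3 plants at 0.25 x 0.20 m, the
20 plants m-2 of a transplanted rice stand).  Each plant carries tiller whorls
of four leaf ranks; each blade is a strip of quads along a parabolically
drooping midrib, with width profile `w(s) = w_max (1 - 0.96 s^2)`.  The
default dimensions give LAI about 4.6, a literature-typical booting-stage
value — the measured architecture of the motivating field stand is not
available, so the defaults are an explicit, config-exposed stand-in, not a
reconstruction.  Architecture factors scale leaf inclination (clamped to
[0, 90] degrees), plant height, and blade width; width (not leaf count)
carries the LAI factor so the leaf-area effect is isolated from rank
structure and angles.

The plot is treated as horizontally periodic everywhere downstream, so even
one plant represents an extended field.  Facets are wrapped into the plot by
whole-facet translation; the tracer additionally bins every facet under its
+-1-tile images so boundary-straddling geometry is seen from both sides.

## Light (`solar_course`, `trace_canopy`, `diurnal_light`)

Solar position uses the Spencer declination series with hour-angle geometry.
Clear-sky irradiance follows a one-parameter transmittance model
(`tau = 0.75`): direct beam `I0 tau^m` on the sun-normal plane and diffuse
`0.3 (1 - tau^m) I0 cos z` on the horizontal, `m` the relative air mass.  The
diffuse sky is a standard-overcast-sky radiance, sampled flux-weighted.

The tracer launches `rays_per_m2 x plot area` rays per category from a plane
above the canopy.  At each hit the ray's energy splits deterministically into
absorbed, reflected and transmitted parts per the facet optics (Lambertian
scattering on both sides, no specular term), and children are traced to
`max_bounces` (default 2) with a 1% energy cutoff; truncated energy is
tracked in a `residual` bucket so the energy ledger
(leaf + soil + escaped + residual = incoming) closes to machine precision by
construction — Monte-Carlo noise appears in *where* energy lands, not in the
total.  Deterministic splitting has markedly lower variance than
Russian-roulette termination at these ray budgets.  Soil is a Lambertian
absorber (reflectance 0 by default).

`fit_extinction` bins facets by cumulative LAI from the top — not geometric
height — because Beer's law is defined on downward-cumulative leaf area, and
fits `log(PPFD)` against depth.  On a homogeneous random-facet slab with a
spherical leaf-angle distribution the fitted coefficient reproduces the
turbid-medium value `G / cos z` with `G = 0.5` within 15%.

## Leaf optics from chlorophyll (`optics_from_chl`)

Broadband PAR absorbance follows a saturating exponential
`a(chl) = a_max (1 - exp(-chl / chl0))` with `a_max = 0.96` and `chl0`
calibrated so a 494.7 umol m-2 leaf absorbs 0.90; the unabsorbed fraction
splits 1:1 between reflectance and transmittance.  This is a deliberate,
fully config-exposed substitute for an empirically fitted optics table.  Its
main known bias: at strongly reduced chlorophyll (0.4x) it gives absorbance
0.64, lower than the ~0.8 typically measured in pale rice leaves, because a
single exponential anchored at (494.7, 0.90) cannot also reproduce the
pigment-packing flatness of real leaves.  Consequences are discussed under
*Limitations*.

## Nitrogen profile (`nitrogen_profile`)

Leaf nitrogen per area follows the light profile:
`N_LA = (N_LA_flag - n_b) (I_l / I_lfl)^b + n_b`, with `I_l` each facet's
daily incident PPFD integral, `I_lfl` the mean over the middle (median-height
tercile) of the flag-leaf layer, and `b = beta GAI^(-alpha)`.  The printed
form of the `b` allometry is ambiguous between a power law and a linear form;
the power form is the default (the nitrogen gradient weakens in denser
canopies, matching the behaviour of the allometry's source) and the linear
form remains available.  Defaults `beta = 0.8`, `alpha = 0.45`, flag-leaf N
1.6 g m-2, basal N 0.4 g m-2.  Incident (not absorbed) light defines the
gradient, and only light *ratios* enter, so the profile is invariant to
uniform rescaling of the light field.

## Leaf biochemistry (`leaf_assimilation`, `psii_partition`)

A full kinetic model of electron transport plus carbon metabolism is out of
scope; the leaf model is a steady-state Farquhar-type core whose capacities
derive from seven protein pools via `Vmax = kcat c`:

| group | capacity role | default constants |
|---|---|---|
| Rubisco | `Vcmax = 3.5 s-1 x 8 sites x mol(550 kDa)` | ~51 umol g-1 s-1 |
| CE (other Calvin enzymes) | caps `Vcmax` at `100 umol g-1 s-1 x CE` | co-limiting at reference |
| ETCF (chain + ATPase) | `Jmax = 260 umol e- g-1 s-1 x ETCF` | Jmax/Vcmax ~ 1.8 |
| PSII | electron throughput cap `300 e- s-1 x [PSII]`; excitation partition | |
| PSI | stoichiometric partner, [PSI]/[PSII] = 1.4 | |
| LHCII / LHCI | chlorophyll (14 per unit) and absorbance only | |

Excitation partitioning at PSII balances supply (half the leaf-absorbed PPFD,
times the open-centre photochemical yield `k_p/(k_p+k_f+k_h0) = 0.83`, a
canonical dark-adapted PSII quantum yield used as calibration, not data)
against the downstream electron sink, blended with a hyperbolic
co-limitation (curvature 0.92) so centres close progressively; closed centres
dissipate via a regulated heat constant.  The three fractions
(photochemistry, heat, fluorescence) sum to 1 exactly.  Assimilation is
`min(Wc, Wj) - Rd` at 25 C and fixed `Ci = 280 umol mol-1` (0.7 x ambient;
no stomatal model), `Rd = 0.015 Vcmax`.

Nitrogen per pool combines protein mass x 16% N with 4 N atoms per bound
chlorophyll.  Within-group stoichiometries sit in one constants object
(`kinetic_params`) so the whole nitrogen account is auditable.

Two routes change leaf chlorophyll: `antenna_size` (LHC pools only, reaction
centres fixed) and `ps_number` (all four photosystem pools co-scaled).  In
this model the antenna route preserves the light-saturated rate and the
absorbed-light initial slope exactly, while the incident-light slope falls
with absorbance; the photosystem-number route additionally lowers capacity
through the PSII throughput cap.  A kinetic model can in addition show a
near-constant incident-light slope under antenna truncation (closure effects
inside the fitted range); that second-order signature is outside what this
steady-state reduction can reproduce, and tests assert the orderings the
model does support.

## Acclimation (`optimize_acclimation`)

`P_max` is linear in each capacity pool and `phi` in PSII across the
documented 0.8-1.2x pool range (`calibrate_linear_relations`; the capacity
relations are exact by construction, R^2 = 1.0; the phi relation carries the
absorbance saturation and reaches R^2 ~ 0.98 in that range).  Each leaf then
solves a one-dimensional problem: split its photosynthetic nitrogen budget
(75% of `N_LA` by default) between the capacity side (Rubisco:CE:ETCF in
reference proportions) and the photosystem side (PSII:PSI:LHC in reference
proportions), maximizing daily carbon uptake of the implied nonrectangular
hyperbola over its own diurnal growth light.  The frontier prunes splits
beyond the PSII-cap peak (they are dominated), and ties break toward the
lower-capacity end.  Growth light is one deterministic clear-sky day — the
shipped sky model is day-to-day constant, so multi-day averaging would be a
no-op; the `course` hook in `diurnal_light` admits stochastic skies later.
Curvature `theta` (0.8 nominal; the calibration's fitted median in practice)
and `R_d` are held fixed during optimization.

After acclimation each leaf's antenna is set so its pool chlorophyll equals
its assigned facet chlorophyll (chlorophyll determines LHC at the acclimated
reaction-centre number).  For dim leaves holding the full canopy-mean
chlorophyll this implies large antennas — an accounting consequence shared by
any model that pins chlorophyll and acclimates photosystem number
independently.

## Scenarios (`run_pipeline`, `run_chl_sweep`, `run_architecture_sweep`)

A scenario multiplies each leaf's default chlorophyll (0.4-1.2x canon) via
the antenna route and applies one nitrogen strategy: `lhc_only` (freed N
leaves the leaf) or `constant_total_n` (freed N spread over all non-LHC pools
proportional to their N shares; conservation is exact to 1e-6 and
property-tested).  The light field is re-traced with the scenario optics,
assimilation is integrated over the full 24 h (night = dark respiration),
and `NUE = A_c / canopy photosynthetic N`, counting the seven pools only —
the NUE definition is isolated in one function (`nue`) because the quantity
is conventionally plotted without a printed formula.

# Synthetic data and what passing tests mean

The toy generators (`single_facet_canopy`, `stacked_facets_canopy`,
`random_canopy`) exist so that tracer physics can be checked against closed
forms: single-interaction energy splits, layer-to-layer transmission,
turbid-medium extinction.  The default stand emulates a booting-stage rice
canopy in its density, rank structure and erectness, but its blade
dimensions, angles and the chlorophyll profile shape are constructed, not
measured; the vertical "measured-like" chlorophyll profile is a qualitative
gradient (declining with rank and toward the tip), rescaled to the requested
mean.  Tests passing on these stands establish internal correctness
(conservation laws, analytic limits, oracle agreement, orderings), not
field-level prediction for any particular cultivar.

Scenario magnitudes on the default stand, for calibration of expectations:
at 0.4x chlorophyll the LHC-only strategy yields A_c +2.3% and NUE +14.4%,
and constant-N reinvestment +3.2% on both — the orderings (reinvestment
beats discarding at every reduced multiplier; both NUE gains positive) are
stable, while the absolute reinvestment gain is bounded by the ~13% share of
photosynthetic nitrogen that the antenna holds under the shipped protein
masses.

# Numerical choices

- **Tracer**: uniform-grid DDA traversal sized to a few triangles per cell;
  Moller-Trumbore two-sided intersection; xorshift64* RNG seeded per time
  step (bit-reproducible given a seed, independent of R's RNG state);
  degenerate triangles are skipped with a warning count.
- **Quadrature**: diurnal integrals use the midpoint rule on the fixed step
  grid (0.5 h default; agreement with fine quadrature to ~0.3%).
- **NRH fitting**: Levenberg-Marquardt with analytic-ish starts (initial
  slope from the light-limited points, asymptote from the curve top) and
  three curvature starts, best residual kept; bounds keep `phi < 0.125`
  (the physical quantum-requirement ceiling) and `theta` in (0, 1).
- **Ties**: the acclimation argmax keeps the first (lowest-capacity) optimum.
- **Degenerate inputs**: all-dark sites fall back to the basal-nitrogen
  profile (the formal limit of the profile equation) and yield pure
  respiration; chlorophyll targets below the core-antenna bound raise errors
  naming the feasible minimum.

# Problem sizes

Default runs use the 3 x 3-plant stand (~4000 facets), 0.5 h steps and
2 x 10^4 rays m-2 per category (~9 x 10^3 rays per step and category, ~2.5 s
per diurnal trace; a full five-multiplier, two-strategy sweep takes ~45 s).
Energy-conservation checks run at ~10^5 rays per step.  The architecture
robustness grid (3 angle x 3 height x 3 LAI x 4 latitudes) runs on a
single-plant periodic stand at 1.5 h steps and 10^4 rays m-2, about 20 s for
216 pipeline runs.  All sizes are config knobs; ray densities scale linearly
in time.

# Known limitations

- The leaf optics substitute underestimates absorbance of strongly
  chlorophyll-reduced leaves (see above).  This depresses the absolute A_c
  benefit of chlorophyll reduction — most visibly in fully erect
  architectures, where deep light penetration leaves little redistribution
  gain to offset the absorbance loss — and is the first place to plug in
  measured spectra via `broadband_optics`.
- The steady-state leaf reduction carries no NPQ induction/relaxation
  kinetics, no metabolite dynamics, and no photorespiration detail beyond
  `Gamma*`.
- No stems, sheaths or panicles; no within-canopy CO2 gradient; temperature
  fixed at 25 C.
- Absolute A_c values depend on the shipped kinetic constants; relational
  results (orderings across scenarios, architectures and latitudes) are the
  robust outputs.
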