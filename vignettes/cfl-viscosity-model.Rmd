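---
title: "Modelling the cell-free layer as a heterogeneous viscosity field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cell-free layer as a heterogeneous viscosity field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cflvisc)
```

## The problem

Blood is a suspension: plasma plus cells. In channels whose height is
comparable to a few cell diameters — the 50–300 µm gaps between the rotating
impeller and the housing of a ventricular assist device (VAD) are the
motivating case — cells migrate away from the walls and a **cell-free layer**
(CFL) forms. The near-wall fluid is then pure carrier (plasma) at its lower
viscosity, so wall shear stresses and pressure losses drop below what a
single-phase calculation at the bulk viscosity predicts: the
Fåhræus–Lindqvist effect, here at Reynolds numbers of 50–150 rather than the
creeping-flow regime of the classical literature.

`cflvisc` represents this migration effect as a *prescribed heterogeneous
viscosity field* `mu_loc(h, x)` for a plane channel (gap height `H`,
width-to-height ratio ≥ 7 so the flow is effectively two-dimensional),
together with a reduced-order solver that turns the field into the two
observables used to judge the model: wall shear stress and the normalized
pressure-loss coefficient `cp/cp_0%`.

## Model structure

### Local rheology

The local viscosity follows the Einstein–Roscoe suspension law

```
mu_loc(h) = mu_carrier * (1 - 1.35 * phi_loc(h))^(-2.5)
```

applied to the local particle volume fraction `phi_loc(h)`
(`einstein_roscoe()`). It is strictly increasing, equals the carrier
viscosity in particle-free fluid, and diverges at `phi = 1/1.35`. The law is
reliable only for dilute suspensions; `fluid_spec()` therefore warns above
`phi = 0.05` (the validated range) without refusing, since the same
machinery remains usable for more concentrated blood analog fluids (BAF).
Adapting the law for physiological hematocrits is out of scope here: no
adapted form is established for this flow regime, so the extension is left
unimplemented rather than guessed.

All viscosities are stored in SI (Pa s); constructors accept the rheometer
unit mPa s behind an explicit `units = "mPa.s"` tag. Shear-rate dependence is
deliberately ignored: at these Reynolds numbers the shear rates
(≈ 400–60 000 s⁻¹) are high enough to treat blood as Newtonian at its
high-shear asymptotic viscosity.

### Streamwise sections

The field has three sections in the flow direction:

1. **Homogeneous inlet** (`x ≤ x0`, default `x0 = 1` µm): the suspension
   enters well mixed, `mu = mu_rheo` across the gap. The 1 µm length is an
   empirical modelling device that seeds the development section.
2. **CFL development** (`x0 < x < x*`): the per-wall layer height grows as a
   tilted parabola `H_CFL(x) = a * sqrt(x - x0)` (`hcfl_profile()`). The
   square-root form is the standard description of migration-driven layer
   growth (a parabola whose axis points along the flow); the exponent is
   exposed for sensitivity studies. The coefficient `a` is calibrated from
   two measurement planes by least squares (`calibrate_parabola()`), exact
   when the two planes are mutually consistent. Development is complete when
   the relative growth per `delta_x = 1` µm falls below 0.1%
   (`completion_station()`); whether that threshold is relative or absolute,
   and over which increment, is not fixed by the source material, so the
   relative-per-µm reading was chosen once and made configurable. When a
   measured steady height is supplied it takes precedence and fixes `x*`.
3. **Steady state** (`x ≥ x*`): one of two submodels, below. At `x = x*` the
   development profile lands exactly on the steady height, so the step
   submodel is continuous across the section boundary.

### The two steady-state submodels

Both enforce the same **consistency constraint**: the height-averaged
viscosity at every station must equal the rheometer value,

```
(1/H) * integral_0^H mu_loc(h, x) dh = mu_rheo .
```

* **Step model** (`submodel = "step"`): carrier viscosity inside the bands,
  a single elevated core value
  `mu_step = (H*mu_rheo - H_cfl*mu_carrier) / (H - H_cfl)`
  outside (`step_viscosity_at()`). `H_cfl` here is read as the *total*
  cell-free thickness (both walls combined): that is the only reading under
  which the two-band profile satisfies the consistency constraint, which the
  model states as a requirement. The per-wall reading is retained behind
  `cfl_interpretation = "per_wall"` as a sensitivity mode; it deliberately
  breaks the constraint and is flagged as such. The step model exists
  because for opaque fluids (blood) the full distribution cannot be measured
  optically — only the CFL height can.
* **Local-distribution model** (`submodel = "local_distribution"`): a
  fourth-degree polynomial is fitted by least squares to the measured
  viscosity profile on the particle-laden core (`fit_local_distribution()`),
  carrier viscosity in the bands, and the core *excess* `mu - mu_carrier` is
  rescaled by the unique factor `beta` that restores the consistency
  constraint (`apply_adjustment()`). Scaling the excess rather than the
  viscosity itself leaves the CFL viscosity untouched, which the model
  fixes at `mu_carrier`. The adjustment is needed because real particle
  suspensions deviate from Einstein–Roscoe: pushing a measured BAF
  distribution through the law underpredicts the measured bulk viscosity
  (`beta > 1`), while for blood at 5% it overpredicts (`beta < 1`).

### Flow solver

The fully developed variable-viscosity problem
`d/dh (mu du/dh) = -G`, `u(0) = u(H) = 0` is solved exactly by quadrature:
the shear stress is linear in `h`, `tau(h) = G (h0 - h)`, with
`h0 = ∫(s/mu) ds / ∫(1/mu) ds`, and `G` scaled to the prescribed bulk
velocity (`solve_developed_profile()`). All reciprocal-viscosity moments are
evaluated in closed form for a piecewise-linear `mu(h)` (with a series
branch for nearly constant intervals to avoid cancellation), so step
profiles represented with repeated grid nodes are integrated *exactly*:
against the closed-form two-layer effective viscosity
`1/mu_eff = (b/a)^3/mu_core + (1-(b/a)^3)/mu_cfl` the solver agrees to
machine precision, and for constant viscosity it reproduces
`tau_w = 6 mu c / H` and `G = 12 mu c / H^2`.

Pressure losses come from quasi-developed streamwise marching
(`march_pressure_loss()`): the developed problem is solved per station and
`delta_p = ∫ G(x) dx`. This lubrication-style approximation replaces a full
Navier–Stokes calculation; it is appropriate because the modelled viscosity
varies slowly in `x` and the validated observables are integrated losses and
steady-section wall shear stress, not entrance-region details. Inertial
development of the velocity profile is neglected by construction.

The pressure-loss coefficient is defined as `cp = delta_p / (rho c^2 / 2)`;
the source material never prints its exact definition, but any constant
multiple cancels in the only quantity compared, the ratio `cp/cp_0%` against
a carrier-only reference at the same Reynolds number (`normalized_cp()`).
With the Reynolds number built on each fluid's own rheometer viscosity
(`Re = rho c L_c / mu_rheo`, characteristic length `H` by default, hydraulic
diameter optional), the developed-limit identity `cp/cp_0% = mu_eff/mu_rheo`
holds, which makes the ratio independent of Reynolds number, density and
channel length — mirroring the Reynolds-independent trend seen
experimentally, and proven in the test suite by sweeping `rho` and `Re`.

Two consequences worth naming:

* a homogeneous (single-phase) field returns `cp/cp_0% = 1` identically;
* for blood at 5% (1.45 vs 1.38 mPa s) the ratio is confined to
  `(mu_carrier/mu_rheo, 1) = (0.9517, 1)` whatever the CFL height. The
  published reductions (0.956 at Re = 100, 0.951 at Re = 125) sit at the
  bottom of this band — 0.951 coincides with the analytic floor at printed
  precision — implying a much thicker effective CFL than the 20 µm measured
  for BAF. The blood CFL height used in the original CFD is not printed, so
  the package exposes `h_cfl_ss` as a free parameter and documents this
  sensitivity instead of asserting a value.

Absolute wall shear stresses in Pa depend on the assumed density and
Reynolds-length convention, neither of which is printed for the validation
experiments; dimensionless ratios are the reproduction targets, and the
dimensional values carry that caveat in the documentation.

## Synthetic measurement profiles

No measurement data are deposited, so `generate_profile()` emulates what the
astigmatism particle tracking velocimetry (APTV) campaigns deliver:
wall-normal concentration profiles with empty near-wall bands, a laden core
(flat plateau, or a symmetric quartic bump `(1-xi^2)^2` emulating mid-plane
clustering — quartic deliberately, so the local-distribution submodel has an
exact-recovery pathway), per-bin truncated-Gaussian noise (count-based
binomial noise behind a flag), and two development-section measurement
planes (`generate_development_planes()`), all seeded and bit-reproducible.

Design choices a user should know:

* **Conservation by construction.** The core amplitude follows from mass
  bookkeeping (`phi_bulk * H / (H - h_cfl_bottom - h_cfl_top)` for the
  plateau), and nodal values are control-cell averages of the ideal profile,
  so the trapezoid height average of the noiseless skeleton equals
  `phi_bulk` *exactly on the emitted grid*, not just in the continuum. The
  same cell-averaging is used when the viscosity field itself is
  discretised, which is how the 1e-10 consistency requirement is met without
  any grid alignment conditions. No tube-versus-discharge hematocrit
  correction is applied — the generator mirrors the consistency logic the
  viscosity model applies, a documented simplification.
* **Edge bins.** A layer edge generally crosses the interior of a grid cell,
  so exactly one node per edge carries a fractional concentration.
  `detect_cfl_height()` inverts that partial-bin average to place the edge
  (exact for plateau cores); the raw grid-quantised rule of the detector is
  available with `refine = FALSE`. Recovery of generator ground truth is
  guaranteed to one bin width, and the quartic fit excludes a one-bin guard
  band next to each detected edge for the same reason.
* **Default noise** is 10% of the bulk fraction per bin in the preset
  scenarios — a realistic scatter for binned counting statistics at these
  seeding densities; the measurement-plane stations (2000 and 8000 µm) are
  package choices, as the source shows its planes only graphically.

What passing tests on these fixtures do **not** show: real APTV profiles
have optics-driven systematic errors (astigmatism point-spread, z-binning
artefacts) and wall reflections that no additive noise model emulates, and
real development lengths are set by lift-force physics the generator does
not contain (heights come from measurement or configuration, never from a
migration model). Closure tests demonstrate internal consistency of
detection, calibration and assembly — not the physical correctness of a
measured profile.

Repeated pressure measurements are summarised with
`measurement_uncertainty()`: `u_x = x_s + t * s_x` with a systematic bound
`x_s` (default 2000 Pa, the value used for the reference experiments) plus
the two-sided Student-t 95% confidence limit on the mean.

## Numerical choices

* Grids: uniform in `h` (default `n_h = 256` bins; assembly refuses grids
  that resolve the steady CFL with fewer than 4 bins), piecewise-uniform in
  `x` (finer in the development section, default 64 + 16 stations). The
  Section 2 → Section 3 transition is instantaneous at `x*`; nothing in the
  source suggests blending.
* Quadrature: composite trapezoid on the field grid for averages;
  closed-form reciprocal moments inside the solver (second-order convergent
  for smooth profiles, exact for piecewise-linear ones, verified by a
  grid-refinement test).
* Degenerate inputs: `a = 0` (or `mu_carrier = mu_rheo`) collapses the field
  to a uniform single-phase medium and every ratio to 1 at machine
  precision; an all-zero particle profile, a CFL swallowing the channel, and
  a core with fewer than five fit points are errors, not silent repairs.
* Ties and floors: a fitted core polynomial dipping below `mu_carrier` is
  floored there with a warning before the adjustment factor is computed;
  calibration heights are floored at zero under noise.

## Problem sizes used by the shipped tests

The test-suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which every guarantee is still meaningful rather than as a
constraint of the method: fields of 128–300 wall-normal bins and ≤ 80
streamwise stations, a 1024-bin grid for the two-layer solver check, 100
randomised field scenarios for the conservation property, 200 seeded
replicates for the calibration-bias check, and Monte-Carlo draws of 10^4 for
the uncertainty limit. Everything completes in well under a minute on one
core; `n_h` can be raised freely for production use.

## Limitations

* The field is *prescribed*, not flow-coupled: no feedback from the solved
  shear field onto migration, no time dependence.
* Plane-channel geometry only; no 3D width effects, no device geometries.
* Valid for gaps around 150 µm, `phi ≤ 5%`, Re 50–150; the Einstein–Roscoe
  law must be replaced before physiological hematocrits are meaningful.
* The marching solver is not a DNS replacement for entrance flows or
  2D stress fields; it targets integrated losses and developed-section wall
  shear stress.

## A worked example

```{r example}
presets <- fluid_presets()
m <- cfl_model(presets$fluids$blood_5pct, presets$geometry,
               a = 0.5, h_cfl_ss = 20)
summary(m)
flow <- solve_flow(m, reynolds = 100)
flow
```

The normalized coefficient sits inside `(0.9517, 1)`: the cell-free layer
lowers the pressure loss below the single-phase prediction, by an amount
bounded by the plasma-to-blood viscosity ratio.
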