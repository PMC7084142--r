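---
title: "Methods: from glacier-algal photophysiology to ice-surface darkening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from glacier-algal photophysiology to ice-surface darkening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bioalbedo` models how blooms of heavily pigmented glacier algae capture
light, generate melt, grow, and darken bare glacier ice. This vignette is
the package's own account of the science it implements: the models and
their assumptions, the parameters that matter, what the synthetic-data
generators do and do not emulate, and the numerical and design choices made
where the problem left them open.

## Rapid light curves and the shading correction

Pulse-amplitude-modulated (PAM) fluorometry yields, per actinic light step
of irradiance $E$, the effective PSII quantum efficiency
$Y = (F_m' - F)/F_m'$, from which relative electron transport is
$rETR = Y \cdot E \cdot s$ with the PSII excitation fraction $s = 0.5$ by
default (equal allocation between photosystems; exposed as
`psii_fraction`). Dark-adapted yields give $F_v/F_m = (F_m - F_0)/F_m$, and
non-photochemical quenching is reported as $(F_m - F_m')/F_m$ by default.
The conventional Stern–Volmer form $(F_m - F_m')/F_m'$ is available via
`convention = "stern_volmer_prime"`; both conventions appear in field
practice, the ratio-of-dark-maximum form is the package default and each
result should state the convention used. Transient $F_m' > F_m$, common in
noisy field data, is clamped to zero quench with a logged warning rather
than propagated as negative NPQ.

`fit_rlc()` fits the Platt-type photoinhibition model
$$rETR(E) = P_s\left(1 - e^{-\alpha E/P_s}\right)e^{-\beta E/P_s},$$
with the Webb exponential ($\beta \equiv 0$) as an option. Two numerical
points deserve emphasis:

* **$rETR_{max}$ is the analytic maximum of the fitted curve over
  $E \ge 0$**, $P_s\,\frac{\alpha}{\alpha+\beta}
  \left(\frac{\beta}{\alpha+\beta}\right)^{\beta/\alpha}$, not the $P_s$
  parameter — the two differ whenever $\beta > 0$. $E_k = rETR_{max}/\alpha$
  is enforced as an identity at construction.
* The fit is a bounded Levenberg–Marquardt least-squares
  (`minpack.lm::nls.lm`, `ftol = ptol = 1e-15`) with a deterministic
  multistart (seven starts built from the low-light slope and the observed
  maximum) before non-convergence is declared; a failed fit is reported
  with `converged = FALSE`, never silently replaced. The dark step ($E=0$)
  is excluded from the objective: its rETR is identically zero and carries
  no slope information. We use `nls.lm` directly rather than an `nls`
  wrapper because a photoinhibition parameter converging to exactly zero
  breaks finite-difference gradients in the wrapper's post-fit machinery.

Glacier algal chloroplasts sit beneath vacuoles of phenolic pigment that
intercept most of the fluorometer's 660-nm actinic light. The shading
correction multiplies every step's $E$ by $(1-p)$, where $p$ is the
phenolic share of the cellular absorption cross-section at the actinic
wavelength (about 0.94 for phenolic-dominated cells). Because yields are
untouched, rETR rescales with $E$ and refitting gives exactly
$E_k' = (1-p)E_k$, $rETR_{max}' = (1-p)\,rETR_{max}$, with $\alpha$
invariant — a scaling law the test suite asserts to $10^{-6}$. The package
applies one uniform $p$ per analysis; whether $p$ should be re-derived per
sample is a data question the package leaves to the user (per-sample
fractions can simply be passed per curve).

## Pigment bio-optics

Spectral extinction coefficients come from the per-wavelength ordinary
least-squares slope of absorbance against concentration × path length,
through the origin because calibration spectra are blank-corrected (a free
intercept is available to detect blank drift, and negative slopes are
clamped to zero with a warning — absorption is physically non-negative).
The slope ($\mathrm{L\,g^{-1}\,cm^{-1}}$) converts to mass-specific
absorption by $1\ \mathrm{L\,g^{-1}\,cm^{-1}} = 10^{-4}\
\mathrm{m^2\,mg^{-1}}$. Whether the downstream transform should also carry
the decadic-to-natural-log factor $\ln 10$ depends on whether a decadic
absorbance slope is being used as an e-folding absorption coefficient; both
conventions are exposed (`extinction_to_mass_absorption(..., convention)`),
the decadic form is the default, and outputs should be labelled with the
convention used.

Single-cell absorption cross-sections are the content-weighted sum
$a(\lambda) = \sum_i a_i(\lambda) C_i$ (m² cell⁻¹): the virtual area of a
completely opaque object blocking the same radiation. All spectra are
resampled linearly onto the canonical 1-nm grid over the intersection of
their ranges; extrapolation is an error, so joint computations with
irradiance (280–750 nm) and extract spectra (250–750 nm) use 280–750. All
carotenoids are treated as photoprotective by default (the `psc` class is
supported but carries zero content in the default profile). No packaging
correction is applied at this stage — that belongs to the energy budget,
where an availability bound exists.

## Cellular energy budget, radiative forcing and melt

Photon–energy conversion uses exact CODATA constants:
$1\ \mathrm{W\,m^{-2}\,nm^{-1}}$ at $\lambda$ nm is
$\lambda \cdot 10^{-9} / (h c N_A) \cdot 10^{6}$ µmol photons m⁻² s⁻¹ nm⁻¹.
Absorbed flux per class is $a_i(\lambda)C_i \times E_{photon}(\lambda)
\times 10^9$ fmol photons cell⁻¹ s⁻¹ nm⁻¹. The light geometrically
available to a benthic filamentous cell is the incident flux times half the
lateral surface area of a cylinder, $\pi w \ell / 2$ (the mean cell,
29.60 × 12.04 µm, gives $5.598 \times 10^{-10}$ m²); a rectangular
$\ell \times w$ alternative is configurable since the true interception
geometry is not known.

Extract-based mass-specific coefficients ignore self-shading of densely
packed pigments, so reconstructed absorption can exceed what reaches the
cell. The **packaging correction** clips, at each wavelength where
$\sum_i \mathrm{absorbed}_i > \mathrm{available}$, all class contributions
by the common factor available/total (proportional allocation). The
alternative `"phenolics_last"` allocation preserves photosynthetic-pigment
absorption and truncates the screening pigment first; proportional is the
default because nothing in the underlying physics distinguishes the classes
at the point of clipping. Conservation (absorbed ≤ available everywhere;
class fractions plus unabsorbed summing to 1) is asserted on 1000 random
budgets in the tests.

Instantaneous radiative forcing multiplies per-cell absorbed *power*
(chlorophyll classes excluded — light used for photochemistry is not
dissipated as heat) by abundance, by a volume-to-area factor, and by
3600 s h⁻¹. The volume-to-area factor maps cells per mL of melted sample to
cells per m² of surface; it is **required, never defaulted silently**,
because it encodes the sampled ice depth. `vol_to_area_factor(depth_cm = 2,
density_ratio = 0.9)` documents the package's reference choice
(2-cm sampling depth, ice/water density 0.9): $2 \times 10^4 \times 0.9 =
18000$ mL m⁻². Hourly melt is
$\int \mathrm{IRF}\,d\lambda / (10^4 \cdot 334\ \mathrm{J\,cm^{-3}})$ cm
w.e.; one hour of 927.78 W m⁻² integrated forcing is exactly 1 cm w.e., a
unit identity the tests hold to $10^{-6}$. Melt is exactly linear in
abundance, so category statistics (mean, SD, SE = SD/√n across all measured
abundances) are computed per abundance and summarised.

## Threshold-gated logistic bloom model

Daily biomass in surface ice follows
$$B_{t+1} = B_t + f_t\,\mu B_t\left(1 - B_t/K\right) - d\,B_t,$$
where $f_t$ is the fraction of the day's 24 hours in which all three
environmental prerequisites hold — snow-free surface ($SH < 2$ cm), light
sufficient for photochemistry ($SWD > 10$ W m⁻²), and liquid water present
($TT > 0.5$ °C) — and $d = 0.10$ d⁻¹ is a fixed loss for mortality and
physical removal. Design choices:

* **Strict inequalities** at all three thresholds; boundary-equal hours are
  non-productive. The tests verify this exhaustively on a 24-hour truth
  table.
* Growth and loss are applied **simultaneously** within one Euler day-step,
  not sequentially — the order changes results at $O(\mu d)$, so it is
  fixed and documented. Loss applies every day, productive or not.
* "Net growth only when growth exceeds losses" is read as ordinary signed
  arithmetic; a `hard_gate` flag provides the alternative reading (zeroing
  any day whose gated growth does not exceed losses).
* $\mu$, $K$ and $B_0$ are **configuration parameters** (defaults 0.6 d⁻¹,
  20000 ng DW mL⁻¹, 100 ng DW mL⁻¹): incubation-derived productivity fits
  are site data, not package constants. `fit_logistic_growth()` estimates
  $(\mu, K)$ from a user-supplied biomass/net-productivity table, and the
  defaults were chosen once as realistic for ablation-zone blooms whose
  late-season standing stocks span roughly $10^2$–$10^4$ ng DW mL⁻¹.
  Because $B_0$ only sets the delay before the sigmoid rise (decay is
  $B_0(1-d)^t$ under snow), trajectories are insensitive to it within an
  order of magnitude; a `b_min` refuge floor (default 0) prevents numerical
  extinction under very long snow cover if desired.

Under constant gating the step has the fixed point
$B^* = K\left(1 - d/(f\mu)\right)$ for $f\mu > d$ (else extinction), which
`equilibrium_biomass()` returns in closed form and long-run iteration
matches to $10^{-6}$. The observed, site-dependent "carrying capacity" of a
bloom is this forcing-dependent equilibrium, not $K$ itself — sites with
fewer productive hours equilibrate lower.

## Two-stream albedo of a loaded ice column

The solver treats a plane-parallel stack of homogeneous layers under
diffuse incidence. Per layer and wavelength, the optical depth is
$\tau = k_{ext}\,\rho\,\Delta z$; after delta-Eddington scaling
($f = g^2$), the hemispheric-mean two-stream coefficients
$\gamma_1 = 2 - \omega(1+g)$, $\gamma_2 = \omega(1-g)$ give the analytic
diffuse reflectance and transmittance of each layer, and layers are
combined upward from the underlying boundary albedo by the standard adding
equations. The conservative-scattering limit ($\omega = 1$) is handled by
its own closed form rather than a numerically fragile $\lambda \to 0$
limit. Direct-beam incidence is not modelled: the intended incident spectra
are diffuse-weighted daily irradiance, and the visible broadband albedo is
the incident-weighted mean over 350–700 nm at 10-nm resolution.

The reference column is five layers — 1 mm on top of four 1-cm layers,
densities 400/400/500/800/800 kg m⁻³, grain lengths
1000/3000/5000/6000/8000 µm — over a flat underlying surface of albedo
0.25. Generation of ice-grain single-scattering properties from geometric
optics is out of scope; `default_ice_column()` ships a **synthetic**
parameterization (mass extinction $3/(\rho_{ice} r_{eff})$, a
grain-size-scaled co-albedo growing toward the red, $g = 0.89$) whose only
role is to make the solver fully testable offline, and user-supplied
per-layer $\omega$, $g$, $k_{ext}$ are the intended input.

Algae enter the top layer as **pure absorption** (their cross-sections were
derived as absorption; a scattering add-on is available by flag). The
mapping from a biomass load in ng DW mL⁻¹ to layer absorption is not
uniquely defined by the measurement conventions, so the package makes one
documented, configurable choice: the load is converted to a column mass per
m² through the same volume-to-area factor used for IRF and placed entirely
in the 1-mm surface layer, consistent with blooms concentrating at the
weathered surface. Scattering is left unchanged, so the layer's
single-scattering albedo strictly decreases wherever algae absorb, and
broadband albedo is non-increasing in load — both asserted in tests. Cell
mass per size class uses cylinder biovolume times a dry-weight density
(default $2.6\times 10^{-4}$ ng µm⁻³, a literature-scale dry-mass density
for green microalgae; configurable, as the published conversion is not a
package constant).

The solver is verified three ways: exact limits (transparent column returns
the underlying albedo to $10^{-9}$; a thick conservative scatterer returns
albedo ≥ 0.999; black substrate under transparent layers returns 0), and an
**independent adding–doubling oracle** in the test suite that rebuilds each
layer's reflectance by doubling from a second-order-accurate infinitesimal
sublayer — agreement is required to $10^{-6}$ on random ≤3-layer columns at
every wavelength.

## What the synthetic generators emulate — and what they do not

* `gen_rlc()` forward-simulates the Platt model through the yield algebra
  ($Y = rETR/(sE)$, $F = F_m'(1-Y)$, an NPQ-like decline of $F_m'$ with E)
  with multiplicative noise, nine steps spanning 0–4000 µmol photons
  m⁻² s⁻¹. Because $Y \le 1$, the generating $\alpha$ cannot exceed the
  PSII fraction $s$; simulating steeper initial slopes requires raising $s$
  identically in generator and fit, where it cancels exactly.
* `gen_calibration()` draws 53 abundances log-uniform over
  187–$2.1\times10^4$ cells mL⁻¹, ties concentration to abundance through
  the 0.041 ng cell⁻¹ phenolic content, and applies multiplicative
  absorbance noise.
* `gen_phenolic_spectrum()` is a sum-of-Gaussians template with the UV-B
  maximum at 300 nm, a 335-nm shoulder, and a visible tail decreasing to
  the red, amplitude-scaled by inverse design so phenolics contribute
  exactly the configured fraction (default 0.94) of the default cell's
  cross-section at 660 nm. The companion chlorophyll/carotenoid spectra are
  smooth synthetic stand-ins at plausible magnitudes — no digitized
  published values, and no test depends on their exact shapes.
* `gen_irradiance_day()` is solar-elevation geometry times a 5778-K
  blackbody shape with a UV cutoff, normalized so the noon photon integral
  equals a configurable peak (default 1700 µmol photons m⁻² s⁻¹, clear-sky
  midsummer at 67° N). It is not an atmospheric radiative-transfer model:
  no airmass-dependent spectral shifts, aerosols or clouds.
* `gen_forcing_season()` produces an ablation season (defaults 1 June –
  1 September, snow-free 25 June) with snow depth strictly above the 2-cm
  threshold until clearance, a diurnal shortwave cycle, and a temperature
  series crossing 0.5 °C in midsummer. It emulates the *statistical
  structure* a regional climate model provides, not its physics.
* `gen_abundances()` draws from zero-truncated lognormals moment-matched to
  the field categories (low 186 ± 276, n = 27; medium 3711 ± 2333, n = 34;
  high 8989 ± 4773, n = 103 cells mL⁻¹) — a skewed law is required because
  the SDs approach or exceed the means.

Passing tests on these inputs demonstrates that the *chain of computations*
is correct (parameter recovery, scaling laws, conservation, analytic fixed
points, solver limits); it does not validate the synthetic spectra against
measured optical properties, reproduce field melt magnitudes (which depend
on measured absorption spectra and true atmospheric irradiance), or
calibrate the bloom parameters against observed populations.

## Problem sizes and runtime choices

The default test and acceptance workloads are sized for a single CPU:
nine-step RLCs with 100-replicate noise studies, 53-sample calibrations,
1000-budget conservation sweeps, 500-day equilibrium iterations, a 93-day
season at hourly forcing resolution, and 10-nm albedo grids with 20-point
load sweeps. The full pipeline (`run_pipeline()`) completes in seconds and
is bit-reproducible: all randomness flows through explicit seeds, and the
run manifest records an MD5 hash per output table.

## Known limitations

* The energy budget assumes 100% down-welling irradiance on a benthic cell
  and ignores subsurface light-field geometry.
* No nutrient, hydrological or grazing dynamics in the bloom model; no
  inter-annual carry-over of biomass.
* The two-stream solver is diffuse-only and consumes supplied (or
  synthetic) layer optical properties; it does not generate geometric-optics
  single-scattering properties or model the near-IR.
* The packaging correction is an energy-conservation clip, not a physical
  packaging model; it bounds but does not resolve intracellular
  self-shading.
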