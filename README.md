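# bioalbedo

Heavily pigmented "glacier algae" bloom in the upper centimeters of bare
ablation-zone ice, where their purpurogallin-type phenolic pigmentation
absorbs UV and visible light, shades the chloroplasts beneath it, dissipates
the captured energy as heat, and darkens the ice surface enough to matter
for surface mass balance. `bioalbedo` implements the quantitative chain that
links these processes, for researchers in cryosphere microbial ecology and
ice-surface energy balance:

1. **Photophysiology** — rapid light curves (RLCs) from PAM fluorometry are
   fitted with the Platt-type photoinhibition model
   `rETR(E) = Ps (1 − e^(−αE/Ps)) e^(−βE/Ps)` (Webb exponential available),
   reporting `α`, `rETRmax` (the analytic curve maximum), `β`, and
   `Ek = rETRmax/α`. A shading correction `E′ = E (1 − p)` converts
   whole-cell to chloroplast-level light response, where `p` is the phenolic
   share of the cellular absorption cross-section at the actinic wavelength.
2. **Bio-optics** — spectral extinction coefficients from the slope of
   absorbance vs concentration (`e = A/lc`), conversion to mass-specific
   absorption (m² mg⁻¹), and single-cell absorption cross-sections
   `a(λ) = Σᵢ aᵢ(λ) Cᵢ` over pigment classes.
3. **Energy budget** — per-cell absorbed vs geometrically available photon
   flux (half the lateral area of a cylindrical cell), an empirical
   packaging correction clipping absorption to availability, and capture
   fractions per pigment class.
4. **Radiative forcing and melt** — population absorption
   `IRF(λ) = P_cell(λ) · N · f_{V→A} · 3600` (chlorophyll absorption
   excluded: light used for photochemistry is not heat), and meltwater
   `melt = ∫IRF dλ / (10⁴ · 334 J cm⁻³)` in cm w.e.
5. **Bloom model** — daily biomass `B' = B + f·µB(1−B/K) − 0.1·B`, gated by
   the fraction `f` of hours with snow depth < 2 cm, shortwave > 10 W m⁻²,
   and air temperature > 0.5 °C.
6. **Albedo** — a multilayer delta-Eddington two-stream solver for a
   five-layer weathered-ice column (underlying albedo 0.25) with the bloom
   loaded into the 1-mm top layer, integrated to visible (350–700 nm)
   broadband albedo.

A seeded synthetic-data module (`gen_*`) generates every input the chain
consumes — RLC fluorescence records, calibration sets, phenolic-dominated
spectra, diel clear-sky irradiance, seasonal hourly forcing, and abundance
categories — so the full pipeline runs with no external data.

## Worked example

```r
library(bioalbedo)

## a whole-cell rapid light curve and its fit
curve <- gen_rlc(alpha = 0.3, ek = 938, noise_cv = 0, seed = 1)[[1]]
fit_rlc(curve)
#> <rlc_fit> platt_photoinhibition: alpha = 0.3, rETRmax = 281.4, beta = 0, Ek = 938 (rss 3.06e-25)

## the phenolic share of the cellular cross-section at the 660-nm actinic
## wavelength, and the chloroplast-level refit after shading correction
cs <- reconstruct_cross_section(default_pigment_profile(),
        c(list(gen_phenolic_spectrum()), unname(default_pigment_spectra())))
p <- class_fraction_at(cs, "phenolic", 660)   # 0.94
fit_rlc(apply_shading_correction(curve, p))
#> <rlc_fit> platt_photoinhibition: alpha = 0.3, rETRmax = 16.88, beta = 0, Ek = 56.28 (rss 1.17e-27)

## daily melt from a high-abundance bloom patch over a diel cycle
diel_melt(cs, cell_geometry(), gen_irradiance_day(),
          gen_abundances("high", seed = 1), vol_to_area_factor())
#> <melt_result> daily melt 0.3519 cm w.e. d-1 (sd 0.163, n 103)
```

The whole-cell curve saturates near `Ek ≈ 938` µmol photons m⁻² s⁻¹; once
the 94% phenolic interception is removed, the chloroplasts turn out to be
low-light adapted (`Ek ≈ 56`) — the shading pigment, not the photosystem,
tolerates the ice-surface light regime. The melt result is the mean daily
meltwater equivalent across the 103 abundances of the high-biomass category.

`run_pipeline(default_config(seed = 1), out_dir)` chains every stage —
synthetic inputs, fits, cross-sections, diel melt, the seasonal bloom
trajectory, and daily visible broadband albedo — writing CSV tables and a
content-hashed manifest; reruns with the same config are bit-identical.

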