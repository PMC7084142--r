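## Cellular energy budget: per-cell spectral absorption vs geometric light
## availability, empirical packaging correction, and conversion of population
## absorption to instantaneous radiative forcing (IRF) and melt.

#' Convert spectral irradiance between energy and photon units
#'
#' `photons = E_W * lambda * 1e-9 / (h c N_A) * 1e6` converts
#' W m-2 nm-1 to µmol photons m-2 s-1 nm-1 using CODATA constants;
#' [energy_from_photons()] is the exact inverse.
#'
#' @param E_W Spectral irradiance, W m-2 nm-1 (>= 0).
#' @param lambda Wavelength, nm (> 0); recycled against `E_W`.
#' @return µmol photons m-2 s-1 nm-1.
#' @export
#' @examples
#' photons_from_energy(1, 550)  # about 4.598
photons_from_energy <- function(E_W, lambda) {
  if (any(lambda <= 0))
    stop_bioalbedo("lambda must be positive", "bioalbedo_domain_error")
  E_W * lambda * 1e-9 / (PLANCK_H * LIGHT_C * AVOGADRO) * 1e6
}

#' @rdname photons_from_energy
#' @param photons µmol photons m-2 s-1 nm-1.
#' @export
energy_from_photons <- function(photons, lambda) {
  if (any(lambda <= 0))
    stop_bioalbedo("lambda must be positive", "bioalbedo_domain_error")
  photons * (PLANCK_H * LIGHT_C * AVOGADRO) / (lambda * 1e-9) / 1e6
}

#' Spectral irradiance at one time point
#'
#' Stores the energy representation and caches the photon representation;
#' the two are kept consistent by construction.
#'
#' @param wavelengths Strictly increasing grid, nm.
#' @param irradiance_W Spectral irradiance, W m-2 nm-1 (>= 0).
#' @param timestamp Optional POSIXct / label for the hour slot.
#' @return A `spectral_irradiance`.
#' @export
spectral_irradiance <- function(wavelengths, irradiance_W, timestamp = NULL) {
  stopifnot(length(wavelengths) == length(irradiance_W))
  if (any(diff(wavelengths) <= 0))
    stop_bioalbedo("wavelength grid must be strictly increasing",
                   "bioalbedo_domain_error")
  if (any(irradiance_W < 0))
    stop_bioalbedo("irradiance must be non-negative", "bioalbedo_domain_error")
  structure(list(timestamp = timestamp, wavelengths = wavelengths,
                 irradiance_W = irradiance_W,
                 irradiance_photons = photons_from_energy(irradiance_W,
                                                          wavelengths)),
            class = "spectral_irradiance")
}

#' Cell geometry for the available-light calculation
#'
#' Filamentous cells are approximated as cylinders; a benthic cell absorbs
#' incoming light over half its lateral surface,
#' `half_lateral_area = pi * width * length / 2` (converted from µm2 to m2).
#' `shape = "rectangle"` uses `length * width` instead.
#'
#' @param length_um,width_um Cell length and width, µm (> 0). Defaults are
#'   the mean dimensions of an average-sized *Ancylonema nordenskioeldii*
#'   cell (29.60 x 12.04 µm).
#' @param shape `"cylinder"` (default) or `"rectangle"`.
#' @return A `cell_geometry` with `half_lateral_area_m2`.
#' @export
cell_geometry <- function(length_um = 29.60, width_um = 12.04,
                          shape = c("cylinder", "rectangle")) {
  shape <- match.arg(shape)
  if (length_um <= 0 || width_um <= 0)
    stop_bioalbedo("cell dimensions must be positive", "bioalbedo_domain_error")
  area_um2 <- if (shape == "cylinder") pi * width_um * length_um / 2
              else length_um * width_um
  structure(list(length_um = length_um, width_um = width_um, shape = shape,
                 half_lateral_area_m2 = area_um2 * 1e-12),
            class = "cell_geometry")
}

#' @noRd
intersect_grid <- function(wl_a, wl_b) {
  wl <- intersect(wl_a, wl_b)
  if (length(wl) < 2)
    stop_bioalbedo("wavelength grids have no usable intersection",
                   "bioalbedo_grid_error")
  sort(wl)
}

#' Per-class photon absorption of a single cell
#'
#' Multiplies each pigment class's cross-section contribution
#' (m2 cell-1 nm-1) by the incident photon irradiance
#' (µmol photons m-2 s-1 nm-1) and scales by 1e9 to femtomoles:
#' fmol photons cell-1 s-1 nm-1. Grids are intersected.
#'
#' @param cross_section A `cell_cross_section`.
#' @param irr A [spectral_irradiance()].
#' @return List with `wavelengths` and `absorbed` (matrix, fmol, one column
#'   per class).
#' @export
absorbed_per_cell <- function(cross_section, irr) {
  wl <- intersect_grid(cross_section$wavelengths, irr$wavelengths)
  a <- cross_section$by_class[match(wl, cross_section$wavelengths), ,
                              drop = FALSE]
  ph <- irr$irradiance_photons[match(wl, irr$wavelengths)]
  list(wavelengths = wl, absorbed = a * ph * 1e9)
}

#' Photon flux geometrically available to a single cell
#'
#' Incident photon irradiance times half the cell's lateral surface area:
#' fmol photons cell-1 s-1 nm-1.
#'
#' @param geometry A [cell_geometry()].
#' @param irr A [spectral_irradiance()].
#' @return List with `wavelengths` and `available` (fmol vector).
#' @export
available_per_cell <- function(geometry, irr) {
  stopifnot(inherits(geometry, "cell_geometry"))
  list(wavelengths = irr$wavelengths,
       available = irr$irradiance_photons * geometry$half_lateral_area_m2 * 1e9)
}

#' Assemble a cellular energy budget
#'
#' Computes per-class absorbed and geometrically available photon fluxes on
#' the common wavelength grid and (by default) applies the packaging
#' correction so absorption never exceeds availability. Summary fractions
#' are spectrally integrated shares of the available flux per class plus the
#' unabsorbed remainder.
#'
#' @param cross_section A `cell_cross_section`.
#' @param geometry A [cell_geometry()].
#' @param irr A [spectral_irradiance()].
#' @param correct_packaging Apply [packaging_correction()]? Default `TRUE`.
#' @return An `energy_budget` with `wavelengths`, `absorbed` (fmol matrix),
#'   `available` (fmol), `clipped` (logical per wavelength), `fractions`.
#' @export
energy_budget <- function(cross_section, geometry, irr,
                          correct_packaging = TRUE) {
  ab <- absorbed_per_cell(cross_section, irr)
  av <- available_per_cell(geometry, irr)
  avail <- av$available[match(ab$wavelengths, av$wavelengths)]
  budget <- structure(list(wavelengths = ab$wavelengths,
                           absorbed = ab$absorbed, available = avail,
                           clipped = rep(FALSE, length(avail)),
                           irradiance_photons =
                             irr$irradiance_photons[match(ab$wavelengths,
                                                          irr$wavelengths)]),
                      class = "energy_budget")
  if (correct_packaging) budget <- packaging_correction(budget)
  budget$fractions <- budget_fractions(budget)
  budget
}

#' Empirical pigment-packaging correction
#'
#' Where the reconstructed per-cell absorption exceeds the light
#' geometrically available to the cell (self-shading of densely packed
#' pigments is not captured by extract-based mass-specific coefficients),
#' absorption is reduced to the available irradiance. All class
#' contributions at a clipped wavelength are rescaled by the common factor
#' `available / total_absorbed` (proportional allocation);
#' `allocation = "phenolics_last"` instead truncates the phenolic
#' contribution first, preserving photosynthetic-pigment absorption.
#'
#' @param budget An `energy_budget`.
#' @param allocation `"proportional"` (default) or `"phenolics_last"`.
#' @return The corrected `energy_budget` with `clipped` flags set.
#' @export
packaging_correction <- function(budget,
                                 allocation = c("proportional",
                                                "phenolics_last")) {
  allocation <- match.arg(allocation)
  if (any(budget$absorbed < 0) || any(budget$available < 0))
    stop_bioalbedo("negative absorption or availability",
                   "bioalbedo_domain_error")
  tot <- rowSums(budget$absorbed)
  over <- tot > budget$available
  if (any(over)) {
    if (allocation == "proportional") {
      f <- budget$available[over] / tot[over]
      budget$absorbed[over, ] <- budget$absorbed[over, , drop = FALSE] * f
    } else {
      ab <- budget$absorbed[over, , drop = FALSE]
      other <- setdiff(colnames(ab), "phenolic")
      other_tot <- rowSums(ab[, other, drop = FALSE])
      ## phenolics take only what is left after the photosynthetic classes
      ab[, "phenolic"] <- pmax(budget$available[over] - other_tot, 0)
      scl <- ifelse(other_tot > budget$available[over],
                    budget$available[over] / other_tot, 1)
      ab[, other] <- ab[, other, drop = FALSE] * scl
      budget$absorbed[over, ] <- ab
    }
    budget$clipped <- budget$clipped | over
  }
  budget
}

#' Spectrally integrated capture fractions of an energy budget
#'
#' @param budget An `energy_budget`.
#' @return Named vector: one fraction of the available flux per pigment
#'   class plus `unabsorbed`; entries sum to 1 for a corrected budget.
#' @export
budget_fractions <- function(budget) {
  wl <- budget$wavelengths
  total_av <- pracma::trapz(wl, budget$available)
  fr <- apply(budget$absorbed, 2, function(a) pracma::trapz(wl, a)) / total_av
  c(fr, unabsorbed = pracma::trapz(
    wl, budget$available - rowSums(budget$absorbed)) / total_av)
}

#' Per-cell absorbed power spectrum for radiative forcing
#'
#' Converts the budget's absorbed photon fluxes to energy units and sums the
#' included classes: W cell-1 nm-1. The chlorophyll classes are excluded by
#' default because light used for photochemistry is not dissipated as heat.
#'
#' @param budget An `energy_budget`.
#' @param exclude_classes Classes to exclude (default `c("chl_a", "chl_b")`).
#' @return List with `wavelengths` and `power_W` (W cell-1 nm-1).
#' @export
per_cell_power <- function(budget, exclude_classes = c("chl_a", "chl_b")) {
  keep <- setdiff(colnames(budget$absorbed), exclude_classes)
  fmol <- rowSums(budget$absorbed[, keep, drop = FALSE])
  umol <- fmol * 1e-9
  list(wavelengths = budget$wavelengths,
       power_W = energy_from_photons(umol, budget$wavelengths))
}

#' Volume-to-area conversion factor for surface-ice samples
#'
#' Abundances are measured per mL of melted surface ice sampled to a fixed
#' depth; the factor maps cells mL-1 to cells m-2 of ice surface:
#' `depth_cm * 1e4 cm2 m-2 * ice/water density ratio` (mL m-2).
#'
#' @param depth_cm Sampled ice depth, cm (default 2).
#' @param density_ratio Ice/water density ratio (default 0.9).
#' @return mL m-2.
#' @export
#' @examples
#' vol_to_area_factor()  # 18000
vol_to_area_factor <- function(depth_cm = 2, density_ratio = 0.9) {
  if (depth_cm <= 0 || density_ratio <= 0)
    stop_bioalbedo("depth and density ratio must be positive",
                   "bioalbedo_domain_error")
  depth_cm * CM2_PER_M2 * density_ratio
}

#' Instantaneous radiative forcing of an algal population
#'
#' `IRF(lambda) = per-cell power * abundance * vol_to_area * 3600`
#' in W m-2 h-1 nm-1 (the 3600 accumulates one hour of absorption).
#'
#' @param power_W Per-cell absorbed power, W cell-1 nm-1 (packaging-corrected
#'   and minus the chlorophyll classes; see [per_cell_power()]).
#' @param abundance Cells mL-1 (>= 0).
#' @param vol_to_area mL m-2 conversion (required; see
#'   [vol_to_area_factor()]).
#' @return IRF spectrum, W m-2 h-1 nm-1 (same length as `power_W`).
#' @export
irf_per_m2 <- function(power_W, abundance, vol_to_area) {
  if (missing(vol_to_area) || is.null(vol_to_area))
    stop_bioalbedo("vol_to_area must be supplied explicitly (mL m-2)",
                   "bioalbedo_missing_config")
  if (any(abundance < 0))
    stop_bioalbedo("abundance must be non-negative", "bioalbedo_domain_error")
  if (vol_to_area <= 0)
    stop_bioalbedo("vol_to_area must be positive", "bioalbedo_domain_error")
  power_W * abundance * vol_to_area * 3600
}

#' Convert an IRF spectrum to hourly melt
#'
#' `melt = integral(IRF dlambda) / (1e4 * 334)`: the spectrally integrated
#' hourly energy (J m-2) divided by cm2-per-m2 scaling and the latent heat
#' of fusion of ice (334 J cm-3), giving cm water equivalent per hour.
#'
#' @param wavelengths nm grid.
#' @param irf IRF spectrum, W m-2 h-1 nm-1.
#' @param lambda_range Integration window, nm (default `c(280, 750)`).
#' @return Hourly melt, cm w.e.
#' @export
melt_from_irf <- function(wavelengths, irf, lambda_range = c(280, 750)) {
  if (lambda_range[1] > lambda_range[2])
    stop_bioalbedo("inverted wavelength range", "bioalbedo_domain_error")
  keep <- wavelengths >= lambda_range[1] & wavelengths <= lambda_range[2]
  if (sum(keep) < 2) return(0)
  pracma::trapz(wavelengths[keep], irf[keep]) /
    (CM2_PER_M2 * LATENT_HEAT_FUSION)
}

#' Abundance sample for one biomass category
#'
#' @param category `"low"`, `"medium"` or `"high"`.
#' @param abundances Cells mL-1, all > 0.
#' @return An `abundance_sample` with `n = length(abundances)`.
#' @export
abundance_sample <- function(category = c("low", "medium", "high"),
                             abundances) {
  category <- match.arg(category)
  if (any(abundances <= 0))
    stop_bioalbedo("abundances must be positive", "bioalbedo_domain_error")
  structure(list(category = category, abundances = abundances,
                 n = length(abundances)),
            class = "abundance_sample")
}

#' Diel melt generation for an abundance category
#'
#' Runs the full chain — energy budget with packaging correction, exclusion
#' of chlorophyll absorption, IRF, hourly melt — for each of 24 hourly
#' spectra, then evaluates daily melt for every abundance in the sample
#' (melt is exactly linear in abundance) and summarises mean, SD and
#' SE = SD/sqrt(n) across the category.
#'
#' @param cross_section A `cell_cross_section`.
#' @param geometry A [cell_geometry()].
#' @param irradiance_series List of exactly 24 [spectral_irradiance()]
#'   objects (hours 0-23).
#' @param abundance An [abundance_sample()] or numeric vector of cells mL-1.
#' @param vol_to_area mL m-2 (required).
#' @param exclude_classes Pigment classes excluded from IRF.
#' @param lambda_range Melt integration window, nm.
#' @return A `melt_result`: `hourly` data.frame (hour, `irf_W_m2` spectrally
#'   integrated at the mean abundance, `melt_cm_we`), `daily_melt` per
#'   abundance, `mean`, `sd`, `se` (cm w.e. d-1), and the constants used.
#' @export
diel_melt <- function(cross_section, geometry, irradiance_series, abundance,
                      vol_to_area, exclude_classes = c("chl_a", "chl_b"),
                      lambda_range = c(280, 750)) {
  if (length(irradiance_series) != 24)
    stop_bioalbedo("irradiance_series must contain exactly 24 hourly spectra",
                   "bioalbedo_missing_hours")
  if (missing(vol_to_area) || is.null(vol_to_area))
    stop_bioalbedo("vol_to_area must be supplied explicitly (mL m-2)",
                   "bioalbedo_missing_config")
  ab <- if (inherits(abundance, "abundance_sample")) abundance$abundances
        else abundance
  if (length(ab) < 1)
    stop_bioalbedo("at least one abundance is required",
                   "bioalbedo_domain_error")
  ## melt and IRF per unit abundance, hour by hour (linearity in abundance)
  unit_irf <- numeric(24); unit_melt <- numeric(24)
  for (h in seq_len(24)) {
    b <- energy_budget(cross_section, geometry, irradiance_series[[h]])
    pw <- per_cell_power(b, exclude_classes = exclude_classes)
    irf1 <- irf_per_m2(pw$power_W, 1, vol_to_area)
    keep <- pw$wavelengths >= lambda_range[1] & pw$wavelengths <= lambda_range[2]
    unit_irf[h] <- if (sum(keep) < 2) 0 else
      pracma::trapz(pw$wavelengths[keep], irf1[keep]) / 3600  # back to W m-2
    unit_melt[h] <- melt_from_irf(pw$wavelengths, irf1, lambda_range)
  }
  mean_ab <- mean(ab)
  daily <- sum(unit_melt) * ab
  n <- length(ab)
  s <- if (n > 1) stats::sd(daily) else NA_real_
  structure(list(
    hourly = data.frame(hour = 0:23, irf_W_m2 = unit_irf * mean_ab,
                        melt_cm_we = unit_melt * mean_ab),
    daily_melt = daily, abundances = ab,
    mean = mean(daily), sd = s, se = if (n > 1) s / sqrt(n) else NA_real_,
    n = n,
    constants = c(latent_heat_J_cm3 = LATENT_HEAT_FUSION,
                  area_scale_cm2_m2 = CM2_PER_M2,
                  vol_to_area_mL_m2 = vol_to_area)),
    class = "melt_result")
}

#' @export
print.melt_result <- function(x, ...) {
  cat(sprintf("<melt_result> daily melt %.4g cm w.e. d-1 (sd %.3g, n %d)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}
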