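## Multilayer delta-Eddington two-stream albedo of an ice column containing
## glacier-algal impurities. Per-layer single-scattering properties are
## inputs; geometric-optics property generation is out of scope, and
## default_ice_column() ships a synthetic, documented parameterization so the
## solver is fully testable offline.

#' Construct a layered ice column
#'
#' Layers are ordered top-down. Optical properties are per layer and per
#' wavelength: single-scattering albedo `ssa`, asymmetry parameter `asym`,
#' and mass extinction coefficient `k_ext` (m2 kg-1).
#'
#' @param thickness_m Layer thicknesses, m (> 0).
#' @param density_kg_m3 Layer densities, kg m-3 (> 0).
#' @param grain_um Effective ice grain lengths, µm.
#' @param wavelengths Wavelength grid, nm (strictly increasing).
#' @param ssa,asym,k_ext Matrices `n_layer x n_wavelength`; `0 <= ssa <= 1`,
#'   `-1 < asym < 1`, `k_ext >= 0`.
#' @param underlying_albedo Albedo of the flat surface beneath the column,
#'   in \[0, 1\] (default 0.25, solid glacier ice beneath the weathered
#'   layer).
#' @return An `ice_column`.
#' @export
ice_column <- function(thickness_m, density_kg_m3, grain_um, wavelengths,
                       ssa, asym, k_ext, underlying_albedo = 0.25) {
  n <- length(thickness_m)
  w <- length(wavelengths)
  ssa <- matrix(ssa, n, w); asym <- matrix(asym, n, w)
  k_ext <- matrix(k_ext, n, w)
  stopifnot(length(density_kg_m3) == n, length(grain_um) == n)
  if (any(thickness_m <= 0) || any(density_kg_m3 <= 0))
    stop_bioalbedo("thickness and density must be positive",
                   "bioalbedo_domain_error")
  if (any(diff(wavelengths) <= 0))
    stop_bioalbedo("wavelength grid must be strictly increasing",
                   "bioalbedo_domain_error")
  if (any(ssa < 0) || any(ssa > 1) || any(abs(asym) >= 1) || any(k_ext < 0))
    stop_bioalbedo("invalid optical properties (need 0<=ssa<=1, |g|<1, k_ext>=0)",
                   "bioalbedo_domain_error")
  if (any(!is.finite(ssa)) || any(!is.finite(asym)) || any(!is.finite(k_ext)))
    stop_bioalbedo("optical properties must be finite at every wavelength",
                   "bioalbedo_domain_error")
  if (underlying_albedo < 0 || underlying_albedo > 1)
    stop_bioalbedo("underlying_albedo must lie in [0, 1]",
                   "bioalbedo_domain_error")
  structure(list(thickness_m = thickness_m, density_kg_m3 = density_kg_m3,
                 grain_um = grain_um, wavelengths = wavelengths,
                 ssa = ssa, asym = asym, k_ext = k_ext,
                 underlying_albedo = underlying_albedo),
            class = "ice_column")
}

#' Synthetic five-layer weathered-ice column
#'
#' The standard bare-ice configuration: five layers (top layer 1 mm, then
#' four 1-cm layers), densities 400/400/500/800/800 kg m-3, grain lengths
#' 1000/3000/5000/6000/8000 µm, over a flat underlying surface of albedo
#' 0.25. The optical properties are a synthetic stand-in for
#' geometric-optics output: mass extinction `3/(rho_ice * r_eff)` for the
#' grain radius, a grain-size-scaled single-scattering co-albedo that grows
#' toward the red, and asymmetry `g = 0.89`.
#'
#' @param wavelengths Grid, nm (default 350-700 at 10 nm).
#' @return An `ice_column`.
#' @export
default_ice_column <- function(wavelengths = seq(350, 700, by = 10)) {
  thickness <- c(0.001, rep(0.01, 4))
  density <- c(400, 400, 500, 800, 800)
  grain <- c(1000, 3000, 5000, 6000, 8000)
  r_eff <- grain * 1e-6 / 2
  k_ext <- outer(3 / (917 * r_eff), rep(1, length(wavelengths)))
  co_albedo <- outer(grain / 1000,
                     1e-4 + 6e-3 * ((wavelengths - 350) / 350)^3)
  ssa <- 1 - co_albedo
  asym <- matrix(0.89, length(grain), length(wavelengths))
  ice_column(thickness, density, grain, wavelengths, ssa, asym, k_ext,
             underlying_albedo = 0.25)
}

#' Algal cell-size mixture for impurity loading
#'
#' Partitions a biomass load across cell-size classes. Mass weights come
#' from cylinder biovolume times the dry-weight conversion; the default
#' assemblage is 76% 20-µm, 15.5% 60-µm and 8.5% 120-µm cells, all 12 µm in
#' circular end diameter.
#'
#' @param fractions Assemblage number fractions, summing to 1.
#' @param lengths_um,diameters_um Cell dimensions per class, µm.
#' @param spectrum A [pigment_spectrum()]-like list (`wavelengths`,
#'   `mass_absorption` in m2 per mg dry weight) shared by the classes, or a
#'   list of one spectrum per class.
#' @param dw_per_um3 Dry weight per biovolume, ng µm-3 (default 2.6e-4).
#' @return An `algal_size_mix` with per-class cell masses (ng) and the
#'   mass-weighted absorption spectrum accessor.
#' @export
algal_size_mix <- function(fractions = c(0.76, 0.155, 0.085),
                           lengths_um = c(20, 60, 120),
                           diameters_um = c(12, 12, 12),
                           spectrum, dw_per_um3 = 2.6e-4) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop_bioalbedo("size-class fractions must sum to 1",
                   "bioalbedo_domain_error")
  stopifnot(length(fractions) == length(lengths_um),
            length(fractions) == length(diameters_um))
  mass_ng <- biovolume_to_dw(cell_biovolume(lengths_um, diameters_um),
                             dw_per_um3)
  spectra <- if (!is.null(spectrum$wavelengths))
    rep(list(spectrum), length(fractions)) else spectrum
  structure(list(fractions = fractions, lengths_um = lengths_um,
                 diameters_um = diameters_um, cell_mass_ng = mass_ng,
                 spectra = spectra, dw_per_um3 = dw_per_um3),
            class = "algal_size_mix")
}

#' Mass-weighted absorption spectrum of a size mixture
#'
#' @param mix An [algal_size_mix()].
#' @param wavelengths Target grid, nm.
#' @return m2 per mg dry weight at each wavelength.
#' @export
algal_mass_absorption <- function(mix, wavelengths) {
  w <- mix$fractions * mix$cell_mass_ng
  w <- w / sum(w)
  out <- numeric(length(wavelengths))
  for (i in seq_along(mix$spectra)) {
    s <- mix$spectra[[i]]
    out <- out + w[i] * resample_spectrum(s$wavelengths, s$mass_absorption,
                                          wavelengths)
  }
  out
}

#' Load an ice column's top layer with algal biomass
#'
#' The biomass load (ng DW per mL of sampled surface ice) is converted to a
#' column mass per m2 through the same volume-to-area factor used for IRF
#' (`mass_mg_m2 = load * vol_to_area * 1e-6`) and placed entirely in the
#' top layer as pure absorption (algal cross-sections were derived as
#' absorption; no scattering is added by default). The layer's mass
#' extinction and single-scattering albedo are adjusted consistently:
#' scattering is unchanged, so `ssa' = scat / (scat + abs)` strictly
#' decreases wherever the algae absorb.
#'
#' @param column An [ice_column()].
#' @param load ng DW mL-1 (>= 0).
#' @param mix An [algal_size_mix()].
#' @param vol_to_area mL m-2 (default [vol_to_area_factor()]).
#' @param add_scattering Optional scattering-to-absorption ratio for the
#'   algal particles (default 0: absorption only).
#' @return A new `ice_column`.
#' @export
add_algal_impurity <- function(column, load, mix,
                               vol_to_area = vol_to_area_factor(),
                               add_scattering = 0) {
  stopifnot(inherits(column, "ice_column"), inherits(mix, "algal_size_mix"))
  if (load < 0)
    stop_bioalbedo("load must be non-negative", "bioalbedo_domain_error")
  if (load == 0) return(column)
  a_mass <- algal_mass_absorption(mix, column$wavelengths)  # m2 mg-1
  mass_mg_m2 <- load * vol_to_area * 1e-6                   # ng -> mg
  tau_abs_add <- a_mass * mass_mg_m2
  dz <- column$thickness_m[1]; rho <- column$density_kg_m3[1]
  tau0 <- column$k_ext[1, ] * rho * dz
  tau_sca <- column$ssa[1, ] * tau0 + add_scattering * tau_abs_add
  tau_abs <- (1 - column$ssa[1, ]) * tau0 + tau_abs_add
  tau_new <- tau_sca + tau_abs
  column$k_ext[1, ] <- tau_new / (rho * dz)
  column$ssa[1, ] <- ifelse(tau_new > 0, tau_sca / tau_new, 1)
  column$algal_load <- load
  column
}

## Two-stream core ------------------------------------------------------------

## Delta-Eddington scaling of (tau, omega, g): similarity transform that
## folds the forward-scattering peak (f = g^2) into the direct beam.
#' @noRd
delta_scale <- function(tau, omega, g) {
  f <- g^2
  list(tau = (1 - omega * f) * tau,
       omega = (1 - f) * omega / (1 - omega * f),
       g = (g - f) / (1 - f))
}

## Diffuse reflectance and transmittance of one homogeneous layer under the
## hemispheric-mean two-stream approximation (gamma1 = 2 - omega(1+g),
## gamma2 = omega(1-g)), after delta-Eddington scaling. Vectorized over
## wavelength. The conservative-scattering limit is handled analytically.
#' @noRd
layer_rt <- function(tau, omega, g) {
  s <- delta_scale(tau, omega, g)
  g1 <- 2 - s$omega * (1 + s$g)
  g2 <- s$omega * (1 - s$g)
  R <- T_ <- numeric(length(tau))
  cons <- abs(g1 - g2) < 1e-12
  if (any(cons)) {
    gt <- g1[cons] * s$tau[cons]
    R[cons] <- gt / (1 + gt)
    T_[cons] <- 1 / (1 + gt)
  }
  if (any(!cons)) {
    i <- !cons
    lam <- sqrt((g1[i] - g2[i]) * (g1[i] + g2[i]))
    Gam <- g2[i] / (g1[i] + lam)
    e1 <- exp(-lam * s$tau[i])
    e2 <- e1^2
    den <- 1 - Gam^2 * e2
    R[i] <- Gam * (1 - e2) / den
    T_[i] <- (1 - Gam^2) * e1 / den
  }
  list(R = R, T = T_)
}

## Add a layer (R1, T1) on top of a reflecting system R_below.
#' @noRd
add_layer_above <- function(R1, T1, R_below) {
  R1 + T1^2 * R_below / (1 - R1 * R_below)
}

#' Solve the spectral albedo of an ice column
#'
#' Plane-parallel multilayer two-stream solution for diffuse incidence:
#' each layer's diffuse reflectance/transmittance comes from the analytic
#' hemispheric-mean two-stream solution after delta-Eddington scaling, and
#' layers are combined upward from the underlying boundary albedo. Per-layer
#' optical depth is `k_ext * density * thickness`.
#'
#' @param column An [ice_column()].
#' @param incident Optional [spectral_irradiance()] used to weight the
#'   visible broadband albedo.
#' @param bba_range Visible integration window for the BBA, nm.
#' @return An `albedo_result`: `wavelengths`, `albedo` (spectral), and
#'   `bba_visible` when `incident` is supplied.
#' @export
solve_albedo <- function(column, incident = NULL, bba_range = c(350, 700)) {
  stopifnot(inherits(column, "ice_column"))
  wl <- column$wavelengths
  R_below <- rep(column$underlying_albedo, length(wl))
  for (i in rev(seq_along(column$thickness_m))) {
    tau <- column$k_ext[i, ] * column$density_kg_m3[i] * column$thickness_m[i]
    rt <- layer_rt(tau, column$ssa[i, ], column$asym[i, ])
    R_below <- add_layer_above(rt$R, rt$T, R_below)
  }
  if (any(!is.finite(R_below)) || any(R_below < -1e-12) || any(R_below > 1 + 1e-12))
    stop_bioalbedo("two-stream solution left [0, 1]: check optical properties",
                   "bioalbedo_numerical_error")
  out <- structure(list(wavelengths = wl,
                        albedo = pmin(pmax(R_below, 0), 1)),
                   class = "albedo_result")
  if (!is.null(incident))
    out$bba_visible <- bba(wl, out$albedo,
                           resample_spectrum(incident$wavelengths,
                                             incident$irradiance_W, wl),
                           bba_range[1], bba_range[2])
  out
}

#' Broadband albedo over a spectral window
#'
#' Incident-spectrum-weighted mean of the spectral albedo:
#' `integral(albedo * E dlambda) / integral(E dlambda)`.
#'
#' @param wavelengths nm grid.
#' @param albedo Spectral albedo on the grid.
#' @param incident Incident spectral irradiance on the same grid (W m-2
#'   nm-1).
#' @param lambda_lo,lambda_hi Window, nm (default 350-700, visible).
#' @return Broadband albedo in \[min albedo, max albedo\].
#' @export
bba <- function(wavelengths, albedo, incident, lambda_lo = 350,
                lambda_hi = 700) {
  keep <- wavelengths >= lambda_lo & wavelengths <= lambda_hi
  if (sum(keep) < 2)
    stop_bioalbedo("fewer than 2 grid points in the BBA window",
                   "bioalbedo_domain_error")
  etot <- pracma::trapz(wavelengths[keep], incident[keep])
  if (etot <= 0)
    stop_bioalbedo("zero incident energy in the BBA window: BBA undefined",
                   "bioalbedo_undefined_bba")
  pracma::trapz(wavelengths[keep], albedo[keep] * incident[keep]) / etot
}
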