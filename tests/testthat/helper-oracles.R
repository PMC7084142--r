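## Independent oracles and small fixture builders used across the suite.

## Brute-force adding-doubling reflectance/transmittance of one homogeneous
## layer: start from a second-order-accurate infinitesimal sublayer of the
## delta-Eddington-scaled hemispheric-mean two-stream equations and double
## k times. Independent of the package's analytic layer solution.
oracle_layer_rt_doubling <- function(tau, omega, g, k = 24) {
  f <- g^2
  tau_s <- (1 - omega * f) * tau
  om_s <- (1 - f) * omega / (1 - omega * f)
  g_s <- (g - f) / (1 - f)
  g1 <- 2 - om_s * (1 + g_s)
  g2 <- om_s * (1 - g_s)
  dt <- tau_s / 2^k
  R <- g2 * dt * (1 - g1 * dt)
  Tt <- 1 - g1 * dt + (g1^2 + g2^2) * dt^2 / 2
  for (i in seq_len(k)) {
    den <- 1 - R^2
    Rn <- R + Tt^2 * R / den
    Tt <- Tt^2 / den
    R <- Rn
  }
  list(R = R, T = Tt)
}

## Adding-doubling albedo of a stack of layers over a reflecting boundary.
oracle_column_albedo <- function(taus, omegas, gs, underlying, k = 24) {
  Rb <- underlying
  for (i in rev(seq_along(taus))) {
    rt <- oracle_layer_rt_doubling(taus[i], omegas[i], gs[i], k)
    Rb <- rt$R + rt$T^2 * Rb / (1 - rt$R * Rb)
  }
  Rb
}

## Spectral irradiance with a flat photon flux (umol m-2 s-1 nm-1).
flat_photon_irradiance <- function(wavelengths, photons = 1) {
  spectral_irradiance(wavelengths,
                      energy_from_photons(rep(photons, length(wavelengths)),
                                          wavelengths))
}

## A flat single-class cross-section (m2 cell-1 at every wavelength).
flat_cross_section <- function(wavelengths, value, class = "phenolic") {
  reconstruct_cross_section(
    pigment_profile(stats::setNames(1, class)),
    list(pigment_spectrum(class, wavelengths,
                          rep(value, length(wavelengths)))),
    grid = wavelengths)
}

## Default whole-cell cross-section shared by several tests.
default_cross_section <- function() {
  prof <- default_pigment_profile()
  sp <- default_pigment_spectra()
  reconstruct_cross_section(prof,
                            c(list(gen_phenolic_spectrum(profile = prof,
                                                         spectra = sp)),
                              unname(sp)))
}

## 24 hours of permissive / hostile forcing for bloom tests.
permissive_day <- list(sh = rep(0, 24), swd = rep(300, 24), tt = rep(3, 24))
snowy_day <- list(sh = rep(5, 24), swd = rep(300, 24), tt = rep(3, 24))
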