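## Seeded generators for every input the analysis chain consumes: RLC
## fluorescence records, pigment calibration sets, phenolic-dominated
## absorption spectra, diel clear-sky spectral irradiance, an ablation-season
## hourly forcing series with snow retreat, and abundance categories.
## Spectral templates are smooth analytic forms (sums of Gaussians /
## blackbody shapes), never digitized figures; all randomness flows through
## an explicit seed and the caller's RNG state is restored.

BOLTZMANN_K <- 1.380649e-23  # J K-1

#' Default nine-step RLC light gradient (0 to 4000 µmol photons m-2 s-1)
#' @return Numeric vector of 9 incident PAR levels.
#' @export
default_rlc_steps <- function() {
  c(0, 60, 140, 300, 620, 1200, 2000, 3000, 4000)
}

#' Generate synthetic rapid light curves
#'
#' Forward-simulates the Platt-type light response with the requested
#' parameters, converts rETR back to PSII quantum efficiencies through
#' `Y = rETR / (E * psii_fraction)`, and emits fluorescence yields
#' consistent with those efficiencies (fixed instrument scale `Fm = 1000`,
#' an NPQ-like decline of `Fm'` with E). Multiplicative Gaussian noise of
#' coefficient `noise_cv` is applied to rETR before the yields are derived,
#' so refitting a noiseless curve recovers the generating parameters.
#'
#' Because `Y` is a yield ratio bounded by 1, the generating `alpha` must
#' not exceed `psii_fraction`; raise `psii_fraction` (in both the generator
#' and the fit, where it cancels exactly) to simulate steeper curves.
#'
#' @param n Number of replicate curves.
#' @param alpha Light-utilization efficiency (initial slope).
#' @param ek Light saturation coefficient, µmol photons m-2 s-1
#'   (`rETRmax = alpha * ek`).
#' @param beta Photoinhibition parameter (>= 0).
#' @param noise_cv Multiplicative noise CV (>= 0).
#' @param steps Incident PAR levels (first may be 0, the dark step).
#' @param psii_fraction PSII excitation fraction (default 0.5).
#' @param fvfm Dark-adapted Fv/Fm encoded in the dark yields.
#' @param seed RNG seed.
#' @return A list of [rlc_curve()] objects.
#' @export
gen_rlc <- function(n = 1, alpha = 0.3, ek = 938, beta = 0, noise_cv = 0,
                    steps = default_rlc_steps(), psii_fraction = 0.5,
                    fvfm = 0.65, seed = 1) {
  if (noise_cv < 0)
    stop_bioalbedo("noise_cv must be non-negative", "bioalbedo_domain_error")
  if (alpha > psii_fraction + 1e-12)
    stop_bioalbedo(
      "alpha > psii_fraction implies Y(PSII) > 1: no fluorescence representation",
      "bioalbedo_domain_error")
  retrmax <- alpha * ek
  Ps <- platt_ps_for_retrmax(alpha, retrmax, beta)
  E <- steps[steps > 0]
  Fm <- 1000
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      retr <- platt_retr(E, alpha, Ps, beta)
      if (noise_cv > 0)
        retr <- retr * (1 + stats::rnorm(length(E), 0, noise_cv))
      y <- pmin(pmax(retr / (E * psii_fraction), 0), 1)
      fmp <- Fm / (1 + 4e-4 * E)
      rlc_curve(sprintf("sim%03d", i), dark_F0 = Fm * (1 - fvfm),
                dark_Fm = Fm, E = E, F = fmp * (1 - y), Fm_prime = fmp)
    })
  })
}

#' Synthetic in-vivo mass-absorption spectra of the photosynthetic and
#' photoprotective pigment classes
#'
#' Smooth sum-of-Gaussian stand-ins for literature chlorophyll-a/b and
#' carotenoid mass-specific absorption spectra (m2 mg-1): blue and red
#' chlorophyll bands, broad blue-green carotenoid bands. Synthetic — values
#' are plausible in magnitude and shape but transcribe no published table.
#'
#' @param wavelengths Grid, nm (default 250-750 at 1 nm).
#' @return Named list of [pigment_spectrum()] objects
#'   (`chl_a`, `chl_b`, `ppc`, `psc`).
#' @export
default_pigment_spectra <- function(wavelengths = 250:750) {
  gauss <- function(mu, sigma) exp(-((wavelengths - mu) / sigma)^2 / 2)
  list(
    chl_a = pigment_spectrum("chl_a", wavelengths,
                             0.035 * gauss(435, 14) + 0.020 * gauss(676, 9) +
                               0.004 * gauss(390, 25)),
    chl_b = pigment_spectrum("chl_b", wavelengths,
                             0.030 * gauss(470, 14) + 0.012 * gauss(649, 9)),
    ppc = pigment_spectrum("ppc", wavelengths,
                           0.045 * gauss(450, 18) + 0.036 * gauss(480, 16)),
    psc = pigment_spectrum("psc", wavelengths,
                           0.035 * gauss(460, 18) + 0.024 * gauss(490, 16)))
}

#' Default cellular pigment contents
#'
#' Phenolic content 0.041 ng per cell; chlorophyll a about 11-fold lower
#' (the phenolic:chl-a ratio typical of heavily pigmented glacier algae);
#' all carotenoids treated as photoprotective, so `psc = 0` by default.
#'
#' @return A [pigment_profile()] with contents in mg per cell.
#' @export
default_pigment_profile <- function() {
  pigment_profile(c(phenolic = 4.1e-8, chl_a = 3.7e-9, chl_b = 1.2e-9,
                    ppc = 2.0e-9, psc = 0))
}

#' Generate a phenolic mass-absorption spectrum
#'
#' Sum-of-Gaussians template peaking in the UV-B at 300 nm with a secondary
#' shoulder at 335 nm and a broad visible tail decreasing to the red. The
#' amplitude is scaled by inverse design so that, combined with the default
#' chlorophyll/carotenoid spectra and cellular contents, phenolics
#' contribute exactly `fraction_660` of the total cellular absorption
#' cross-section at 660 nm (the fluorometer's actinic wavelength).
#'
#' @param wavelengths Grid, nm.
#' @param fraction_660 Target phenolic fraction at 660 nm (default 0.94).
#' @param profile Cellular contents used for the inverse design.
#' @param spectra Companion class spectra used for the inverse design.
#' @return A [pigment_spectrum()] of class `"phenolic"` (m2 mg-1).
#' @export
gen_phenolic_spectrum <- function(wavelengths = 250:750, fraction_660 = 0.94,
                                  profile = default_pigment_profile(),
                                  spectra = default_pigment_spectra(wavelengths)) {
  template <- exp(-((wavelengths - 300) / 26)^2 / 2) +
    0.32 * exp(-((wavelengths - 335) / 11)^2 / 2) +
    0.28 * exp(-pmax(wavelengths - 300, 0) / 260)
  others_660 <- sum(vapply(spectra, function(s) {
    cls <- s$pigment_class
    if (!cls %in% names(profile$contents)) return(0)
    stats::approx(s$wavelengths, s$mass_absorption, xout = 660)$y *
      profile$contents[[cls]]
  }, numeric(1)))
  t660 <- stats::approx(wavelengths, template, xout = 660)$y
  c_phe <- profile$contents[["phenolic"]]
  amp <- fraction_660 / (1 - fraction_660) * others_660 / (t660 * c_phe)
  pigment_spectrum("phenolic", wavelengths, amp * template)
}

#' Generate a pigment calibration set
#'
#' Emulates a field calibration campaign: `n` surface-ice samples with cell
#' abundances log-uniform over `abundance_range`, phenolic concentrations
#' proportional to abundance through the per-cell content, and absorbances
#' `A = e c l (1 + eps)` with multiplicative Gaussian noise.
#'
#' @param e_true True extinction spectrum: list with `wavelengths` (nm) and
#'   `e` (L g-1 cm-1). Default: the decadic equivalent of
#'   [gen_phenolic_spectrum()].
#' @param n Number of samples (>= 3; default 53).
#' @param abundance_range Cells mL-1 range (default 187 to 2.1e4).
#' @param phenol_ng_per_cell Per-cell phenolic content, ng (default 0.041).
#' @param path_length Cuvette path, cm.
#' @param noise_cv Multiplicative absorbance noise CV.
#' @param seed RNG seed.
#' @return A [calibration_set()].
#' @export
gen_calibration <- function(e_true = NULL, n = 53,
                            abundance_range = c(187, 2.1e4),
                            phenol_ng_per_cell = 0.041, path_length = 1,
                            noise_cv = 0, seed = 1) {
  if (n < 3)
    stop_bioalbedo("need n >= 3 calibration samples", "bioalbedo_domain_error")
  if (abundance_range[1] >= abundance_range[2] || abundance_range[1] <= 0)
    stop_bioalbedo("degenerate abundance range", "bioalbedo_domain_error")
  if (is.null(e_true)) {
    ph <- gen_phenolic_spectrum()
    e_true <- list(wavelengths = ph$wavelengths,
                   e = ph$mass_absorption / 1e-4)
  }
  with_seed(seed, {
    ab <- exp(stats::runif(n, log(abundance_range[1]),
                           log(abundance_range[2])))
    ab <- sort(ab)
    ## span the printed range exactly
    ab[1] <- abundance_range[1]; ab[n] <- abundance_range[2]
    conc <- ab * phenol_ng_per_cell * 1e-6  # ng/mL -> g/L
    A <- outer(conc * path_length, e_true$e)
    if (noise_cv > 0)
      A <- A * (1 + matrix(stats::rnorm(length(A), 0, noise_cv), nrow(A)))
    calibration_set(A, e_true$wavelengths, conc, path_length,
                    cell_abundance = ab)
  })
}

#' Solar elevation angle
#'
#' Simple declination/hour-angle geometry with solar noon at clock hour 12.
#'
#' @param hour Clock hour (0-23, solar time).
#' @param doy Day of year.
#' @param latitude Degrees north.
#' @return sin(elevation), in \[-1, 1\].
#' @export
solar_elevation_sin <- function(hour, doy, latitude) {
  decl <- 23.44 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  lat <- latitude * pi / 180
  ha <- (hour - 12) * 15 * pi / 180
  sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
}

#' Generate a diel series of clear-sky spectral irradiance
#'
#' Parametric stand-in for an atmospheric radiative-transfer spectrum: a
#' 5778-K blackbody shape with a logistic UV cutoff near 310 nm, scaled so
#' the spectrally integrated photon irradiance at solar noon equals
#' `peak_par`, and modulated through the day by solar elevation (zero below
#' the horizon).
#'
#' @param date Date (default 2016-07-26, midsummer).
#' @param latitude Degrees north (default 67.04, the dark-zone ice camp).
#' @param peak_par Noon photon irradiance integral, µmol photons m-2 s-1
#'   (default 1700, typical of clear-sky midsummer on the ice sheet).
#' @param wavelengths Grid, nm (default 280-750 at 1 nm).
#' @param seed Unused source of randomness kept for interface symmetry; the
#'   series is deterministic.
#' @return List of 24 [spectral_irradiance()] objects (hours 0-23).
#' @export
gen_irradiance_day <- function(date = as.Date("2016-07-26"), latitude = 67.04,
                               peak_par = 1700, wavelengths = 280:750,
                               seed = 1) {
  date <- as.Date(date)
  if (is.na(date)) stop_bioalbedo("invalid date", "bioalbedo_domain_error")
  if (abs(latitude) > 90)
    stop_bioalbedo("latitude must lie in [-90, 90]", "bioalbedo_domain_error")
  doy <- as.integer(strftime(date, "%j"))
  lam_m <- wavelengths * 1e-9
  planck <- lam_m^-5 / (exp(PLANCK_H * LIGHT_C /
                              (lam_m * BOLTZMANN_K * 5778)) - 1)
  shape_photons <- planck * lam_m / (1 + exp(-(wavelengths - 310) / 10))
  shape_photons <- shape_photons / pracma::trapz(wavelengths, shape_photons)
  rel <- pmax(solar_elevation_sin(0:23, doy, latitude), 0)
  if (rel[13] > 0) rel <- rel / rel[13]  # normalize to solar noon (hour 12)
  lapply(0:23, function(h) {
    photons <- shape_photons * peak_par * rel[h + 1]
    spectral_irradiance(wavelengths, energy_from_photons(photons, wavelengths),
                        timestamp = as.POSIXct(date, tz = "UTC") + h * 3600)
  })
}

#' Generate an ablation-season hourly forcing series
#'
#' Emulates regional-climate-model output for a melt season: snowpack
#' thickness declining linearly to zero at `snow_free`, (strictly above the
#' 2-cm growth threshold before that date, so no productive hours occur
#' under snow), a diurnal shortwave cycle with seasonal modulation and
#' additive noise, and an air-temperature series with diurnal and seasonal
#' cycles crossing the 0.5 degC threshold in midsummer.
#'
#' @param start,end First and last simulated days (Dates).
#' @param snow_free Date at which the surface becomes snow-free.
#' @param seed RNG seed for the noise terms.
#' @return data.frame with hourly `timestamp` (UTC), `sh_cm`, `swd_w_m2`,
#'   `tt_c`.
#' @export
gen_forcing_season <- function(start = as.Date("2016-06-01"),
                               end = as.Date("2016-09-01"),
                               snow_free = as.Date("2016-06-25"), seed = 1) {
  start <- as.Date(start); end <- as.Date(end); snow_free <- as.Date(snow_free)
  if (start >= end)
    stop_bioalbedo("start must precede end", "bioalbedo_domain_error")
  t0 <- as.POSIXct(start, tz = "UTC")
  t1 <- as.POSIXct(end, tz = "UTC") + 23 * 3600
  ts <- seq(t0, t1, by = "hour")
  hour <- as.integer(format(ts, "%H"))
  frac_season <- as.numeric(ts - t0, units = "days") /
    as.numeric(t1 - t0, units = "days")
  ## snow: > 2 cm strictly until snow_free, then bare ice
  tsf <- as.POSIXct(snow_free, tz = "UTC")
  melt_frac <- pmin(pmax(as.numeric(ts - t0, units = "secs") /
                           max(as.numeric(tsf - t0, units = "secs"), 1), 0), 1)
  sh <- ifelse(ts < tsf, 2 + 23 * (1 - melt_frac), 0)
  with_seed(seed, {
    swd <- pmax(0, 650 * (0.75 + 0.25 * sin(pi * frac_season)) *
                  pmax(sin(pi * (hour - 4) / 16), 0) +
                  stats::rnorm(length(ts), 0, 15))
    tt <- -1 + 4.2 * sin(pi * frac_season) +
      2.5 * sin(2 * pi * (hour - 9) / 24) +
      stats::rnorm(length(ts), 0, 0.3)
    data.frame(timestamp = ts, sh_cm = sh, swd_w_m2 = swd, tt_c = tt)
  })
}

#' Generate a cell-abundance sample for one biomass category
#'
#' Draws from a lognormal matched by moments to the category's field
#' statistics — low 186 +/- 276 (n = 27), medium 3711 +/- 2333 (n = 34),
#' high 8989 +/- 4773 (n = 103) cells mL-1. A skewed zero-truncated law is
#' required because the printed SDs approach or exceed the means.
#'
#' @param category `"low"`, `"medium"` or `"high"`.
#' @param seed RNG seed.
#' @param n Optional override of the category's sample size.
#' @return An [abundance_sample()].
#' @export
gen_abundances <- function(category = c("low", "medium", "high"), seed = 1,
                           n = NULL) {
  category <- match.arg(category)
  p <- switch(category,
              low = c(mean = 186, sd = 276, n = 27),
              medium = c(mean = 3711, sd = 2333, n = 34),
              high = c(mean = 8989, sd = 4773, n = 103))
  if (is.null(n)) n <- p[["n"]]
  sdlog2 <- log(1 + (p[["sd"]] / p[["mean"]])^2)
  meanlog <- log(p[["mean"]]) - sdlog2 / 2
  with_seed(seed, {
    abundance_sample(category,
                     stats::rlnorm(n, meanlog = meanlog, sdlog = sqrt(sdlog2)))
  })
}

#' Category mean abundances (cells mL-1) used throughout the analysis
#' @return Named vector `c(low = 186, medium = 3711, high = 8989)`.
#' @export
abundance_category_means <- function() {
  c(low = 186, medium = 3711, high = 8989)
}
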