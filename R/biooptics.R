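## Pigment bio-optics: extinction-coefficient calibration from absorbance vs
## concentration, conversion to mass-specific absorption, and reconstruction
## of single-cell absorption cross-sections a(lambda) = sum_i a_i(lambda) C_i.

#' Construct a pigment calibration set
#'
#' Pairs blank-corrected absorbance spectra with extract concentrations for
#' slope-based estimation of the spectral extinction coefficient
#' `e(lambda) = A/(l c)`.
#'
#' @param absorbance Matrix of dimensionless absorbances, one row per sample,
#'   one column per wavelength.
#' @param wavelengths Strictly increasing wavelength grid, nm.
#' @param concentration Pigment concentrations, g per L (>= 0), one per sample.
#' @param path_length Cuvette path length, cm (> 0).
#' @param cell_abundance Optional cells per mL, one per sample.
#' @return A `calibration_set`.
#' @export
calibration_set <- function(absorbance, wavelengths, concentration,
                            path_length = 1, cell_abundance = NULL) {
  absorbance <- as.matrix(absorbance)
  stopifnot(ncol(absorbance) == length(wavelengths),
            nrow(absorbance) == length(concentration))
  if (any(diff(wavelengths) <= 0))
    stop_bioalbedo("wavelength grid must be strictly increasing",
                   "bioalbedo_domain_error")
  if (any(concentration < 0))
    stop_bioalbedo("concentrations must be non-negative",
                   "bioalbedo_domain_error")
  if (path_length <= 0)
    stop_bioalbedo("path_length must be positive", "bioalbedo_domain_error")
  structure(list(absorbance = absorbance, wavelengths = wavelengths,
                 concentration = concentration, path_length = path_length,
                 cell_abundance = cell_abundance),
            class = "calibration_set")
}

#' Fit the spectral extinction coefficient from a calibration set
#'
#' Per-wavelength ordinary least squares slope of absorbance against
#' `concentration * path_length`: `e(lambda)` in L g-1 cm-1. The regression
#' is through the origin by default (spectra are blank-corrected); with
#' `intercept = TRUE` a free intercept is fitted and reported, which is
#' useful for detecting blank drift. Negative fitted slopes are clamped to
#' zero with a warning (absorption is physically non-negative).
#'
#' @param calib A [calibration_set()].
#' @param intercept Fit a free intercept? Default `FALSE`.
#' @return A data.frame with columns `wavelength`, `e`, `r2` (and
#'   `intercept` when fitted).
#' @export
fit_extinction <- function(calib, intercept = FALSE) {
  stopifnot(inherits(calib, "calibration_set"))
  x <- calib$concentration * calib$path_length
  if (length(unique(calib$concentration)) < 3)
    stop_bioalbedo(
      "need >= 3 distinct concentrations for slope estimation (rank-deficient)",
      "bioalbedo_rank_deficient")
  A <- calib$absorbance
  if (intercept) {
    xc <- x - mean(x)
    slope <- as.numeric(crossprod(xc, sweep(A, 2, colMeans(A)))) / sum(xc^2)
    b0 <- colMeans(A) - slope * mean(x)
    fitted <- outer(x, slope) + matrix(b0, nrow(A), ncol(A), byrow = TRUE)
  } else {
    slope <- as.numeric(crossprod(x, A)) / sum(x^2)
    b0 <- NULL
    fitted <- outer(x, slope)
  }
  if (any(slope < 0)) {
    warning("negative fitted extinction at ", sum(slope < 0),
            " wavelength(s): clamped to 0", call. = FALSE)
    fitted[, slope < 0] <- if (intercept)
      matrix(b0[slope < 0], nrow(A), sum(slope < 0), byrow = TRUE) else 0
    slope <- pmax(slope, 0)
  }
  rss <- colSums((A - fitted)^2)
  tss <- if (intercept) colSums(sweep(A, 2, colMeans(A))^2) else colSums(A^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, NA_real_)
  out <- data.frame(wavelength = calib$wavelengths, e = slope, r2 = r2)
  if (intercept) out$intercept <- b0
  out
}

#' Convert an extinction coefficient to a mass-specific absorption coefficient
#'
#' Unit algebra: 1 L g-1 cm-1 = 1e-4 m2 mg-1. With
#' `convention = "natural"` the decadic absorbance slope is additionally
#' multiplied by `ln(10)` to give a natural-log (e-folding) absorption
#' coefficient; the default keeps the decadic convention.
#'
#' @param e Extinction coefficient(s), L g-1 cm-1 (>= 0).
#' @param convention `"decadic"` (default) or `"natural"`.
#' @return Mass-specific absorption, m2 mg-1.
#' @export
#' @examples
#' extinction_to_mass_absorption(0.05)             # 5e-6
#' extinction_to_mass_absorption(0.05, "natural")  # 1.1513e-5
extinction_to_mass_absorption <- function(e, convention = c("decadic", "natural")) {
  convention <- match.arg(convention)
  if (any(e < 0))
    stop_bioalbedo("e must be non-negative", "bioalbedo_domain_error")
  e * 1e-4 * if (convention == "natural") log(10) else 1
}

#' Mass-specific absorption spectrum of one pigment class
#'
#' @param pigment_class One of `"phenolic"`, `"chl_a"`, `"chl_b"`, `"psc"`,
#'   `"ppc"`.
#' @param wavelengths Strictly increasing grid, nm.
#' @param mass_absorption `a_i(lambda)` in m2 mg-1 (>= 0).
#' @return A `pigment_spectrum`.
#' @export
pigment_spectrum <- function(pigment_class, wavelengths, mass_absorption) {
  pigment_class <- match.arg(pigment_class,
                             c("phenolic", "chl_a", "chl_b", "psc", "ppc"))
  stopifnot(length(wavelengths) == length(mass_absorption))
  if (any(diff(wavelengths) <= 0))
    stop_bioalbedo("wavelength grid must be strictly increasing",
                   "bioalbedo_domain_error")
  if (any(mass_absorption < 0))
    stop_bioalbedo("mass_absorption must be non-negative",
                   "bioalbedo_domain_error")
  structure(list(pigment_class = pigment_class, wavelengths = wavelengths,
                 mass_absorption = mass_absorption),
            class = "pigment_spectrum")
}

#' Cellular pigment contents
#'
#' @param contents Named numeric vector of per-cell pigment contents `C_i`
#'   in mg per cell (>= 0); names are pigment classes.
#' @return A `pigment_profile`.
#' @export
#' @examples
#' pigment_profile(c(phenolic = 4.1e-8, chl_a = 3.7e-9))
pigment_profile <- function(contents) {
  stopifnot(is.numeric(contents), !is.null(names(contents)))
  if (any(contents < 0))
    stop_bioalbedo("pigment contents must be non-negative",
                   "bioalbedo_domain_error")
  structure(list(contents = contents), class = "pigment_profile")
}

## Linear resampling onto a target grid; extrapolation is forbidden.
#' @noRd
resample_spectrum <- function(wavelengths, values, target) {
  if (min(target) < min(wavelengths) || max(target) > max(wavelengths))
    stop_bioalbedo("resampling would extrapolate beyond the measured range",
                   "bioalbedo_grid_error")
  stats::approx(wavelengths, values, xout = target, method = "linear")$y
}

#' Reconstruct a single-cell absorption cross-section
#'
#' `a(lambda) = sum_i a_i(lambda) * C_i` over pigment classes: the virtual
#' area (m2 per cell) of a completely opaque object blocking the equivalent
#' radiation. No packaging correction is applied here (see
#' [packaging_correction()]). Spectra on different grids are linearly
#' resampled onto the canonical 1-nm grid over the intersection of their
#' ranges; extrapolation is an error.
#'
#' @param profile A [pigment_profile()] (contents `C_i`, mg per cell).
#' @param spectra List of [pigment_spectrum()] objects covering every class
#'   with non-zero content.
#' @param grid Optional target wavelength grid, nm.
#' @return A `cell_cross_section` with fields `wavelengths`, `total`
#'   (m2 cell-1) and `by_class` (matrix, one column per class).
#' @export
reconstruct_cross_section <- function(profile, spectra, grid = NULL) {
  stopifnot(inherits(profile, "pigment_profile"))
  classes <- names(profile$contents)
  have <- vapply(spectra, function(s) s$pigment_class, character(1))
  active <- classes[profile$contents > 0]
  missing <- setdiff(active, have)
  if (length(missing))
    stop_bioalbedo(paste("no spectrum supplied for pigment class(es):",
                         paste(missing, collapse = ", ")),
                   "bioalbedo_missing_spectrum")
  use <- spectra[match(intersect(classes, have), have)]
  if (is.null(grid)) {
    lo <- max(vapply(use, function(s) min(s$wavelengths), numeric(1)))
    hi <- min(vapply(use, function(s) max(s$wavelengths), numeric(1)))
    if (lo >= hi)
      stop_bioalbedo("pigment spectra have no common wavelength range",
                     "bioalbedo_grid_error")
    grid <- seq(ceiling(lo), floor(hi), by = 1)
  }
  by_class <- vapply(use, function(s) {
    resample_spectrum(s$wavelengths, s$mass_absorption, grid) *
      profile$contents[[s$pigment_class]]
  }, numeric(length(grid)))
  by_class <- matrix(by_class, nrow = length(grid),
                     dimnames = list(NULL, vapply(use, `[[`, "",
                                                  "pigment_class")))
  structure(list(wavelengths = grid, total = rowSums(by_class),
                 by_class = by_class),
            class = "cell_cross_section")
}

#' @export
print.cell_cross_section <- function(x, ...) {
  cat(sprintf(
    "<cell_cross_section> %d-%d nm, classes: %s; integrated %.3g m2 nm cell-1\n",
    min(x$wavelengths), max(x$wavelengths),
    paste(colnames(x$by_class), collapse = ", "),
    spectral_integral(x)))
  invisible(x)
}

#' Spectrally integrate a cross-section (trapezoidal rule)
#'
#' @param cross_section A `cell_cross_section`.
#' @param lambda_lo,lambda_hi Integration bounds, nm (inside the grid;
#'   default full grid).
#' @return Integrated cross-section, m2 nm cell-1 on the nm grid.
#' @export
spectral_integral <- function(cross_section,
                              lambda_lo = min(cross_section$wavelengths),
                              lambda_hi = max(cross_section$wavelengths)) {
  if (lambda_lo > lambda_hi)
    stop_bioalbedo("inverted wavelength range", "bioalbedo_domain_error")
  wl <- cross_section$wavelengths
  if (lambda_lo < min(wl) || lambda_hi > max(wl))
    stop_bioalbedo("integration range outside the wavelength grid",
                   "bioalbedo_domain_error")
  keep <- wl >= lambda_lo & wl <= lambda_hi
  if (sum(keep) < 2) return(0)
  pracma::trapz(wl[keep], cross_section$total[keep])
}

#' Fraction of the total cross-section contributed by one class at a wavelength
#'
#' @param cross_section A `cell_cross_section`.
#' @param pigment_class Class name present in the cross-section.
#' @param lambda Wavelength, nm (linearly interpolated within the grid).
#' @return Fraction in \[0, 1\].
#' @export
class_fraction_at <- function(cross_section, pigment_class, lambda) {
  wl <- cross_section$wavelengths
  if (lambda < min(wl) || lambda > max(wl))
    stop_bioalbedo("lambda outside the wavelength grid",
                   "bioalbedo_domain_error")
  if (!pigment_class %in% colnames(cross_section$by_class))
    stop_bioalbedo(paste("class not in cross-section:", pigment_class),
                   "bioalbedo_domain_error")
  tot <- stats::approx(wl, cross_section$total, xout = lambda)$y
  if (tot <= 0)
    stop_bioalbedo("total cross-section is zero at lambda: fraction undefined",
                   "bioalbedo_undefined_fraction")
  cls <- stats::approx(wl, cross_section$by_class[, pigment_class],
                       xout = lambda)$y
  cls / tot
}

#' Write a cross-section to CSV (wavelength, total, one column per class)
#' @param cross_section A `cell_cross_section`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cross_section_csv <- function(cross_section, path) {
  d <- data.frame(wavelength_nm = cross_section$wavelengths,
                  total_m2_cell = cross_section$total)
  d <- cbind(d, as.data.frame(cross_section$by_class))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
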