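## Fluorescence-derived photophysiology: Fv/Fm, rETR, NPQ, rapid light curve
## (RLC) fitting, and the phenolic-shading correction that converts whole-cell
## light response to chloroplast-level light response.

#' Construct a rapid light curve record
#'
#' Holds one sample's dark-adapted yields (`F0`, `Fm`) and the ordered
#' actinic light steps of a rapid light curve: incident PAR `E`
#' (µmol photons m-2 s-1), steady-state yield `F` and maximal yield under
#' actinic light `Fm_prime` (arbitrary fluorometer units).
#'
#' @param sample_id Character label.
#' @param dark_F0,dark_Fm Dark-adapted minimum and maximum fluorescence
#'   yields, `dark_Fm >= dark_F0 >= 0`.
#' @param E Numeric vector of incident PAR per step; non-negative and
#'   strictly increasing.
#' @param F,Fm_prime Per-step steady-state and maximal yields,
#'   `Fm_prime >= F >= 0`.
#' @return An object of class `rlc_curve`.
#' @export
#' @examples
#' rlc_curve("s1", 100, 400, E = c(0, 50, 100, 200, 400),
#'           F = c(100, 120, 150, 180, 210),
#'           Fm_prime = c(400, 390, 370, 330, 300))
rlc_curve <- function(sample_id, dark_F0, dark_Fm, E, F, Fm_prime) {
  stopifnot(is.numeric(E), is.numeric(F), is.numeric(Fm_prime),
            length(E) == length(F), length(E) == length(Fm_prime))
  if (!is.finite(dark_Fm) || dark_Fm < dark_F0 || dark_F0 < 0)
    stop_bioalbedo("dark yields must satisfy dark_Fm >= dark_F0 >= 0",
                   "bioalbedo_invalid_measurement")
  if (any(E < 0) || any(diff(E) <= 0))
    stop_bioalbedo("E values must be non-negative and strictly increasing",
                   "bioalbedo_invalid_measurement")
  if (any(Fm_prime < F) || any(F < 0))
    stop_bioalbedo("steps must satisfy Fm_prime >= F >= 0",
                   "bioalbedo_invalid_measurement")
  structure(list(sample_id = as.character(sample_id),
                 dark_F0 = dark_F0, dark_Fm = dark_Fm,
                 steps = data.frame(E = E, F = F, Fm_prime = Fm_prime)),
            class = "rlc_curve")
}

#' @export
print.rlc_curve <- function(x, ...) {
  cat(sprintf("<rlc_curve> %s: %d steps, E in [%g, %g], Fv/Fm = %.3f\n",
              x$sample_id, nrow(x$steps), min(x$steps$E), max(x$steps$E),
              compute_fvfm(x$dark_F0, x$dark_Fm)))
  invisible(x)
}

#' Maximum quantum efficiency of PSII
#'
#' `Fv/Fm = (Fm - F0)/Fm` from dark-adapted yields; an inverse stress proxy
#' in microalgae, bounded in \[0, 1\].
#'
#' @param dark_F0,dark_Fm Dark-adapted minimum and maximum yields.
#' @return Numeric in \[0, 1\].
#' @export
#' @examples
#' compute_fvfm(100, 400)  # 0.75
compute_fvfm <- function(dark_F0, dark_Fm) {
  if (any(!is.finite(dark_Fm)) || any(dark_Fm <= 0))
    stop_bioalbedo("dark_Fm must be positive", "bioalbedo_invalid_measurement")
  if (any(dark_F0 < 0) || any(dark_F0 > dark_Fm))
    stop_bioalbedo("requires dark_Fm >= dark_F0 >= 0",
                   "bioalbedo_invalid_measurement")
  (dark_Fm - dark_F0) / dark_Fm
}

#' Relative electron transport rate through PSII
#'
#' `rETR = Y(PSII) * E * psii_fraction`, with the PSII/PSI excitation split
#' fixed at 0.5 by default (equal allocation between photosystems).
#'
#' @param y_psii Effective PSII quantum efficiency, `(Fm' - F)/Fm'`, in
#'   \[0, 1\].
#' @param E Incident PAR, µmol photons m-2 s-1.
#' @param psii_fraction Fraction of excitation allocated to PSII.
#' @return rETR in arbitrary units.
#' @export
compute_retr <- function(y_psii, E, psii_fraction = 0.5) {
  if (any(y_psii < 0) || any(y_psii > 1))
    stop_bioalbedo("y_psii must lie in [0, 1]", "bioalbedo_domain_error")
  if (any(E < 0))
    stop_bioalbedo("E must be non-negative", "bioalbedo_domain_error")
  y_psii * E * psii_fraction
}

#' Non-photochemical quenching across a light curve
#'
#' Default convention is `(Fm - Fm')/Fm` (quench expressed as a fraction of
#' the dark-adapted maximum yield); `convention = "stern_volmer_prime"`
#' computes the conventional Stern-Volmer form `(Fm - Fm')/Fm'`. Transient
#' `Fm' > Fm` (negative quench, common in noisy field data) is clamped to
#' zero with a warning.
#'
#' @param Fm Dark-adapted maximal yield, positive.
#' @param Fm_prime Maximal yield under actinic light, positive.
#' @param convention `"fm"` (default) or `"stern_volmer_prime"`.
#' @return NPQ (dimensionless, >= 0).
#' @export
#' @examples
#' compute_npq(400, 250)                                  # 0.375
#' compute_npq(400, 250, convention = "stern_volmer_prime")  # 0.6
compute_npq <- function(Fm, Fm_prime, convention = c("fm", "stern_volmer_prime")) {
  convention <- match.arg(convention)
  if (any(!is.finite(Fm)) || any(Fm <= 0) || any(Fm_prime <= 0))
    stop_bioalbedo("Fm and Fm_prime must be positive",
                   "bioalbedo_invalid_measurement")
  over <- Fm_prime > Fm
  if (any(over)) {
    warning("Fm_prime > Fm at ", sum(over),
            " step(s): negative quench clamped to 0", call. = FALSE)
    Fm_prime <- pmin(Fm_prime, Fm)
  }
  denom <- if (convention == "fm") Fm else Fm_prime
  (Fm - Fm_prime) / denom
}

#' Per-step derived quantities of a rapid light curve
#'
#' Computes the effective PSII quantum efficiency `Y(PSII) = (Fm' - F)/Fm'`
#' and rETR for every step of a curve (steps with `Fm' = 0` get `Y = 0`).
#'
#' @inheritParams fit_rlc
#' @return A data.frame with columns `E`, `F`, `Fm_prime`, `y_psii`, `retr`.
#' @export
rlc_retr <- function(curve, psii_fraction = 0.5) {
  stopifnot(inherits(curve, "rlc_curve"))
  s <- curve$steps
  y <- ifelse(s$Fm_prime > 0, (s$Fm_prime - s$F) / s$Fm_prime, 0)
  cbind(s, y_psii = y, retr = y * s$E * psii_fraction)
}

## P-E model forms ------------------------------------------------------------

#' Platt-type light-response model with photoinhibition
#'
#' `rETR(E) = Ps (1 - exp(-alpha E / Ps)) exp(-beta E / Ps)`. With
#' `beta = 0` this reduces to the Webb exponential saturating form.
#'
#' @param E PAR, µmol photons m-2 s-1.
#' @param alpha Initial slope.
#' @param Ps Scale parameter (equals the plateau when `beta = 0`).
#' @param beta Photoinhibition parameter (>= 0).
#' @return Modelled rETR.
#' @export
platt_retr <- function(E, alpha, Ps, beta = 0) {
  Ps * (1 - exp(-alpha * E / Ps)) * exp(-beta * E / Ps)
}

#' Analytic maximum of the Platt light-response curve over E >= 0
#'
#' For `beta > 0` the curve peaks at finite E and the maximum differs from
#' `Ps`; for `beta = 0` the supremum is `Ps`.
#' @inheritParams platt_retr
#' @return rETRmax.
#' @export
platt_retrmax <- function(alpha, Ps, beta = 0) {
  if (beta <= 0) return(Ps)
  Ps * (alpha / (alpha + beta)) * (beta / (alpha + beta))^(beta / alpha)
}

## Inverse of platt_retrmax in Ps: the Ps giving a requested curve maximum.
#' @noRd
platt_ps_for_retrmax <- function(alpha, retrmax, beta = 0) {
  if (beta <= 0) return(retrmax)
  retrmax / ((alpha / (alpha + beta)) * (beta / (alpha + beta))^(beta / alpha))
}

## RLC fitting ----------------------------------------------------------------

#' @noRd
new_rlc_fit <- function(model_name, alpha, retrmax, beta, rss, converged,
                        Ps = NA_real_, sample_id = NA_character_) {
  structure(list(sample_id = sample_id, model_name = model_name,
                 alpha = alpha, rETRmax = retrmax, beta = beta,
                 Ek = retrmax / alpha, Ps = Ps, rss = rss,
                 converged = converged),
            class = "rlc_fit")
}

#' @export
print.rlc_fit <- function(x, ...) {
  cat(sprintf(
    "<rlc_fit> %s: alpha = %.4g, rETRmax = %.4g, beta = %.4g, Ek = %.4g (rss %.3g%s)\n",
    x$model_name, x$alpha, x$rETRmax, x$beta, x$Ek, x$rss,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Fit a light-response model to (E, rETR) points
#'
#' Least-squares fit of either the Platt-type photoinhibition model or the
#' Webb exponential to electron-transport points. Dark (`E = 0`) points are
#' excluded from the objective (rETR is identically zero there and carries
#' no slope information). A deterministic bounded multistart (>= 5 starts)
#' guards against local minima; non-convergence is reported, never silently
#' replaced.
#'
#' @param E,retr Numeric vectors of PAR and rETR.
#' @param model `"platt"` (default) or `"webb"`.
#' @param n_starts Number of multistart attempts (>= 5 recommended).
#' @return An `rlc_fit` with fields `alpha`, `rETRmax`, `beta`,
#'   `Ek = rETRmax/alpha`, `rss`, `converged`.
#' @export
fit_rlc_points <- function(E, retr, model = c("platt", "webb"), n_starts = 7) {
  model <- match.arg(model)
  stopifnot(length(E) == length(retr))
  usable <- is.finite(E) & is.finite(retr) & E > 0
  if (all(retr[usable] == 0) || !any(usable))
    stop_bioalbedo("all rETR values are zero: degenerate curve",
                   "bioalbedo_degenerate_curve")
  if (sum(usable) < 4)
    stop_bioalbedo("fewer than 4 usable (E > 0) steps",
                   "bioalbedo_insufficient_data")
  E <- E[usable]; retr <- retr[usable]
  o <- order(E); E <- E[o]; retr <- retr[o]

  ## starting values: alpha0 from the low-light slope, Ps0 from the observed max
  a0 <- max((retr[2] - retr[1]) / (E[2] - E[1]), retr[1] / E[1],
            0.05 * max(retr) / max(E))
  p0 <- max(retr)
  grid <- expand.grid(fa = c(1, 0.3, 3), fp = c(1, 0.5, 2.5),
                      b0 = c(0, a0 / 20))
  grid <- grid[seq_len(max(n_starts, 5L)), , drop = FALSE]

  ctrl <- minpack.lm::nls.lm.control(maxiter = 1024, ftol = 1e-15,
                                     ptol = 1e-15, gtol = 0)
  resid_fun <- if (model == "platt") {
    function(p) retr - platt_retr(E, p[1], p[2], p[3])
  } else {
    function(p) retr - webb_retr(E, p[1], p[2])
  }
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    st <- grid[i, ]
    start <- if (model == "platt") c(a0 * st$fa, p0 * st$fp, st$b0)
             else c(a0 * st$fa, p0 * st$fp)
    lower <- c(1e-12, 1e-12, 0)[seq_along(start)]
    fit <- try(suppressWarnings(minpack.lm::nls.lm(
      par = start, lower = lower, fn = resid_fun, control = ctrl)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    conv <- fit$info %in% 1:4
    if (is.null(best) || (fit$deviance < best$fit$deviance))
      best <- list(fit = fit, converged = conv)
  }
  if (is.null(best))
    return(new_rlc_fit(model, NA_real_, NA_real_, NA_real_, Inf, FALSE))
  cf <- best$fit$par
  rss <- best$fit$deviance
  if (model == "platt") {
    retrmax <- platt_retrmax(cf[1], cf[2], cf[3])
    new_rlc_fit("platt_photoinhibition", cf[1], retrmax, cf[3], rss,
                best$converged, Ps = cf[2])
  } else {
    new_rlc_fit("webb_exponential", cf[1], cf[2], 0, rss,
                best$converged, Ps = cf[2])
  }
}

#' Webb exponential light-response model (no photoinhibition)
#' @inheritParams platt_retr
#' @param retrmax Saturation plateau.
#' @return Modelled rETR.
#' @export
webb_retr <- function(E, alpha, retrmax) {
  retrmax * (1 - exp(-alpha * E / retrmax))
}

#' Fit a rapid light curve
#'
#' Derives per-step rETR from the curve's fluorescence yields and fits the
#' chosen light-response model; see [fit_rlc_points()] for the objective and
#' multistart policy. At least 4 steps with `E > 0` are required.
#'
#' @param curve An [rlc_curve()].
#' @param model `"platt"` (default, photoinhibition-capable) or `"webb"`.
#' @param psii_fraction PSII excitation fraction used in rETR (default 0.5).
#' @param n_starts Multistart attempts.
#' @return An `rlc_fit`.
#' @export
fit_rlc <- function(curve, model = c("platt", "webb"), psii_fraction = 0.5,
                    n_starts = 7) {
  stopifnot(inherits(curve, "rlc_curve"))
  if (nrow(curve$steps) < 4)
    stop_bioalbedo("at least 4 light steps are required for fitting",
                   "bioalbedo_insufficient_data")
  d <- rlc_retr(curve, psii_fraction = psii_fraction)
  fit <- fit_rlc_points(d$E, d$retr, model = model, n_starts = n_starts)
  fit$sample_id <- curve$sample_id
  fit
}

#' Correct an RLC for shading by phenolic pigmentation
#'
#' Chloroplasts sit beneath vacuoles of phenolic pigment that intercept most
#' of the fluorometer's actinic light; the incident excitation that actually
#' reaches the chloroplast is `E' = E * (1 - fraction)`, where `fraction` is
#' the proportion of the total cellular absorption cross-section contributed
#' by phenolics at the measurement wavelength (about 0.94 at 660 nm for
#' phenolic-dominated cells). Yields are unchanged; refitting the corrected
#' curve yields chloroplast-level parameters (`Ek` and `rETRmax` scale by
#' `1 - fraction`, `alpha` is invariant).
#'
#' @param curve An [rlc_curve()].
#' @param fraction Phenolic fraction of the cellular absorption cross-section
#'   at the actinic wavelength, in \[0, 1\]. May also be a `shading_factor`.
#' @return A new `rlc_curve` with scaled `E`.
#' @export
apply_shading_correction <- function(curve, fraction) {
  stopifnot(inherits(curve, "rlc_curve"))
  if (inherits(fraction, "shading_factor")) fraction <- fraction$fraction_phenolic
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction < 0 || fraction > 1)
    stop_bioalbedo("fraction must be a single value in [0, 1]",
                   "bioalbedo_domain_error")
  out <- curve
  out$steps$E <- curve$steps$E * (1 - fraction)
  attr(out, "shading_fraction") <- fraction
  out
}

#' Shading factor at a wavelength
#'
#' @param wavelength Wavelength, nm.
#' @param fraction_phenolic Phenolic fraction of the total cellular
#'   absorption cross-section at that wavelength, in \[0, 1\].
#' @return A `shading_factor` object.
#' @export
shading_factor <- function(wavelength, fraction_phenolic) {
  if (fraction_phenolic < 0 || fraction_phenolic > 1)
    stop_bioalbedo("fraction_phenolic must lie in [0, 1]",
                   "bioalbedo_domain_error")
  structure(list(wavelength = wavelength,
                 fraction_phenolic = fraction_phenolic),
            class = "shading_factor")
}

#' Summarise fitted RLC parameters by group
#'
#' Mean, SD, SE and n of `alpha`, `rETRmax`, `beta` and `Ek` for two groups
#' of fits (e.g. control vs NPQ-inhibited assemblages). No hypothesis test
#' is performed. SE is `NA` for single-fit groups.
#'
#' @param fits_a,fits_b Lists of `rlc_fit` objects (each non-empty).
#' @param labels Character length-2 group labels.
#' @return A data.frame with columns `parameter`, `group`, `mean`, `sd`,
#'   `se`, `n`.
#' @export
compare_rlc_groups <- function(fits_a, fits_b, labels = c("a", "b")) {
  if (length(fits_a) < 1 || length(fits_b) < 1)
    stop_bioalbedo("both groups must contain at least one fit",
                   "bioalbedo_domain_error")
  params <- c("alpha", "rETRmax", "beta", "Ek")
  one <- function(fits, label) {
    do.call(rbind, lapply(params, function(p) {
      v <- vapply(fits, function(f) f[[p]], numeric(1))
      n <- length(v)
      s <- if (n > 1) stats::sd(v) else NA_real_
      data.frame(parameter = p, group = label, mean = mean(v), sd = s,
                 se = if (n > 1) s / sqrt(n) else NA_real_, n = n)
    }))
  }
  out <- rbind(one(fits_a, labels[1]), one(fits_b, labels[2]))
  rownames(out) <- NULL
  out
}

## CSV interfaces -------------------------------------------------------------

#' Read rapid light curves from a long-format CSV
#'
#' Expects columns `sample_id`, `step_index`, `E_umol_m2_s`, `F`, `Fm_prime`;
#' the `step_index = 0` row of each sample is the dark measurement carrying
#' `F0` (in `F`) and `Fm` (in `Fm_prime`).
#'
#' @param path CSV path.
#' @return A named list of [rlc_curve()] objects.
#' @export
read_rlc_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "step_index", "E_umol_m2_s", "F", "Fm_prime")
  if (!all(need %in% names(d)))
    stop_bioalbedo(paste("missing columns:",
                         paste(setdiff(need, names(d)), collapse = ", ")),
                   "bioalbedo_schema_error")
  out <- lapply(split(d, d$sample_id), function(s) {
    s <- s[order(s$step_index), ]
    dark <- s[s$step_index == 0, ]
    if (nrow(dark) != 1)
      stop_bioalbedo("each sample needs exactly one step_index = 0 dark row",
                     "bioalbedo_schema_error")
    li <- s[s$step_index > 0, ]
    rlc_curve(s$sample_id[1], dark_F0 = dark$F, dark_Fm = dark$Fm_prime,
              E = li$E_umol_m2_s, F = li$F, Fm_prime = li$Fm_prime)
  })
  out[order(names(out))]
}

#' Write rapid light curves to the long CSV layout read by [read_rlc_csv()]
#' @param curves List of [rlc_curve()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rlc_csv <- function(curves, path) {
  rows <- do.call(rbind, lapply(curves, function(cu) {
    rbind(data.frame(sample_id = cu$sample_id, step_index = 0,
                     E_umol_m2_s = 0, F = cu$dark_F0, Fm_prime = cu$dark_Fm),
          data.frame(sample_id = cu$sample_id,
                     step_index = seq_len(nrow(cu$steps)),
                     E_umol_m2_s = cu$steps$E, F = cu$steps$F,
                     Fm_prime = cu$steps$Fm_prime))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Tabulate a list of RLC fits
#' @param fits List of `rlc_fit` objects.
#' @return A data.frame, one row per fit.
#' @export
rlc_fit_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(sample_id = f$sample_id, model = f$model_name,
               alpha = f$alpha, rETRmax = f$rETRmax, beta = f$beta,
               Ek = f$Ek, rss = f$rss, converged = f$converged)
  }))
}
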