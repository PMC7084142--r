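## Threshold-gated logistic bloom model: daily glacier-algal biomass in
## surface ice over an ablation season, driven by hourly snow depth,
## shortwave-down radiation and air temperature.

#' Bloom model parameters
#'
#' Growth is logistic, `g(B) = mu B (1 - B/K)`, gated by the fraction of
#' each day in which all three environmental thresholds are met
#' (snow-free `SH < sh_max`, light `SWD > swd_min`, liquid water
#' `TT > tt_min`; strict inequalities), with a fixed daily loss fraction.
#'
#' @param mu Intrinsic daily net growth coefficient, d-1 (> 0).
#' @param K Logistic carrying capacity, ng DW mL-1 (> 0).
#' @param b0 Initial biomass, ng DW mL-1 (> 0).
#' @param loss Daily loss fraction in \[0, 1) (default 0.10: mortality plus
#'   physical removal from the ice surface).
#' @param sh_max Snow-depth threshold, cm (growth requires `SH < sh_max`).
#' @param swd_min Shortwave-down threshold, W m-2 (`SWD > swd_min`).
#' @param tt_min Air-temperature threshold, deg C (`TT > tt_min`).
#' @param b_min Refuge floor for biomass (default 0; a small positive value
#'   prevents numerical extinction during long snow cover).
#' @param hard_gate If `TRUE`, a day's net change is zeroed unless gated
#'   growth strictly exceeds the loss term (alternative reading of
#'   "growth must exceed losses"); default `FALSE` applies the signed sum.
#' @return A `bloom_params`.
#' @export
bloom_params <- function(mu, K, b0, loss = 0.10, sh_max = 2, swd_min = 10,
                         tt_min = 0.5, b_min = 0, hard_gate = FALSE) {
  if (mu <= 0 || K <= 0 || b0 <= 0)
    stop_bioalbedo("mu, K and b0 must be positive", "bioalbedo_domain_error")
  if (loss < 0 || loss >= 1)
    stop_bioalbedo("loss must lie in [0, 1)", "bioalbedo_domain_error")
  structure(list(mu = mu, K = K, b0 = b0, loss = loss,
                 sh_max = sh_max, swd_min = swd_min, tt_min = tt_min,
                 b_min = b_min, hard_gate = hard_gate),
            class = "bloom_params")
}

#' Fraction of a day permissive for growth
#'
#' An hour counts as productive only when all three strict inequalities
#' hold: `SH < sh_max`, `SWD > swd_min`, `TT > tt_min`. Boundary-equal
#' values do not count.
#'
#' @param sh,swd,tt Numeric vectors of exactly 24 hourly values (snow depth
#'   cm, shortwave-down W m-2, air temperature deg C).
#' @param params A [bloom_params()].
#' @return Fraction in \[0, 1\].
#' @export
productive_fraction <- function(sh, swd, tt, params) {
  if (length(sh) != 24 || length(swd) != 24 || length(tt) != 24)
    stop_bioalbedo("each forcing variable needs exactly 24 hourly records",
                   "bioalbedo_missing_hours")
  if (anyNA(sh) || anyNA(swd) || anyNA(tt))
    stop_bioalbedo("forcing contains missing hourly values",
                   "bioalbedo_missing_hours")
  mean(sh < params$sh_max & swd > params$swd_min & tt > params$tt_min)
}

#' Logistic net growth rate
#'
#' `g(B) = mu B (1 - B/K)`, floored at zero for `B > K` (losses are the
#' separate daily term, not negative growth).
#'
#' @param B Biomass, ng DW mL-1 (>= 0).
#' @param params A [bloom_params()].
#' @return ng DW mL-1 d-1.
#' @export
logistic_net_growth <- function(B, params) {
  if (any(B < 0))
    stop_bioalbedo("biomass must be non-negative", "bioalbedo_domain_error")
  pmax(0, params$mu * B * (1 - B / params$K))
}

#' Advance the bloom by one day
#'
#' Euler day-step with growth and loss applied simultaneously:
#' `B' = B + f g(B) - loss * B`, floored at `b_min`.
#'
#' @param B Biomass, ng DW mL-1.
#' @param f Productive fraction of the day, in \[0, 1\].
#' @param params A [bloom_params()].
#' @return Next-day biomass.
#' @export
step_day <- function(B, f, params) {
  g <- f * logistic_net_growth(B, params)
  d <- params$loss * B
  delta <- if (params$hard_gate && g <= d) -d else g - d
  max(params$b_min, B + delta)
}

#' Simulate a full ablation season
#'
#' Iterates [productive_fraction()] and [step_day()] from `params$b0` over
#' every complete day of the forcing series. The forcing must cover a
#' contiguous run of days with exactly 24 hourly records each; gaps are an
#' error listing the missing dates.
#'
#' @param forcing data.frame with columns `timestamp` (POSIXct, hourly),
#'   `sh_cm`, `swd_w_m2`, `tt_c` (as produced by [gen_forcing_season()]).
#' @param params A [bloom_params()].
#' @return A data.frame (`bloom_trajectory`): `date`, `productive_fraction`,
#'   `growth`, `loss` (ng DW mL-1 d-1) and end-of-day `biomass`.
#' @export
run_season <- function(forcing, params) {
  need <- c("timestamp", "sh_cm", "swd_w_m2", "tt_c")
  if (!all(need %in% names(forcing)))
    stop_bioalbedo(paste("forcing must have columns:",
                         paste(need, collapse = ", ")),
                   "bioalbedo_schema_error")
  dates <- as.Date(forcing$timestamp, tz = "UTC")
  counts <- table(dates)
  full <- as.Date(names(counts)[counts == 24])
  expected <- seq(min(dates), max(dates), by = "day")
  missing <- expected[!expected %in% full]
  if (length(missing))
    stop_bioalbedo(paste("forcing has incomplete or missing days:",
                         paste(format(missing), collapse = ", ")),
                   "bioalbedo_missing_hours")
  forcing <- forcing[order(forcing$timestamp), ]
  dates <- as.Date(forcing$timestamp, tz = "UTC")
  days <- split(seq_len(nrow(forcing)), dates)
  B <- params$b0
  out <- vector("list", length(days))
  for (i in seq_along(days)) {
    idx <- days[[i]]
    f <- productive_fraction(forcing$sh_cm[idx], forcing$swd_w_m2[idx],
                             forcing$tt_c[idx], params)
    g <- f * logistic_net_growth(B, params)
    l <- params$loss * B
    B <- step_day(B, f, params)
    out[[i]] <- data.frame(date = as.Date(names(days)[i]),
                           productive_fraction = f, growth = g, loss = l,
                           biomass = B)
  }
  traj <- do.call(rbind, out)
  rownames(traj) <- NULL
  class(traj) <- c("bloom_trajectory", "data.frame")
  traj
}

#' Equilibrium biomass under constant gating
#'
#' Fixed point of the day-step under a constant productive fraction:
#' `B* = K (1 - loss / (f mu))` when `f mu > loss`, else 0 (the population
#' cannot persist). The observed, site-dependent "carrying capacity" of a
#' bloom is this forcing-dependent equilibrium, not `K` itself.
#'
#' @param params A [bloom_params()].
#' @param f Constant productive fraction.
#' @return B*, ng DW mL-1.
#' @export
equilibrium_biomass <- function(params, f = 1) {
  if (f * params$mu <= params$loss) return(0)
  params$K * (1 - params$loss / (f * params$mu))
}

#' Fit logistic net-productivity parameters from incubation data
#'
#' Least-squares estimate of `(mu, K)` from a table of biomass vs net
#' productivity, `P = mu B (1 - B/K)`.
#'
#' @param biomass Biomass values, ng DW mL-1 (> 0).
#' @param net_productivity Net productivity, ng DW mL-1 d-1.
#' @return List with `mu`, `K`, `rss`, `converged`.
#' @export
fit_logistic_growth <- function(biomass, net_productivity) {
  stopifnot(length(biomass) == length(net_productivity), length(biomass) >= 3)
  fit <- minpack.lm::nls.lm(
    par = c(mu = max(net_productivity / biomass), K = 1.5 * max(biomass)),
    lower = c(1e-12, 1e-12),
    fn = function(p) net_productivity - p[1] * biomass * (1 - biomass / p[2]),
    control = minpack.lm::nls.lm.control(maxiter = 1024, ftol = 1e-15,
                                         ptol = 1e-15))
  list(mu = fit$par[[1]], K = fit$par[[2]], rss = fit$deviance,
       converged = fit$info %in% 1:4)
}

#' Cylinder biovolume of a cell
#'
#' `pi * (width/2)^2 * length` in µm3.
#'
#' @param length_um,width_um Cell dimensions, µm.
#' @return µm3.
#' @export
#' @examples
#' cell_biovolume(29.60, 12.04)  # about 3370
cell_biovolume <- function(length_um, width_um) {
  pi * (width_um / 2)^2 * length_um
}

#' Convert biovolume to dry-weight biomass
#'
#' @param biovolume_um3 Biovolume, µm3 (per cell or per mL).
#' @param dw_per_um3 Conversion factor, ng DW per µm3 (required; a
#'   literature-scale default for heavily pigmented glacier algae is about
#'   2.6e-4 ng µm-3).
#' @return ng DW (same basis as the biovolume).
#' @export
biovolume_to_dw <- function(biovolume_um3, dw_per_um3) {
  if (missing(dw_per_um3) || is.null(dw_per_um3))
    stop_bioalbedo("dw_per_um3 must be supplied explicitly (ng DW per um3)",
                   "bioalbedo_missing_config")
  if (dw_per_um3 <= 0)
    stop_bioalbedo("dw_per_um3 must be positive", "bioalbedo_domain_error")
  biovolume_um3 * dw_per_um3
}
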