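test_that("energy-photon conversions match physical constants and invert exactly", {
  expect_equal(photons_from_energy(1, 550), 4.598, tolerance = 1e-3 / 4.598)
  expect_equal(photons_from_energy(0, 550), 0)
  E <- c(0.3, 1.2, 2.5)
  round_trip <- energy_from_photons(photons_from_energy(E, 450), 450)
  expect_equal(round_trip, E, tolerance = 1e-12)
  expect_error(photons_from_energy(1, 0), class = "bioalbedo_domain_error")
})

test_that("cell geometry gives the cylinder half-lateral area of the mean cell", {
  g <- cell_geometry()
  expect_equal(g$half_lateral_area_m2, pi * 12.04 * 29.60 / 2 * 1e-12,
               tolerance = 1e-12)
  expect_equal(g$half_lateral_area_m2, 5.598e-10, tolerance = 1e-4)
  ## available light is proportional to cell length
  irr <- flat_photon_irradiance(400:500)
  a1 <- available_per_cell(cell_geometry(29.60, 12.04), irr)$available
  a2 <- available_per_cell(cell_geometry(59.20, 12.04), irr)$available
  expect_equal(a2, 2 * a1, tolerance = 1e-12)
  ## rectangle alternative
  gr <- cell_geometry(10, 5, shape = "rectangle")
  expect_equal(gr$half_lateral_area_m2, 50e-12)
})

test_that("absorbed flux is cross-section times photon irradiance in femtomoles", {
  wl <- 400:500
  cs <- flat_cross_section(wl, 1e-10)
  ab <- absorbed_per_cell(cs, flat_photon_irradiance(wl, 1))
  expect_equal(unname(ab$absorbed[, "phenolic"]), rep(0.1, length(wl)),
               tolerance = 1e-12)
  ## zero irradiance, zero absorption; doubling irradiance doubles absorption
  expect_true(all(absorbed_per_cell(cs,
    flat_photon_irradiance(wl, 0))$absorbed == 0))
  ab2 <- absorbed_per_cell(cs, flat_photon_irradiance(wl, 2))
  expect_equal(ab2$absorbed, 2 * ab$absorbed, tolerance = 1e-12)
})

test_that("packaging correction clips proportionally and conserves availability", {
  mk_budget <- function(absorbed, available) {
    structure(list(wavelengths = seq_along(available) + 399,
                   absorbed = absorbed, available = available,
                   clipped = rep(FALSE, length(available))),
              class = "energy_budget")
  }
  b <- mk_budget(matrix(c(1.5, 0.5), 1, dimnames = list(NULL, c("A", "B"))),
                 1.0)
  cb <- packaging_correction(b)
  expect_equal(unname(cb$absorbed[1, ]), c(0.75, 0.25))
  expect_true(cb$clipped)

  ## absorption below availability is untouched
  b2 <- mk_budget(matrix(c(0.3, 0.2), 1, dimnames = list(NULL, c("A", "B"))),
                  1.0)
  cb2 <- packaging_correction(b2)
  expect_equal(cb2$absorbed, b2$absorbed)
  expect_false(cb2$clipped)

  ## phenolics-last allocation truncates the screening pigment first
  b3 <- mk_budget(matrix(c(1.5, 0.4), 1,
                         dimnames = list(NULL, c("phenolic", "chl_a"))), 1.0)
  cb3 <- packaging_correction(b3, allocation = "phenolics_last")
  expect_equal(unname(cb3$absorbed[1, ]), c(0.6, 0.4))

  ## random budgets never exceed availability after correction
  set.seed(11)
  for (i in 1:200) {
    n <- 10
    ab <- matrix(stats::runif(3 * n, 0, 2), n, 3,
                 dimnames = list(NULL, c("phenolic", "chl_a", "ppc")))
    av <- stats::runif(n, 0.5, 2)
    cb <- packaging_correction(mk_budget(ab, av))
    expect_true(all(rowSums(cb$absorbed) <= cb$available * (1 + 1e-12)))
  }
})

test_that("budget capture fractions plus the unabsorbed remainder sum to one", {
  cs <- default_cross_section()
  b <- energy_budget(cs, cell_geometry(), gen_irradiance_day()[[13]])
  expect_equal(sum(b$fractions), 1, tolerance = 1e-9)
  expect_true(all(b$fractions >= 0 & b$fractions <= 1))
  expect_true(all(rowSums(b$absorbed) <= b$available * (1 + 1e-12)))
})

test_that("IRF is linear in abundance and requires an explicit area factor", {
  power <- rep(1e-12, 101)
  expect_true(all(irf_per_m2(power, 0, vol_to_area_factor()) == 0))
  expect_equal(irf_per_m2(power, 2000, vol_to_area_factor()),
               2 * irf_per_m2(power, 1000, vol_to_area_factor()),
               tolerance = 1e-15)
  expect_error(irf_per_m2(power, 1000), class = "bioalbedo_missing_config")
  expect_equal(vol_to_area_factor(), 18000)
  ## at the printed category means the IRF ratio is the abundance ratio
  means <- abundance_category_means()
  r <- irf_per_m2(power, means[["high"]], 18000) /
    irf_per_m2(power, means[["medium"]], 18000)
  expect_equal(unique(r), 8989 / 3711, tolerance = 1e-12)
})

test_that("one hour of 927.78 W m-2 melts exactly 1 cm w.e.", {
  wl <- 280:750
  ## an hourly energy input equal to the latent heat of a 1-cm slab:
  ## 334e4 J m-2 h-1, i.e. a constant 927.78 W m-2 held for one hour
  irf <- rep(334e4 / 470, length(wl))
  expect_equal(melt_from_irf(wl, irf), 1.0, tolerance = 1e-9)
  expect_equal(melt_from_irf(wl, rep(927.78 * 3600 / 470, length(wl))), 1.0,
               tolerance = 5e-6)
  expect_equal(melt_from_irf(wl, rep(0, length(wl))), 0)
  ## halving the window on a flat spectrum halves the melt
  expect_equal(melt_from_irf(wl, irf, c(280, 515)),
               melt_from_irf(wl, irf) / 2, tolerance = 1e-12)
  expect_error(melt_from_irf(wl, irf, c(750, 280)),
               class = "bioalbedo_domain_error")
})

test_that("diel melt is linear in abundance with category statistics", {
  cs <- default_cross_section()
  geom <- cell_geometry()
  day <- gen_irradiance_day()
  ## a dark day melts nothing
  dark <- lapply(day, function(s)
    spectral_irradiance(s$wavelengths, rep(0, length(s$wavelengths))))
  m0 <- diel_melt(cs, geom, dark, c(5000, 9000), vol_to_area_factor())
  expect_equal(m0$daily_melt, c(0, 0))

  ## missing hours are an error, as is a missing area factor
  expect_error(diel_melt(cs, geom, day[1:23], 5000, vol_to_area_factor()),
               class = "bioalbedo_missing_hours")
  expect_error(diel_melt(cs, geom, day, 5000),
               class = "bioalbedo_missing_config")

  ## single abundance: SE is flagged undefined
  m1 <- diel_melt(cs, geom, day, 8989, vol_to_area_factor())
  expect_true(is.na(m1$se))

  ## linearity: the category mean melt equals the melt at the mean abundance
  ab <- gen_abundances("medium", seed = 5)
  mcat <- diel_melt(cs, geom, day, ab, vol_to_area_factor())
  mmean <- diel_melt(cs, geom, day, mean(ab$abundances), vol_to_area_factor())
  expect_equal(mcat$mean, mmean$mean, tolerance = 1e-12)
  expect_equal(mcat$se, mcat$sd / sqrt(ab$n), tolerance = 1e-12)
  ## daily melt is the sum over hours
  expect_equal(sum(mmean$hourly$melt_cm_we), mmean$mean, tolerance = 1e-12)
})

test_that("excluding photochemistry can only reduce melt", {
  cs <- default_cross_section()
  geom <- cell_geometry()
  day <- gen_irradiance_day()
  with_chl <- diel_melt(cs, geom, day, 8989, vol_to_area_factor(),
                        exclude_classes = character(0))
  without_chl <- diel_melt(cs, geom, day, 8989, vol_to_area_factor())
  expect_lte(without_chl$mean, with_chl$mean)

  ## with zero chlorophyll content the exclusion is a no-op
  prof <- default_pigment_profile()
  contents <- prof$contents
  contents[c("chl_a", "chl_b")] <- 0
  sp <- default_pigment_spectra()
  cs0 <- reconstruct_cross_section(pigment_profile(contents),
                                   c(list(gen_phenolic_spectrum()),
                                     unname(sp)))
  a <- diel_melt(cs0, geom, day, 8989, vol_to_area_factor(),
                 exclude_classes = character(0))
  b <- diel_melt(cs0, geom, day, 8989, vol_to_area_factor())
  expect_equal(a$mean, b$mean, tolerance = 1e-12)
})
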