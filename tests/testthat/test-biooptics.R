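test_that("extinction slopes are recovered exactly from noiseless calibrations", {
  wl <- seq(300, 700, by = 100)
  conc <- c(0.1, 0.2, 0.5, 1.0)
  A <- outer(conc * 1, rep(0.05, length(wl)))
  calib <- calibration_set(A, wl, conc, path_length = 1)
  ext <- fit_extinction(calib)
  expect_equal(ext$e, rep(0.05, length(wl)), tolerance = 1e-12)
  expect_equal(ext$r2, rep(1, length(wl)), tolerance = 1e-12)

  ## free-intercept variant reports the blank drift
  A2 <- sweep(A, 2, 0.01, "+")
  ext2 <- fit_extinction(calibration_set(A2, wl, conc), intercept = TRUE)
  expect_equal(ext2$e, rep(0.05, length(wl)), tolerance = 1e-10)
  expect_equal(ext2$intercept, rep(0.01, length(wl)), tolerance = 1e-10)
})

test_that("degenerate concentration designs are rejected, negative slopes clamped", {
  wl <- c(400, 500)
  expect_error(
    fit_extinction(calibration_set(matrix(0, 4, 2), wl, rep(0, 4))),
    class = "bioalbedo_rank_deficient")
  expect_error(
    fit_extinction(calibration_set(matrix(1, 4, 2), wl, rep(0.5, 4))),
    class = "bioalbedo_rank_deficient")
  ## anti-correlated absorbance at one band gets clamped to zero
  conc <- c(0.1, 0.2, 0.5, 1.0)
  A <- cbind(0.05 * conc, -0.01 * conc)
  expect_warning(ext <- fit_extinction(calibration_set(A, wl, conc)),
                 "clamped")
  expect_equal(ext$e[2], 0)
  expect_gt(ext$e[1], 0)
})

test_that("noisy calibrations at the campaign's scale recover the spectrum within 5%", {
  wl <- seq(250, 750, by = 100)
  e_true <- list(wavelengths = wl, e = c(300, 180, 90, 45, 25, 15))
  calib <- gen_calibration(e_true = e_true, n = 53, noise_cv = 0.02, seed = 7)
  ext <- fit_extinction(calib)
  expect_true(all(abs(ext$e - e_true$e) / e_true$e < 0.05))
  expect_equal(length(calib$concentration), 53)
})

test_that("extinction-to-mass-absorption unit algebra is exact", {
  expect_equal(extinction_to_mass_absorption(0.05), 5e-6)
  expect_equal(extinction_to_mass_absorption(0.05, "natural"),
               5e-6 * log(10), tolerance = 1e-12)
  expect_equal(extinction_to_mass_absorption(0.05, "natural"), 1.1513e-5,
               tolerance = 1e-4)
  expect_equal(extinction_to_mass_absorption(0), 0)
  expect_error(extinction_to_mass_absorption(-1),
               class = "bioalbedo_domain_error")
})

test_that("cross-section reconstruction is the content-weighted sum of class spectra", {
  wl <- 250:750
  flat <- pigment_spectrum("phenolic", wl, rep(0.01, length(wl)))
  cs <- reconstruct_cross_section(pigment_profile(c(phenolic = 4.1e-8)),
                                  list(flat))
  expect_equal(cs$total, rep(4.1e-10, length(cs$wavelengths)),
               tolerance = 1e-12)

  ## additivity of two classes
  chl <- pigment_spectrum("chl_a", wl, rep(0.02, length(wl)))
  cs2 <- reconstruct_cross_section(
    pigment_profile(c(phenolic = 4.1e-8, chl_a = 1e-9)), list(flat, chl))
  expect_equal(cs2$total, cs2$by_class[, "phenolic"] + cs2$by_class[, "chl_a"])
  expect_equal(cs2$total, rep(4.1e-10 + 2e-11, length(cs2$wavelengths)),
               tolerance = 1e-12)

  ## zero contents give an identically zero cross-section
  cs0 <- reconstruct_cross_section(pigment_profile(c(phenolic = 0)),
                                   list(flat))
  expect_true(all(cs0$total == 0))

  ## a missing spectrum for a non-zero class is an error
  expect_error(
    reconstruct_cross_section(pigment_profile(c(chl_b = 1e-9)), list(flat)),
    class = "bioalbedo_missing_spectrum")

  ## resampling never extrapolates
  narrow <- pigment_spectrum("phenolic", 400:500, rep(0.01, 101))
  expect_error(
    reconstruct_cross_section(pigment_profile(c(phenolic = 1e-8)),
                              list(narrow), grid = 350:550),
    class = "bioalbedo_grid_error")
})

test_that("spectral integration and engineered fold-changes behave analytically", {
  wl <- 250:750
  cs <- flat_cross_section(wl, 1e-10)
  expect_equal(spectral_integral(cs), 500e-10, tolerance = 1e-12)
  expect_equal(spectral_integral(cs, 400, 650), 250e-10, tolerance = 1e-12)
  expect_equal(spectral_integral(flat_cross_section(wl, 0)), 0)
  expect_error(spectral_integral(cs, 700, 400),
               class = "bioalbedo_domain_error")

  ## a dominant class built to carry 49x the base absorption gives a
  ## with/without integral ratio of exactly 50
  base <- pigment_spectrum("chl_a", wl, rep(1e-3, length(wl)))
  dominant <- pigment_spectrum("phenolic", wl, rep(4.9e-2, length(wl)))
  with_p <- reconstruct_cross_section(
    pigment_profile(c(chl_a = 1e-8, phenolic = 1e-8)), list(base, dominant))
  without_p <- reconstruct_cross_section(
    pigment_profile(c(chl_a = 1e-8)), list(base))
  expect_equal(spectral_integral(with_p) / spectral_integral(without_p), 50,
               tolerance = 1e-12)
})

test_that("class fractions partition the cross-section", {
  wl <- 250:750
  single <- flat_cross_section(wl, 1e-10)
  expect_equal(class_fraction_at(single, "phenolic", 500), 1.0)
  two <- reconstruct_cross_section(
    pigment_profile(c(phenolic = 1e-8, chl_a = 1e-8)),
    list(pigment_spectrum("phenolic", wl, rep(0.01, length(wl))),
         pigment_spectrum("chl_a", wl, rep(0.01, length(wl)))))
  expect_equal(class_fraction_at(two, "phenolic", 660), 0.5)
  zero <- flat_cross_section(wl, 0)
  expect_error(class_fraction_at(zero, "phenolic", 500),
               class = "bioalbedo_undefined_fraction")
})

test_that("additivity, homogeneity and fraction normalization hold on random profiles", {
  set.seed(41)
  wl <- seq(250, 750, by = 10)
  for (i in 1:100) {
    contents <- stats::runif(3, 0, 1e-8)
    names(contents) <- c("phenolic", "chl_a", "ppc")
    specs <- lapply(names(contents), function(cl)
      pigment_spectrum(cl, wl, stats::runif(length(wl), 0, 0.05)))
    cs <- reconstruct_cross_section(pigment_profile(contents), specs)
    expect_lt(max(abs(cs$total - rowSums(cs$by_class))) /
                max(cs$total, 1e-300), 1e-12)
    ## class fractions sum to 1 wherever total > 0
    at <- 500
    fr <- sum(vapply(names(contents), function(cl)
      class_fraction_at(cs, cl, at), numeric(1)))
    expect_equal(fr, 1, tolerance = 1e-12)
    ## doubling every content doubles the total everywhere
    cs2 <- reconstruct_cross_section(pigment_profile(contents * 2), specs)
    expect_equal(cs2$total, 2 * cs$total, tolerance = 1e-12)
  }
})
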