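test_that("Fv/Fm, rETR and NPQ follow their defining ratios", {
  expect_equal(compute_fvfm(100, 400), 0.75)
  expect_equal(compute_fvfm(0, 350), 1.0)
  expect_equal(compute_fvfm(350, 350), 0.0)
  expect_error(compute_fvfm(100, 0), class = "bioalbedo_invalid_measurement")
  expect_error(compute_fvfm(500, 400), class = "bioalbedo_invalid_measurement")

  expect_equal(compute_retr(0.6, 100), 30)
  expect_equal(compute_retr(0.75, 0), 0)
  expect_equal(compute_retr(0, 4000), 0)
  expect_error(compute_retr(1.2, 100), class = "bioalbedo_domain_error")

  expect_equal(compute_npq(400, 250), 0.375)
  expect_equal(compute_npq(400, 400), 0)
  expect_equal(compute_npq(400, 250, convention = "stern_volmer_prime"), 0.6)
  expect_warning(val <- compute_npq(400, 450), "clamped")
  expect_equal(val, 0)
})

test_that("light-response fits invert noiseless forward-generated curves", {
  cur <- gen_rlc(alpha = 0.3, ek = 200, beta = 0, noise_cv = 0, seed = 1)[[1]]
  f <- fit_rlc(cur)
  expect_lt(abs(f$alpha - 0.3) / 0.3, 1e-6)
  expect_lt(abs(f$rETRmax - 60) / 60, 1e-6)
  expect_lt(abs(f$Ek - 200) / 200, 1e-6)
  expect_true(f$converged)
  ## Ek identity holds by construction
  expect_equal(f$Ek, f$rETRmax / f$alpha, tolerance = 1e-12)

  ## the Webb form is available and recovers the same saturating curve
  fw <- fit_rlc(cur, model = "webb")
  expect_lt(abs(fw$alpha - 0.3) / 0.3, 1e-6)
  expect_equal(fw$beta, 0)

  ## with photoinhibition, rETRmax is the analytic curve maximum, not Ps
  fb <- fit_rlc(gen_rlc(alpha = 0.3, ek = 200, beta = 0.006)[[1]])
  expect_lt(abs(fb$beta - 0.006) / 0.006, 1e-4)
  expect_lt(abs(fb$rETRmax - 60) / 60, 1e-6)
  expect_gt(fb$Ps, fb$rETRmax)
})

test_that("degenerate and under-determined curves raise typed errors", {
  cur <- gen_rlc(alpha = 0.3, ek = 200)[[1]]
  dead <- cur
  dead$steps$F <- dead$steps$Fm_prime  # Y = 0 everywhere
  expect_error(fit_rlc(dead), class = "bioalbedo_degenerate_curve")
  short <- rlc_curve("s", 100, 400, E = c(10, 20, 30),
                     F = c(100, 100, 100), Fm_prime = c(400, 390, 380))
  expect_error(fit_rlc(short), class = "bioalbedo_insufficient_data")
  ## a fully shaded curve has no light information left
  expect_error(fit_rlc(apply_shading_correction(cur, 1)),
               class = "bioalbedo_degenerate_curve")
})

test_that("shading correction rescales both light axes and leaves alpha invariant", {
  cur <- gen_rlc(alpha = 0.3, ek = 938, beta = 0)[[1]]
  f0 <- fit_rlc(cur)

  ## identity case
  same <- fit_rlc(apply_shading_correction(cur, 0))
  expect_equal(same$Ek, f0$Ek, tolerance = 1e-12)

  ## half shading: alpha invariant, rETRmax and Ek halved
  fh <- fit_rlc(apply_shading_correction(cur, 0.5))
  expect_lt(abs(fh$alpha - f0$alpha) / f0$alpha, 1e-6)
  expect_lt(abs(fh$rETRmax - 0.5 * f0$rETRmax) / f0$rETRmax, 1e-6)
  expect_lt(abs(fh$Ek - 0.5 * f0$Ek) / f0$Ek, 1e-6)

  ## the phenolic fraction at the actinic wavelength shifts a whole-cell
  ## Ek of ~938 to the chloroplast level, 938 * 0.06 = 56.28
  fc <- fit_rlc(apply_shading_correction(cur, 0.94))
  expect_lt(abs(fc$Ek - 0.06 * f0$Ek) / f0$Ek, 1e-6)
  expect_equal(fc$Ek, 56.28, tolerance = 1e-4)
})

test_that("scaling the light axis scales rETRmax and Ek and not alpha", {
  cur <- gen_rlc(alpha = 0.25, ek = 400, beta = 0)[[1]]
  f0 <- fit_rlc(cur)
  s <- 2.5
  scaled <- rlc_curve(cur$sample_id, cur$dark_F0, cur$dark_Fm,
                      E = cur$steps$E * s, F = cur$steps$F,
                      Fm_prime = cur$steps$Fm_prime)
  fs <- fit_rlc(scaled)
  expect_lt(abs(fs$alpha - f0$alpha) / f0$alpha, 1e-6)
  expect_lt(abs(fs$rETRmax - s * f0$rETRmax) / (s * f0$rETRmax), 1e-6)
  expect_lt(abs(fs$Ek - s * f0$Ek) / (s * f0$Ek), 1e-6)
})

test_that("fitted saturating curves without photoinhibition are non-decreasing", {
  f <- fit_rlc(gen_rlc(alpha = 0.4, ek = 300, beta = 0)[[1]])
  pred <- platt_retr(seq(0, 4000, by = 10), f$alpha, f$Ps, f$beta)
  expect_true(all(diff(pred) >= -1e-12))
})

test_that("group summaries report mean, SD, SE and n per parameter", {
  mk <- function(ek) {
    f <- fit_rlc(gen_rlc(alpha = 0.3, ek = ek)[[1]])
    f
  }
  fits <- lapply(c(40, 46, 52), mk)
  tab <- compare_rlc_groups(fits, fits, labels = c("ctrl", "dtt"))
  ek_row <- tab[tab$parameter == "Ek" & tab$group == "ctrl", ]
  expect_equal(ek_row$mean, 46, tolerance = 1e-5)
  expect_equal(ek_row$se, 6 / sqrt(3), tolerance = 1e-4)
  expect_equal(ek_row$n, 3)
  ## identical groups differ by zero in every mean
  expect_equal(tab$mean[tab$group == "ctrl"], tab$mean[tab$group == "dtt"])
  ## degenerate single-fit group: SE is flagged missing
  tab1 <- compare_rlc_groups(fits[1], fits[2])
  expect_true(all(is.na(tab1$se)))
  expect_error(compare_rlc_groups(list(), fits),
               class = "bioalbedo_domain_error")
})

test_that("the long-format RLC CSV round-trips curves exactly", {
  curves <- gen_rlc(n = 2, alpha = 0.3, ek = 500, noise_cv = 0.05, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_rlc_csv(curves, path)
  back <- read_rlc_csv(path)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$steps$E, curves[[1]]$steps$E)
  expect_equal(back[[1]]$steps$Fm_prime, curves[[1]]$steps$Fm_prime,
               tolerance = 1e-12)
  expect_equal(back[[1]]$dark_Fm, curves[[1]]$dark_Fm)
})
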