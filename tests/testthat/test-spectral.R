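# Power-law exponent fits, the Rayleigh transition diameter and
# host-absorption peak detection.

test_that("an exact power law is recovered to high precision at any scale", {
  wl <- seq(800, 1000, by = 10)
  for (prefac in c(1e-3, 1, 2e7)) {
    fit <- fit_power_law(wl, prefac * wl^-3.3)
    expect_equal(fit$exponent, -3.3, tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
  flat <- fit_power_law(wl, rep(0.25, length(wl)))
  expect_equal(flat$exponent, 0, tolerance = 1e-12)
})

test_that("monotone decreasing scattering gives a negative exponent", {
  wl <- seq(800, 1000, by = 25)
  mu_s <- 0.5 * exp(-(wl - 800) / 300)
  expect_lt(fit_power_law(wl, mu_s)$exponent, 0)
})

test_that("power-law fitting rejects unusable input", {
  expect_error(fit_power_law(c(810, 900, 990), c(1, 1, 1)), "4 points")
  wl <- seq(800, 1000, 25)
  y <- rep(1, length(wl)); y[3] <- 0
  expect_error(fit_power_law(wl, y), "non-positive")
})

test_that("a 5 nm monodisperse silicon suspension reaches the Rayleigh slope", {
  tab <- ri_table(c(400, 1000), n = c(3.6, 3.6))     # constant index
  susp <- suspension(size_distribution(5, 0), 0.5, "water")
  sp <- ensemble_properties(susp, seq(800, 1000, by = 10), index_table = tab)
  fit <- fit_power_law(sp$wavelength_nm, sp$mu_s, c(800, 1000))
  expect_lt(abs(abs(fit$exponent) - 4.0), 0.05)
})

test_that("the Rayleigh condition d = lambda / 15 is linear and rounds as expected", {
  got <- rayleigh_upper_diameter(550)
  expect_equal(got$d_exact_nm, 550 / 15, tolerance = 1e-12)  # 36.67 nm
  expect_identical(got$d_rounded_nm, 37)
  expect_identical(rayleigh_upper_diameter(150)$d_exact_nm, 10)
  expect_equal(rayleigh_upper_diameter(1300)$d_exact_nm, 86.6667,
               tolerance = 1e-4)
  # linearity
  expect_equal(rayleigh_upper_diameter(1100)$d_exact_nm,
               2 * rayleigh_upper_diameter(550)$d_exact_nm, tolerance = 1e-12)
})

test_that("the water absorption band near 970 nm is found only for aqueous hosts", {
  wl <- seq(900, 1010, by = 10)
  water <- suspension(size_distribution(14, 10, "truncnorm"), 0.5, "water")
  sp_w <- ensemble_properties(water, wl)
  pk_w <- detect_absorption_peak(sp_w, window = c(930, 1010))
  expect_true(pk_w$found)
  expect_gte(pk_w$peak_wavelength_nm, 960)
  expect_lte(pk_w$peak_wavelength_nm, 980)

  ethanol <- suspension(size_distribution(25, 13, "truncnorm"), 0.5, "ethanol")
  sp_e <- ensemble_properties(ethanol, wl)
  pk_e <- detect_absorption_peak(sp_e, window = c(930, 1010))
  expect_false(pk_e$found)
})

test_that("strictly monotone absorption has no peak; bad windows error", {
  sp <- optical_spectrum(seq(900, 1010, 10), mu_a = seq(0.1, 0.01,
                                                        length.out = 12),
                         mu_s = rep(0.1, 12), g = rep(0.5, 12))
  expect_false(detect_absorption_peak(sp, c(930, 1010))$found)
  expect_error(detect_absorption_peak(sp, c(800, 1010)), "support")
})

test_that("the spectral report bundles all three analyses", {
  wl <- seq(790, 1010, by = 10)
  susp <- suspension(size_distribution(14, 10, "truncnorm"), 0.5, "water")
  sp <- ensemble_properties(susp, wl)
  path <- withr::local_tempfile(fileext = ".json")
  rep <- spectral_report(sp, fit_range = c(800, 1000), path = path)
  expect_lt(rep$power_law$exponent, 0)
  expect_identical(rep$rayleigh_diameter$d_rounded_nm, 37)
  expect_true(rep$absorption_peak$found)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$power_law$exponent, rep$power_law$exponent,
               tolerance = 1e-12)
})
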