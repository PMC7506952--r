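# Single-particle Mie series and polydisperse ensemble averaging.

test_that("Mie cross-section reaches the Rayleigh limit for small spheres", {
  m <- complex(real = 3.6)
  for (d in c(2, 5, 10)) {
    for (wl in c(600, 800, 1000)) {
      mie <- mie_single(d, wl, m, n_host = 1.33)
      ray <- oracle_rayleigh(d, wl, m, 1.33)
      expect_lt(abs(mie$C_sca - ray) / ray, 0.01)
      if (mie$x < 0.05)
        expect_lt(abs(mie$g), 1e-3)  # deep Rayleigh regime is symmetric
    }
  }
})

test_that("Mie results match an independent high-precision evaluation", {
  # frozen from a 40-digit spherical-Bessel (mpmath) evaluation of the
  # same scattering problem
  cases <- list(
    list(m = complex(real = 1.55), x = 5.213,
         Qsca = 3.10499591508, g = 0.633104415995),
    list(m = complex(real = 1.5, imaginary = 0.5), x = 2.5,
         Qsca = 1.09707181909, Qabs = 1.46580167837, g = 0.748905978949),
    list(m = complex(real = 3.6 / 1.33), x = 1.0,
         Qsca = 3.09723306684, g = 0.521617743862),
    list(m = complex(real = 2.8, imaginary = 0.1), x = 0.8,
         Qsca = 0.815567659633, Qabs = 0.237476754542, g = 0.313800623869))
  wl <- 550
  for (cs in cases) {
    d <- cs$x * wl / pi
    got <- mie_single(d, wl, cs$m, n_host = 1)
    geom_cs <- pi * (d / 2)^2
    expect_equal(got$C_sca / geom_cs, cs$Qsca, tolerance = 1e-8)
    expect_equal(got$g, cs$g, tolerance = 1e-8)
    if (!is.null(cs$Qabs))
      expect_equal(got$C_abs / geom_cs, cs$Qabs, tolerance = 1e-8)
  }
})

test_that("index-matched particles neither scatter nor absorb", {
  got <- mie_single(50, 600, complex(real = 1.33), n_host = 1.33)
  expect_identical(got$C_sca, 0)
  expect_identical(got$C_abs, 0)
})

test_that("Rayleigh cross-section follows the d^6 / lambda^-4 laws", {
  m <- complex(real = 3.6)
  base <- rayleigh_cross_section(10, 500, m, 1.33)
  expect_equal(rayleigh_cross_section(10, 1000, m, 1.33), base / 16,
               tolerance = 1e-12)
  expect_equal(rayleigh_cross_section(20, 500, m, 1.33), base * 64,
               tolerance = 1e-12)
  expect_equal(base, oracle_rayleigh(10, 500, m, 1.33), tolerance = 1e-12)
})

test_that("oversized spheres raise a truncation error instead of silently truncating", {
  expect_error(mie_single(5e5, 400, complex(real = 1.5), 1.33),
               "size parameter")
})

test_that("zero-width distribution reproduces the single-particle result", {
  susp <- suspension(size_distribution(37, 0), concentration = 0.5,
                     host = "water")
  tab <- ri_silicon()
  sp <- ensemble_properties(susp, c(550, 800))
  one <- mie_single(37, 550, ri_eval(tab, 550), 1.33)
  f_vol <- 0.5e-3 / 2.33
  N <- f_vol / (pi / 6 * 37^3)
  expect_equal(sp$mu_s[1], N * one$C_sca * 1e6, tolerance = 1e-12)
  expect_equal(sp$g[1], one$g, tolerance = 1e-12)
})

test_that("ensemble properties are linear in concentration and reduce to host at zero", {
  dist <- size_distribution(25, 13, "truncnorm")
  wl <- c(500, 700, 970)
  s1 <- ensemble_properties(suspension(dist, 0.25, "water"), wl)
  s2 <- ensemble_properties(suspension(dist, 0.5, "water"), wl)
  expect_equal(s2$mu_s, 2 * s1$mu_s, tolerance = 1e-10)
  host <- host_medium("water")
  expect_equal(s2$mu_a - host$mu_a(wl), 2 * (s1$mu_a - host$mu_a(wl)),
               tolerance = 1e-10)
  s0 <- ensemble_properties(suspension(dist, 0, "water"), wl)
  expect_equal(s0$mu_s, rep(0, 3))
  expect_equal(s0$mu_a, host$mu_a(wl), tolerance = 1e-12)
})

test_that("small-particle lognormal ensemble mu_s decreases monotonically beyond 550 nm", {
  # mean 14 nm / SD 10 nm lognormal ensemble in water
  susp <- suspension(size_distribution(14, 10, "lognormal"), 0.5, "water")
  wl <- seq(550, 1000, by = 50)
  sp <- ensemble_properties(susp, wl)
  expect_true(all(diff(sp$mu_s) < 0))
})

test_that("ensemble spectral slope stays at the Rayleigh exponent or below", {
  # all-small (d < 50 nm) ensembles with constant index sit at the Rayleigh
  # slope; the O(x^2) finite-size correction can steepen the local log-log
  # slope by a few percent before the Mie flattening takes over
  tab <- ri_table(c(400, 1000), n = c(3.6, 3.6))   # constant, transparent
  for (mean_d in c(10, 25, 40)) {
    sd_d <- min(mean_d / 4, (50 - mean_d) / 4.5)  # keep all mass below 50 nm
    susp <- suspension(size_distribution(mean_d, sd_d, "truncnorm"),
                       0.5, "water")
    sp <- ensemble_properties(susp, seq(800, 1000, 25), index_table = tab)
    slope <- fit_power_law(sp$wavelength_nm, sp$mu_s, c(800, 1000))$exponent
    expect_lte(abs(slope), 4 * 1.03)
  }
})
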