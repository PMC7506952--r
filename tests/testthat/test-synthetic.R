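# Scenario catalogue and the synthetic measurement generator.

test_that("scenario ensembles reproduce the catalogued size statistics", {
  cases <- list(list(label = "mesoporous_water", mean = 14, sd = 10),
                list(label = "heavilydoped_sinw_ethanol", mean = 28, sd = 9),
                list(label = "microporous_water", mean = 65, sd = 22))
  for (cs in cases) {
    sc <- sinp_scenario(cs$label, seed = 101)
    x <- sample_sizes(sc, 1e5)
    expect_lt(abs(mean(x) - cs$mean), 0.5)
    expect_lt(abs(stats::sd(x) - cs$sd), 0.5)
    expect_true(all(x > 0))
  }
})

test_that("the bimodal microporous-in-water ensemble really has two modes", {
  sc <- sinp_scenario("microporous_water", seed = 3)
  x <- sample_sizes(sc, 5e4)
  dens <- stats::density(x)
  # local maxima of the kernel density estimate
  y <- dens$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  modes <- dens$x[peaks[y[peaks] > 0.25 * max(y)]]
  expect_gte(length(modes), 2)
})

test_that("a zero-variance scenario distribution is degenerate", {
  sc <- sinp_scenario("mesoporous_water",
                      distribution = size_distribution(37, 0), seed = 2)
  expect_equal(sample_sizes(sc, 10), rep(37, 10))
})

test_that("scenario sampling is reproducible from the scenario seed", {
  a <- sample_sizes(sinp_scenario("mesoporous_ethanol", seed = 7), 100)
  b <- sample_sizes(sinp_scenario("mesoporous_ethanol", seed = 7), 100)
  expect_identical(a, b)
})

test_that("all eight scenarios build and produce finite forward spectra", {
  wl <- c(450, 700, 950)
  for (lab in sinp_scenarios()$label) {
    sc <- sinp_scenario(lab)
    tr <- ensemble_properties(as_suspension(sc), wl)
    expect_true(all(is.finite(tr$mu_a)) && all(is.finite(tr$mu_s)))
    expect_true(all(tr$mu_s > 0))
  }
})

test_that("small-particle scenarios stay within the expected mu_s envelope", {
  # the smallest ensembles, whose forward spectra sit on the measured scale
  wl <- seq(400, 1000, by = 50)
  for (lab in c("mesoporous_water", "lowdoped_sinw_ethanol",
                "heavilydoped_sinw_ethanol")) {
    tr <- ensemble_properties(as_suspension(sinp_scenario(lab)), wl)
    expect_true(all(tr$mu_s >= 0.001 & tr$mu_s <= 1),
                label = paste(lab, "mu_s in [0.001, 1]"))
  }
})

test_that("the generator is exact at zero noise and reproducible with a seed", {
  sc <- sinp_scenario("mesoporous_water", multiplicative_sd = 0,
                      additive_sd = 0, seed = 17)
  wl <- c(600, 800, 970)
  run <- synthesize_spectra(sc, wavelengths = wl,
                            config = sim_config(n_photons = 5e3, seed = 23))
  expect_identical(run$spectra$T_C, run$clean$T_C)
  expect_identical(run$spectra$R_D, run$clean$R_D)
  run2 <- synthesize_spectra(sc, wavelengths = wl,
                             config = sim_config(n_photons = 5e3, seed = 23))
  expect_identical(run$spectra, run2$spectra)
  expect_equal(run$ground_truth$mu_a, run2$ground_truth$mu_a)
  # noise on: channels differ from clean but stay in range
  sc_n <- sinp_scenario("mesoporous_water", seed = 17)
  run_n <- synthesize_spectra(sc_n, wavelengths = wl,
                              config = sim_config(n_photons = 5e3, seed = 23))
  expect_false(identical(run_n$spectra$T_C, run_n$clean$T_C))
  expect_true(all(unlist(run_n$spectra[c("T_C", "T_D", "R_D")]) >= 0))
})

test_that("aqueous ground truth shows strong blue absorption fading by 750 nm", {
  sc <- sinp_scenario("mesoporous_water")
  wl <- seq(400, 1000, by = 50)
  tr <- ensemble_properties(as_suspension(sc), wl)
  vis <- wl <= 750
  expect_true(all(diff(tr$mu_a[vis]) < 0))      # monotone decrease 400-750
  expect_lt(tr$mu_a[wl == 750], 0.05)           # near zero by 750 nm
  expect_gt(tr$mu_a[1], 10 * tr$mu_a[wl == 750])
})
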