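# Monte-Carlo photon transport: analytic oracles, conservation, determinism.

test_that("index-matched lossless slab transmits everything", {
  geom <- cuvette_geometry(n_wall = 1, n_suspension = 1)
  tr <- mc_simulate(geom, 0, 0, 0, sim_config(n_photons = 1e4, seed = 1))
  expect_identical(tr$T_C, 1)
  expect_identical(tr$R_D, 0)
  expect_identical(tr$A_medium, 0)
})

test_that("Fresnel reflectance matches closed forms", {
  expect_equal(fresnel_unpolarized(1.33, 1.33, 0.5), 0)
  expect_equal(fresnel_unpolarized(1, 1.45, 1), (0.45 / 2.45)^2,
               tolerance = 1e-12)
  # beyond the critical angle: total internal reflection
  cos_crit <- sqrt(1 - (1 / 1.45)^2)
  expect_equal(fresnel_unpolarized(1.45, 1, cos_crit * 0.5), 1)
  # symmetric in propagation direction at normal incidence
  expect_equal(fresnel_unpolarized(1.33, 1.45, 1),
               fresnel_unpolarized(1.45, 1.33, 1), tolerance = 1e-12)
})

test_that("Henyey-Greenstein sampling has the right branches and first moment", {
  u <- c(0, 0.25, 0.5, 0.75, 1)
  expect_equal(hg_sample(0, u), 2 * u - 1)
  set.seed(99)
  draws <- hg_sample(0.9, stats::runif(1e6))
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.9), 3 * se)
  expect_true(all(draws >= -1 & draws <= 1))
})

test_that("unscattered transmission matches the Beer-Lambert x Fresnel etalon oracle", {
  geom <- cuvette_geometry()
  for (mu_a in c(0.02, 0.1, 0.2)) {
    tr <- mc_simulate(geom, mu_a, 0, 0, sim_config(n_photons = 2e5, seed = 7))
    expected <- oracle_tc_no_scatter(mu_a, geom)
    expect_lt(abs(tr$T_C - expected), 3 * tr$se_T_C)
    expect_identical(tr$T_D, 0)
  }
})

test_that("weight ledger balances to launched weight for any parameters", {
  geom <- cuvette_geometry()
  cases <- list(c(0, 0, 0), c(0.2, 0, 0), c(0, 0.6, 0.95), c(0.05, 0.3, 0.7),
                c(0.2, 0.6, 0.5), c(0.01, 0.02, 0))
  for (cs in cases) {
    tr <- mc_simulate(geom, cs[1], cs[2], cs[3],
                      sim_config(n_photons = 1e5, seed = 13))
    total <- tr$T_C + tr$T_D + tr$R_D + tr$A_medium + tr$side_loss
    expect_lt(abs(total - 1), 1e-9)
  }
})

test_that("identical seeds give bit-identical results, different seeds differ", {
  geom <- cuvette_geometry()
  cfg <- sim_config(n_photons = 5e4, seed = 21)
  a <- mc_simulate(geom, 0.05, 0.3, 0.7, cfg)
  b <- mc_simulate(geom, 0.05, 0.3, 0.7, cfg)
  expect_identical(unclass(a), unclass(b))
  c <- mc_simulate(geom, 0.05, 0.3, 0.7, sim_config(n_photons = 5e4, seed = 22))
  expect_false(identical(a$T_C, c$T_C))
})

test_that("T_C falls with mu_a and mu_s; R_D rises with mu_s", {
  geom <- cuvette_geometry()
  cfg <- function(s) sim_config(n_photons = 2e5, seed = s)
  tc_mua <- vapply(c(0, 0.1, 0.2), function(mu_a)
    mc_simulate(geom, mu_a, 0.2, 0.7, cfg(31))$T_C, numeric(1))
  expect_true(all(diff(tc_mua) < 0))
  runs <- lapply(c(0, 0.3, 0.6), function(mu_s)
    mc_simulate(geom, 0.05, mu_s, 0.7, cfg(32)))
  expect_true(all(diff(vapply(runs, `[[`, numeric(1), "T_C")) < 0))
  expect_true(all(diff(vapply(runs, `[[`, numeric(1), "R_D")) > 0))
})

test_that("Monte-Carlo standard errors shrink as 1/sqrt(n)", {
  geom <- cuvette_geometry()
  ns <- c(1e4, 2e4, 4e4, 8e4)
  ses <- vapply(seq_along(ns), function(i)
    mc_simulate(geom, 0.05, 0.3, 0.7,
                sim_config(n_photons = ns[i], seed = 40 + i))$se_T_C,
    numeric(1))
  slope <- stats::coef(stats::lm(log(ses) ~ log(ns)))[2]
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("invalid transport inputs are rejected", {
  geom <- cuvette_geometry()
  expect_error(mc_simulate(geom, -0.1, 0.3, 0.7), "mu_a")
  expect_error(mc_simulate(geom, 0.1, 0.3, 1.5), "g")
  expect_error(cuvette_geometry(collimated_half_angle = 95))
})
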