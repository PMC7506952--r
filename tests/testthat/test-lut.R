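# Lookup-table construction, the inversion functional and the argmin search.

test_that("the inversion functional obeys its algebra", {
  expect_identical(functional_f(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3)), 0)
  expect_identical(functional_f(2 * c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3)), 3)
  expect_equal(functional_f(c(0.11, 0.20, 0.30), c(0.10, 0.20, 0.30)), 0.01,
               tolerance = 1e-12)
  tr <- measurement_triple(0.4, 0.1, 0.05)
  expect_identical(functional_f(tr, tr), 0)
})

test_that("a zero measured channel is rejected by name", {
  expect_error(functional_f(c(0.1, 0.2, 0.3), c(0.1, 0, 0.3)), "T_D")
  expect_error(functional_f(c(0.1, 0.2, 0.3), c(0, 0.2, 0.3)), "T_C")
  expect_error(lut_invert(shared_lut(), c(0.1, 0.2, 0)), "R_D")
})

test_that("a single-node table reproduces one simulate call exactly", {
  geom <- shared_geom()
  cfg <- sim_config(n_photons = 1e4, seed = 5)
  lut <- lut_build(geom, lut_grid(mu_a = 0.05, mu_s = 0.3, g = 0.6), cfg)
  expect_equal(nrow(lut$nodes), 1L)
  cfg_node <- cfg
  cfg_node$seed <- lut$nodes$seed[1]
  direct <- mc_simulate(geom, 0.05, 0.3, 0.6, cfg_node)
  expect_identical(lut$nodes$T_C, direct$T_C)
  expect_identical(lut$nodes$T_D, direct$T_D)
  expect_identical(lut$nodes$R_D, direct$R_D)
})

test_that("rebuilding with the same base seed is bit-identical", {
  geom <- shared_geom()
  grid <- lut_grid(mu_a = c(0, 0.1), mu_s = c(0.1, 0.3), g = c(0, 0.6))
  a <- lut_build(geom, grid, sim_config(n_photons = 5e3, seed = 9))
  b <- lut_build(geom, grid, sim_config(n_photons = 5e3, seed = 9))
  expect_identical(a$nodes, b$nodes)
})

test_that("inverting exact node values returns that node with F = 0", {
  lut <- shared_lut()
  ok <- which(lut$nodes$T_C > 0 & lut$nodes$T_D > 0 & lut$nodes$R_D > 0)
  for (i in ok[c(1L, ceiling(length(ok) / 2), length(ok))]) {
    res <- lut_invert(lut, c(lut$nodes$T_C[i], lut$nodes$T_D[i],
                             lut$nodes$R_D[i]))
    expect_equal(res$node_index, i)
    expect_identical(res$F_min, 0)
    expect_lte(res$F_min, res$runner_up_F)
  }
})

test_that("the argmin equals a brute-force scan with the functional", {
  lut <- shared_lut()
  set.seed(3)
  for (rep in 1:10) {
    m <- c(runif(1, 0.05, 0.8), runif(1, 0.01, 0.3), runif(1, 0.01, 0.2))
    res <- lut_invert(lut, m)
    brute <- vapply(seq_len(nrow(lut$nodes)), function(i)
      functional_f(c(lut$nodes$T_C[i], lut$nodes$T_D[i], lut$nodes$R_D[i]),
                   m), numeric(1))
    expect_equal(res$node_index, which.min(brute))
    expect_equal(res$F_min, min(brute), tolerance = 1e-14)
  }
})

test_that("ties break towards the lexicographically smallest node", {
  # duplicate channel values at two nodes: the smaller (mu_a, mu_s, g) wins
  lut <- shared_lut()
  nd <- lut$nodes
  j0 <- which(nd$T_C > 0 & nd$T_D > 0 & nd$R_D > 0)[1]
  j <- which(nd$mu_a == max(nd$mu_a))
  j <- j[length(j)]
  nd[j, c("T_C", "T_D", "R_D")] <- nd[j0, c("T_C", "T_D", "R_D")]
  lut2 <- lut
  lut2$nodes <- nd
  res <- lut_invert(lut2, unlist(nd[j0, c("T_C", "T_D", "R_D")]))
  expect_equal(res$node_index, j0)
})

test_that("tables serialise and reload bit-exactly", {
  lut <- shared_lut()
  path <- withr::local_tempfile(fileext = ".csv")
  lut_write(lut, path)
  back <- lut_read(path)
  expect_identical(back$nodes, lut$nodes)
  expect_identical(back$axis_mu_a, lut$axis_mu_a)
  expect_identical(back$axis_mu_s, lut$axis_mu_s)
  expect_identical(back$axis_g, lut$axis_g)
  expect_identical(unclass(back$geometry), unclass(lut$geometry))
  expect_identical(unclass(back$config), unclass(lut$config))
})

test_that("refinement never worsens the functional and flags itself", {
  lut <- shared_lut()
  m <- c(0.45, 0.12, 0.05)
  coarse <- lut_invert(lut, m)
  fine <- lut_invert(lut, m, refine = TRUE)
  expect_lte(fine$F_min, coarse$F_min)
  if (fine$F_min < coarse$F_min) expect_true(fine$interpolated)
})
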