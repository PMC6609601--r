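test_that("photons cross an empty grid without depositing", {
  grid <- list(dims = c(10L, 10L, 10L), origin = c(0, 0, 0), voxel_cm = 1,
               material = rep(0L, 1000), organ = rep(1L, 1000), n_organs = 1L)
  e_grid <- 5:150
  mu <- matrix(1e-12, 1, length(e_grid))
  n <- 500
  set.seed(1)
  res <- transport_photons(grid, mu, mu * 0, e_grid,
                           cbind(rep(-1, n), 5, 5), cbind(rep(1, n), 0, 0),
                           rep(60, n))
  expect_equal(res$organ_dep_kev, 0)
  expect_equal(res$n_uncollided_exits, n)
})

test_that("uncollided slab transmission matches Beer-Lambert", {
  sc <- gen_slab_scenario(mu = 0.2, thickness = 5)  # mu*t = 1
  r <- slab_transmission(sc, n_histories = 1e4, seed = 2)
  expect_lt(abs(r$transmission - exp(-1)), 4 * r$se)
  sc0 <- gen_slab_scenario(mu = 1, thickness = 0)
  expect_equal(slab_transmission(sc0, 2000, seed = 3)$transmission, 1)
})

test_that("forced photoelectric absorption conserves energy exactly", {
  # opaque slab: every history deposits its full energy
  sc <- gen_slab_scenario(mu = 100, thickness = 10)
  n <- 2000
  set.seed(4)
  src <- cbind(rep(-0.5, n), 5, 5)
  dir <- cbind(rep(1, n), 0, 0)
  res <- transport_photons(sc$grid, sc$mu_lin, sc$mu_compton, sc$e_grid,
                           src, dir, rep(60, n), photoelectric_only = TRUE)
  expect_equal(res$total_deposited_kev, n * 60, tolerance = 1e-9)
  expect_equal(res$organ_dep_kev, n * 60, tolerance = 1e-9)
  expect_equal(res$total_emitted_kev, n * 60)
})

test_that("full simulations conserve energy and are seed-reproducible", {
  ph <- shared_phantom()
  g <- exposure_geometry()
  s1 <- run_simulation(g, phantom = ph, n_histories = 5000, seed = 10)
  s2 <- run_simulation(g, phantom = ph, n_histories = 5000, seed = 10)
  expect_identical(s1$organ_doses, s2$organ_doses)
  expect_identical(s1$effective$effective_dose, s2$effective$effective_dose)
  expect_lte(s1$deposited_kev, s1$emitted_kev)
  expect_gt(s1$deposited_kev, 0)
  expect_error(run_simulation(g, phantom = ph, n_histories = 100),
               "at least 1000")
  expect_error(run_simulation(g, phantom = ph, n_histories = 5000,
                              seed = "abc"), "seed")
})

test_that("organ doses are exactly linear in the dose-area product", {
  ph <- shared_phantom()
  s1 <- run_simulation(exposure_geometry(dap = 60), phantom = ph,
                       n_histories = 5000, seed = 11)
  s2 <- run_simulation(exposure_geometry(dap = 120), phantom = ph,
                       n_histories = 5000, seed = 11)
  expect_equal(s2$organ_doses$dose_ugy, 2 * s1$organ_doses$dose_ugy,
               tolerance = 1e-12)
})

test_that("a beam that misses the phantom warns and tallies nothing", {
  ph <- shared_phantom()
  g <- exposure_geometry(reference_point = c(0, -3, 200))
  expect_warning(s <- run_simulation(g, phantom = ph, n_histories = 1000,
                                     seed = 12), "did not intersect")
  expect_true(all(s$organ_doses$dose_ugy == 0))
})

test_that("per-organ standard errors shrink like one over sqrt(n)", {
  ph <- shared_phantom()
  g <- exposure_geometry()
  ns <- c(1e3, 1e4, 1e5)
  se <- vapply(seq_along(ns), function(i) {
    s <- run_simulation(g, phantom = ph, n_histories = ns[i], seed = 20 + i)
    s$organ_doses$se_ugy[s$organ_doses$organ == "skin"]
  }, numeric(1))
  slope <- unname(coef(lm(log(se) ~ log(ns)))[2])
  expect_gt(slope, -0.6)
  expect_lt(slope, -0.4)
})
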