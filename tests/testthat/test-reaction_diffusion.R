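# Field integrator: decay closed form, mass conservation under no-flux
# boundaries, refined-timestep oracle, secretion-map rules and COM sampling.

test_that("uniform field with pure decay follows the discrete closed form", {
  f <- matrix(3.5, 9, 7)
  delta <- 0.008
  n <- 40
  for (i in seq_len(n)) f <- step_fields(f, diffusion = 0.2, decay = delta)
  expect_equal(unique(as.vector(round(f, 12))),
               round(3.5 * (1 - delta)^n, 12), tolerance = 1e-6)
})

test_that("pure diffusion conserves mass to 1e-8 relative over 1000 steps", {
  set.seed(1)
  f <- matrix(runif(30 * 20), 30, 20)
  m0 <- total_field(f)
  for (i in 1:1000) f <- step_fields(f, diffusion = 0.24, decay = 0)
  expect_equal(total_field(f), m0, tolerance = 1e-8)
  expect_true(all(f >= 0))
})

test_that("a boundary-adjacent point source loses no mass through the walls", {
  f <- matrix(0, 15, 15)
  src <- matrix(0, 15, 15); src[1, 1] <- 2
  m <- 0
  for (i in 1:200) { f <- step_fields(f, 0.25, 0, secretion = src); m <- m + 2 }
  expect_equal(total_field(f), m, tolerance = 1e-10)
})

test_that("point-source profile matches a 4x-refined-timestep reference within 1% L2", {
  src <- matrix(0, 21, 21); src[11, 11] <- 1
  coarse <- matrix(0, 21, 21)
  for (i in 1:100) coarse <- step_fields(coarse, 0.9, 0, secretion = src,
                                         substeps = 5)
  fine <- matrix(0, 21, 21)
  for (i in 1:100) fine <- step_fields(fine, 0.9, 0, secretion = src,
                                       substeps = 20)
  rel_l2 <- sqrt(sum((coarse - fine)^2)) / sqrt(sum(fine^2))
  expect_lt(rel_l2, 0.01)
})

test_that("stability bound violations are refused", {
  f <- matrix(1, 5, 5)
  expect_error(step_fields(f, diffusion = 1, decay = 0, substeps = 2),
               "stability")
  expect_silent({ f2 <- step_fields(f, diffusion = 1, decay = 0, substeps = 4) })
})

test_that("secretion maps follow the cell-state rules", {
  p <- fixture_params()
  # one M2 macrophage with no ECM contact, INF = 0 everywhere
  sim <- fixture_sim(list(list(x = 3:5, y = 3:5, type = "Macrophage")),
                     params = p)
  maps <- build_secretion_map(sim)
  grid <- lattice_matrix(sim)
  on_cell <- grid == 1
  expect_true(all(maps$pdgf[on_cell] > 0))
  expect_true(all(maps$pdgf[!on_cell] == 0))
  expect_equal(total_field(maps$pdgf), p$secretion$pdgf_mac_m2)
  expect_true(all(maps$mmp == 0))
  expect_true(all(maps$csf1 == 0))

  # no cells -> all-zero maps
  sim0 <- simulation_from_grid(matrix(0L, 6, 6), integer(0), p)
  expect_true(all(vapply(build_secretion_map(sim0), total_field, 0) == 0))

  # fibrolytic-phase senescent cell: CSF1 + INF + MMP, no PDGF
  sim2 <- fixture_sim(list(list(x = 3:5, y = 3:5,
                                type = "SenescentMyofibroblast")), params = p)
  sim2$flags$sen_clock <- p$rules$t_nis_days + 1
  maps2 <- build_secretion_map(sim2)
  expect_true(all(vapply(maps2[c("csf1", "inf", "mmp")], total_field, 0) > 0))
  expect_equal(total_field(maps2$pdgf), 0)

  # fibrogenic-phase senescent cell: PDGF only
  sim3 <- fixture_sim(list(list(x = 3:5, y = 3:5,
                                type = "SenescentMyofibroblast")), params = p)
  sim3$flags$sen_clock <- 0
  maps3 <- build_secretion_map(sim3)
  expect_gt(total_field(maps3$pdgf), 0)
  expect_equal(total_field(maps3$inf), 0)

  # macrophage touching ECM secretes MMP even while M2
  sim4 <- fixture_sim(list(list(x = 3:5, y = 3:5, type = "Macrophage"),
                           list(x = 6, y = 3, type = "ECM")), params = p)
  maps4 <- build_secretion_map(sim4)
  expect_gt(total_field(maps4$mmp), 0)

  # activated fibroblast secretes CSF1 only while touching a macrophage
  sim5 <- fixture_sim(list(list(x = 2:4, y = 2:4, type = "Fibroblast"),
                           list(x = 5:7, y = 2:4, type = "Macrophage")),
                      params = p)
  sim5$flags$activated[1] <- TRUE
  maps5 <- build_secretion_map(sim5)
  expect_gt(sum(maps5$csf1[lattice_matrix(sim5) == 1]), 0)
  sim6 <- fixture_sim(list(list(x = 2:4, y = 2:4, type = "Fibroblast")),
                      params = p)
  sim6$flags$activated[1] <- TRUE
  expect_equal(total_field(build_secretion_map(sim6)$csf1), 0)
})

test_that("field_at_com uses the round-half-up nearest pixel", {
  f <- matrix(seq_len(36), 6, 6)
  expect_equal(field_at_com(f, c(3, 4)), f[3, 4])
  expect_equal(field_at_com(f, c(3.9, 3.9)), f[4, 4])
  expect_equal(field_at_com(f, c(3.5, 3.2)), f[4, 3])
  expect_equal(field_at_com(matrix(5, 4, 4), c(2.2, 3.7)), 5)
  expect_error(field_at_com(f, c(40, 2)), "out of bounds")
})

test_that("total_field sums pixels", {
  expect_equal(total_field(matrix(0, 4, 4)), 0)
  f <- matrix(0, 4, 4); f[2, 3] <- 7
  expect_equal(total_field(f), 7)
  set.seed(2)
  g <- matrix(rexp(20), 5, 4)
  expect_equal(total_field(g), sum(as.vector(g)))
})

test_that("fields stay non-negative through integrated simulation steps", {
  p <- fixture_params()
  sim <- build_initial_state(p, seed = 4)
  run_mcs(sim, 60, fields = TRUE)
  behaviour_sweep(sim)
  for (f in field_names())
    expect_true(all(field_matrix(sim, f) >= 0))
})
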