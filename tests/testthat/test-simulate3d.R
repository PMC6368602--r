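test_that("deformation matrices have the stated forms", {
  sh <- deformation_matrix(deform_params("shear", lam = 0.05))
  expect_equal(sh, matrix(c(1, 0, 0, 0, 1, 0, 0.05, 0, 1), 3L, 3L))
  th <- 3.5 * pi / 180
  ro <- deformation_matrix(deform_params("rotation", theta_deg = 3.5))
  expect_equal(ro, matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0,
                            0, 0, 1), 3L, 3L))
  expect_equal(det(ro), 1)
})

test_that("shear and rotation steps fix their center and match the matrix", {
  set.seed(4)
  pts <- matrix(runif(30, 0, 100), 10L, 3L)
  ctr <- c(49.5, 49.5, 49.5)
  sh <- shear_step(pts, 0.05, center = ctr)
  expect_equal(shear_step(matrix(ctr, 1L), 0.05, center = ctr),
               matrix(ctr, 1L))
  A <- deformation_matrix(deform_params("shear", lam = 0.05))
  expect_equal(sh, sweep(sweep(pts, 2L, ctr) %*% t(A), 2L, ctr, "+"),
               tolerance = 1e-12)
  ro <- rotate_step(pts, 3.5, center = ctr)
  R <- deformation_matrix(deform_params("rotation", theta_deg = 3.5))
  expect_equal(ro, sweep(sweep(pts, 2L, ctr) %*% t(R), 2L, ctr, "+"),
               tolerance = 1e-12)
  expect_equal(rotate_step(pts, 0), pts)
})

test_that("generated fibers lie inside the box with sane lengths", {
  set.seed(21)
  p <- network_gen_params(box_size = 80, n_fibers = 40L)
  fibers <- generate_network(p)
  expect_gt(length(fibers), 30L)
  for (f in fibers) {
    expect_true(all(f >= 0 & f <= 79))
    expect_gte(nrow(f), 2L)
  }
  lens <- vapply(fibers, function(f) curve_length(ft_curve(f)), numeric(1))
  expect_gt(mean(lens), 20)
  expect_lt(mean(lens), 50)
})

test_that("simulated truth transforms exactly by the per-step matrix", {
  sim <- simulate_deformation_sequence(
    network_gen_params(box_size = 30, n_fibers = 4L, fiber_length = 15,
                       seed = 5L),
    deform_params("shear", lam = 0.05, n_steps = 2L))
  expect_length(sim$stacks, 3L)
  expect_equal(dim(sim$stacks[[1L]]), c(30, 30, 30))
  for (t in 1:2) {
    for (i in seq_along(sim$truth$frames[[t]])) {
      p0 <- sim$truth$frames[[t]][[i]]$points
      p1 <- sim$truth$frames[[t + 1L]][[i]]$points
      pred <- sweep(sweep(p0, 2L, sim$center) %*% t(sim$matrix),
                    2L, sim$center, "+")
      expect_equal(unname(p1), unname(pred), tolerance = 1e-9)
    }
  }
})

test_that("the 3D simulator is reproducible", {
  np <- network_gen_params(box_size = 24, n_fibers = 3L, fiber_length = 10,
                           seed = 2L)
  dp <- deform_params("rotation", n_steps = 1L)
  s1 <- simulate_deformation_sequence(np, dp)
  s2 <- simulate_deformation_sequence(np, dp)
  expect_identical(s1$stacks, s2$stacks)
})
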