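test_that("the movie simulator is reproducible and well-formed", {
  p <- growth_params(image_size = c(64L, 64L), n_frames = 3L, seed = 9L)
  s1 <- simulate_filament_sequence(p)
  s2 <- simulate_filament_sequence(p)
  expect_identical(s1$images, s2$images)
  expect_length(s1$images, 3L)
  expect_equal(dim(s1$images[[1L]]), c(64L, 64L))
  expect_true(all(s1$images[[1L]] >= 0))
})

test_that("growth adds fixed-length segments at the stated acceptance rate", {
  set.seed(11)
  p <- growth_params()
  st <- new_filament_state(c(50, 50), 0, p)
  st <- grow_filament_step(st, p)
  expect_equal(st$n_added, nrow(st$points) - 1L)
  expect_gt(st$n_added, 190L)   # Binomial(300, 0.8), far tails excluded
  expect_lt(st$n_added, 290L)
  seg <- sqrt(rowSums(diff(st$points[, 1:2])^2))
  expect_equal(seg, rep(p$delta, length(seg)), tolerance = 1e-9)
})

test_that("persistence length estimation recognizes a straight walk", {
  straight <- cbind(seq(0, 100, by = 0.05), 0)
  expect_equal(estimate_persistence_length(straight), Inf)
  expect_error(estimate_persistence_length(straight[1:10, ]),
               "insufficient data")
})

test_that("ground truth stays inside the field of view", {
  p <- growth_params(image_size = c(96L, 96L), n_frames = 10L, seed = 3L,
                     n_initial = 6L)
  sim <- simulate_filament_sequence(p)
  for (gt in sim$truth$frames) {
    for (cv in gt) {
      expect_true(all(cv$points[, 1:2] >= 0 & cv$points[, 1:2] <= 95))
    }
  }
  # filament identities persist across frames
  ids_first <- vapply(sim$truth$frames[[1L]], `[[`, integer(1), "id")
  ids_last <- vapply(sim$truth$frames[[10L]], `[[`, integer(1), "id")
  expect_true(all(ids_first %in% ids_last))
})

test_that("rendering places intensity on the filament", {
  pts <- cbind(seq(10, 50, by = 0.05), 30, 0)
  p <- growth_params(image_size = c(64L, 64L), noise_max = 0)
  img <- render_frame_2d(list(list(points = pts,
                                   brightness = rep(5, nrow(pts)))), p)
  expect_gt(img[31, 31], 10)       # on the line (row = y + 1, col = x + 1)
  expect_lt(img[56, 31], 1e-6)     # far off the line
})
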