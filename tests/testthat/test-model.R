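test_that("curve construction validates input and pads 2D points", {
  cv <- ft_curve(cbind(c(0, 1), c(0, 0)), id = 3L, frame = 2L)
  expect_s3_class(cv, "ft_curve")
  expect_equal(ncol(cv$points), 3L)
  expect_equal(cv$points[, "z"], c(0, 0))
  expect_equal(cv$id, 3L)
  expect_equal(cv$frame, 2L)
  expect_error(ft_curve(cbind(c(0, NA), c(0, 1))), "finite")
  expect_error(ft_curve(matrix(0, 2, 4)), "2 or 3 columns")
})

test_that("curve length handles open and closed polylines", {
  tri <- cbind(c(0, 3, 3), c(0, 0, 4))
  expect_equal(curve_length(ft_curve(tri)), 7)
  expect_equal(curve_length(ft_curve(tri, closed = TRUE)), 12)
  expect_error(curve_length(ft_curve(cbind(1, 1))), "at least 2")
})

test_that("resampling gives uniform spacing and preserves endpoints", {
  set.seed(42)
  t <- seq(0, pi / 2, length.out = 40)
  quarter <- ft_curve(cbind(10 * cos(t), 10 * sin(t)))
  rs <- resample_curve(quarter, 0.5)
  seg <- sqrt(rowSums(diff(rs$points)^2))
  expect_lt(diff(range(seg)), 1e-3)          # uniform up to polyline kinks
  expect_equal(rs$points[1L, ], quarter$points[1L, ])
  expect_equal(rs$points[nrow(rs$points), ],
               quarter$points[nrow(quarter$points), ])
  expect_equal(curve_length(rs), 10 * pi / 2, tolerance = 1e-3)

  ring <- ft_curve(cbind(5 * cos(t * 4)[-40], 5 * sin(t * 4)[-40]),
                   closed = TRUE)
  rr <- resample_curve(ring, 1)
  expect_true(rr$closed)
  expect_equal(curve_length(rr), 2 * pi * 5, tolerance = 0.05)
})

test_that("tangents of a straight curve are constant unit vectors", {
  cv <- ft_curve(cbind(seq(0, 10, by = 0.5), seq(0, 5, by = 0.25)))
  tg <- curve_tangents(cv)
  expect_equal(sqrt(rowSums(tg^2)), rep(1, nrow(tg)))
  d <- c(2, 1, 0) / sqrt(5)
  expect_true(all(abs(sweep(tg, 2L, d)) < 1e-9))
})

test_that("curve tips point outward", {
  cv <- ft_curve(cbind(seq(0, 20), rep(0, 21)))
  tips <- curve_tips(cv)
  expect_length(tips, 2L)
  expect_equal(tips[[1L]]$end, "head")
  expect_equal(tips[[1L]]$tangent, c(-1, 0, 0), tolerance = 1e-9)
  expect_equal(tips[[2L]]$tangent, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(tips[[2L]]$position, c(20, 0, 0), ignore_attr = TRUE)
  expect_length(curve_tips(ft_curve(cbind(c(0, 1, 1), c(0, 0, 1)),
                                    closed = TRUE)), 0L)
})

test_that("frame and track constructors validate their invariants", {
  c1 <- ft_curve(cbind(0:1, 0:1), id = 1L)
  c2 <- ft_curve(cbind(2:3, 0:1), id = 1L)
  expect_error(ft_frame(0L, curves = list(c1, c2)), "unique")
  expect_error(ft_track(1L, c(0L, 0L), c(1L, 2L)), "strictly increasing")
  expect_error(ft_track(1L, c(0L, 1L), 1L), "mismatch")
  expect_error(tracking_params(eta = -1), "eta")
  expect_error(detection_params(ridge_threshold = 0), "positive")
})
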