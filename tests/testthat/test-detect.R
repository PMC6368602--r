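test_that("gaussian smoothing preserves a constant image", {
  img <- matrix(5, 32, 32)
  sm <- gaussian_smooth(img, 1.5)
  expect_equal(sm, img, tolerance = 1e-9)
})

test_that("a straight bright line is extracted accurately", {
  p0 <- c(12, 20); p1 <- c(52, 44)
  img <- line_image(p0, p1)
  curves <- extract_centerlines(img)
  expect_length(curves, 1L)
  cv <- curves[[1L]]
  expect_false(cv$closed)
  # endpoints sit where the intensity crosses the ridge threshold, slightly
  # beyond the deposited ends
  expect_lt(abs(curve_length(cv) - sqrt(sum((p1 - p0)^2))), 2.5)
  expect_lt(max_line_deviation(cv$points, p0, p1), 0.5)
  ends <- cv$points[c(1L, nrow(cv$points)), 1:2]
  d_ends <- min(sqrt(sum((ends[1L, ] - p0)^2)) + sqrt(sum((ends[2L, ] - p1)^2)),
                sqrt(sum((ends[1L, ] - p1)^2)) + sqrt(sum((ends[2L, ] - p0)^2)))
  expect_lt(d_ends, 3)
})

test_that("a crossing is dissected at one junction with four tips", {
  img <- multi_line_image(list(list(c(10, 32), c(54, 32)),
                               list(c(32, 10), c(32, 54))))
  fr <- detect_frame(img)
  expect_length(fr$junctions, 1L)
  jn <- fr$junctions[[1L]]
  expect_lt(sqrt(sum((jn$position[1:2] - c(32, 32))^2)), 2)
  expect_length(jn$tips, 4L)
  expect_length(fr$curves, 4L)

  spliced <- local_match_frame(fr)
  expect_length(spliced$curves, 2L)
  lens <- sort(vapply(spliced$curves, curve_length, numeric(1)))
  expect_true(all(abs(lens - 44) < 2.5))
})

test_that("short spurious blobs are rejected by min_curve_length", {
  img <- line_image(c(30, 30), c(32, 30))  # 2 px: below the 5 px minimum
  expect_length(extract_centerlines(img), 0L)
})

test_that("a bright ring is detected as a closed curve", {
  t <- seq(0, 2 * pi, length.out = 400)[-400]
  pts <- cbind(32 + 15 * cos(t), 32 + 15 * sin(t), 0)
  params <- growth_params(image_size = c(64L, 64L), psf_sigma = 1.5,
                          noise_max = 0)
  img <- render_frame_2d(list(list(points = pts,
                                   brightness = rep(40, nrow(pts)))),
                         params)
  fr <- detect_frame(img)
  expect_length(fr$curves, 1L)
  expect_true(fr$curves[[1L]]$closed)
  expect_equal(curve_length(fr$curves[[1L]]), 2 * pi * 15, tolerance = 0.05)
})

test_that("detection works on 3D stacks", {
  fib <- rbind(c(8, 15, 10), c(40, 22, 30))
  np <- network_gen_params(box_size = 48, noise_max = 0)
  stk <- render_stack(list(fib), np)
  curves <- extract_centerlines(stk)
  expect_length(curves, 1L)
  expect_equal(curve_length(curves[[1L]]),
               sqrt(sum((fib[2L, ] - fib[1L, ])^2)), tolerance = 0.08)
})
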