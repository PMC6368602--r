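test_that("curve distance is symmetric and exact on parallel lines", {
  a <- ft_curve(cbind(0:20, rep(0, 21)), frame = 0L)
  b <- ft_curve(cbind(0:20, rep(4, 21)), id = 2L, frame = 1L)
  expect_equal(curve_distance(a, a$points), 0)
  expect_equal(curve_distance(a, b), 4)
  expect_equal(curve_distance(a, b), curve_distance(b, a))
})

test_that("edge weight applies the gap penalty and saturates at eta", {
  p <- tracking_params(eta = 20, c = 1)
  a <- ft_curve(cbind(0:20, rep(0, 21)), frame = 0L)
  mk <- function(fr, off) ft_curve(cbind(0:20, rep(off, 21)),
                                   id = 2L, frame = fr)
  expect_equal(edge_weight(a, mk(1L, 4), p), 4)
  expect_equal(edge_weight(a, mk(2L, 4), p), 4 * exp(1))
  expect_equal(edge_weight(a, mk(4L, 4), p), 20)  # capped
  expect_error(edge_weight(mk(1L, 4), a, p), "forward")
  # monotone in the gap until saturation
  w <- vapply(1:6, function(g) edge_weight(a, mk(g, 2), p), numeric(1))
  expect_true(all(diff(w) >= 0))
  expect_true(all(w <= p$eta))
  expect_equal(w[6L], p$eta)
})

test_that("the graph keeps only forward, near, in-gap edges", {
  p <- tracking_params(eta = 5, max_frame_gap = 2L)
  mk <- function(fr, id, off) ft_curve(cbind(0:10, rep(off, 11)),
                                       id = id, frame = fr)
  frames <- list(
    ft_frame(0L, curves = list(mk(0L, 1L, 0), mk(0L, 2L, 30))),
    ft_frame(1L, curves = list(mk(1L, 1L, 1))),
    ft_frame(3L, curves = list(mk(3L, 1L, 2))))
  g <- build_graph(frames, p)
  expect_equal(nrow(g$vertices), 4L)
  # no intra-frame edges, nothing to the far curve (distance 30 > eta),
  # and frame 0 -> 3 exceeds the gap
  key <- paste(g$vertices$frame[g$edges$from],
               g$vertices$frame[g$edges$to])
  expect_setequal(unique(key), c("0 1", "1 3"))
  expect_false(any(g$edges$from == 2L | g$edges$to == 2L))
})

test_that("a drifting curve is covered by a single track", {
  mk <- function(fr, off) ft_curve(cbind(0:10, rep(off, 11)),
                                   id = 1L, frame = fr)
  frames <- lapply(0:3, function(t) ft_frame(t, curves = list(mk(t, t))))
  res <- track_frames(frames)
  expect_length(res$tracks, 1L)
  expect_equal(res$tracks[[1L]]$frames, 0:3)
})

test_that("tracks re-link across a missed frame", {
  mk <- function(fr, off) ft_curve(cbind(0:10, rep(off, 11)),
                                   id = 1L, frame = fr)
  frames <- list(ft_frame(0L, curves = list(mk(0L, 0))),
                 ft_frame(1L, curves = list()),
                 ft_frame(2L, curves = list(mk(2L, 1))))
  res <- track_frames(frames, tracking_params(max_frame_gap = 3L))
  expect_length(res$tracks, 1L)
  expect_equal(res$tracks[[1L]]$frames, c(0L, 2L))
  # with the gap disabled the two sightings stay separate
  res1 <- track_frames(frames, tracking_params(max_frame_gap = 1L))
  expect_length(res1$tracks, 2L)
})

test_that("the path cover objective matches brute-force enumeration", {
  for (seed in 1:25) {
    inst <- random_cover_instance(seed)
    g <- build_graph(inst$frames, inst$params)
    tracks <- solve_path_cover(g, inst$params)
    # every vertex covered exactly once
    got <- do.call(rbind, lapply(tracks, function(tr) {
      cbind(tr$frames, tr$curve_ids)
    }))
    expect_equal(nrow(got), nrow(g$vertices))
    expect_false(anyDuplicated(got) > 0)
    expect_equal(path_cover_cost(tracks, g),
                 enumerate_path_cover_cost(g), tolerance = 1e-9)
  }
})
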