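straight_tip <- function(curve_id, tangent, position = c(0, 0, 0),
                         end = "tail") {
  ft_tip(curve_id, end, position, tangent)
}

test_that("orientation dissimilarity follows the tip-tangent angle", {
  t1 <- straight_tip(1L, c(1, 0, 0))
  t2 <- straight_tip(2L, c(-1, 0, 0))
  t3 <- straight_tip(3L, c(0, 1, 0))
  expect_equal(d_ori(t1, t2), 0)            # facing across the junction
  expect_equal(d_ori(t1, t3), 0.5)          # perpendicular
  expect_equal(d_ori(t1, straight_tip(4L, c(1, 0, 0))), 1)  # same direction
  expect_equal(d_ori(t1, straight_tip(1L, c(-1, 0, 0))), 1) # same curve
})

test_that("one-way distance weights proximity by tangent alignment", {
  u <- ft_curve(cbind(0:20, rep(0, 21)))
  r <- ft_curve(cbind(0:20, rep(3, 21)))
  expect_equal(one_way_distance(u, u), 0)
  expect_equal(one_way_distance(u, r), 3 * exp(-1), tolerance = 1e-9)
  perp <- ft_curve(cbind(rep(10, 21), seq(3, 23)))
  # tangents orthogonal: no alignment discount at the nearest points
  expect_gt(one_way_distance(u, perp), 3 * exp(-1))
})

test_that("closest previous curve is the one-way-distance argmin", {
  prev <- ft_frame(0L, curves = list(
    ft_curve(cbind(0:10, rep(0, 11)), id = 1L),
    ft_curve(cbind(0:10, rep(20, 11)), id = 2L)))
  u <- ft_curve(cbind(0:10, rep(19, 11)), id = 7L, frame = 1L)
  cp <- closest_prev_curve(u, prev)
  expect_equal(cp$id, 2L)
  expect_equal(cp$f, 1 * exp(-1), tolerance = 1e-9)
  expect_true(is.na(closest_prev_curve(u, NULL)$id))
})

test_that("temporal dissimilarity distinguishes shared predecessors", {
  t1 <- straight_tip(1L, c(1, 0, 0)); t2 <- straight_tip(2L, c(-1, 0, 0))
  expect_equal(d_tem(t1, t2, list()), 0)    # no information
  same <- list("1" = list(id = 5L, f = 0.2), "2" = list(id = 5L, f = 0.9))
  expect_equal(d_tem(t1, t2, same), 0.7, tolerance = 1e-12)
  diff_pred <- list("1" = list(id = 5L, f = 0.2),
                    "2" = list(id = 6L, f = 0.2))
  expect_equal(d_tem(t1, t2, diff_pred), 1)
  far <- list("1" = list(id = 5L, f = 0), "2" = list(id = 5L, f = 7))
  expect_equal(d_tem(t1, t2, far), 1)       # clamped
})

test_that("junction matching pairs facing tips and rejects the rest", {
  jx <- ft_junction(1L, 0L, c(0, 0, 0), tips = list(
    straight_tip(1L, c(1, 0, 0)), straight_tip(2L, c(-1, 0, 0)),
    straight_tip(3L, c(0, 1, 0)), straight_tip(4L, c(0, -1, 0))))
  pg <- match_tips_at_junction(jx)
  expect_length(pg$pairs, 2L)
  got <- lapply(pg$pairs, function(pr) {
    sort(c(pr[[1L]]$curve_id, pr[[2L]]$curve_id))
  })
  expect_true(list(c(1L, 2L)) %in% got && list(c(3L, 4L)) %in% got)
  expect_length(pg$unpaired, 0L)
})

test_that("odd junctions pair the collinear tips and leave the spur", {
  # a 3-tip junction: the through pair must form even though a cyclic
  # assignment relaxation would be cheaper than pair + single
  jx <- ft_junction(1L, 0L, c(0, 0, 0), tips = list(
    straight_tip(1L, c(1, 0, 0)), straight_tip(2L, c(-1, 0, 0)),
    straight_tip(3L, c(0, 1, 0))))
  pg <- match_tips_at_junction(jx)
  expect_length(pg$pairs, 1L)
  expect_setequal(c(pg$pairs[[1L]][[1L]]$curve_id,
                    pg$pairs[[1L]][[2L]]$curve_id), c(1L, 2L))
  expect_length(pg$unpaired, 1L)
  expect_equal(pg$unpaired[[1L]]$curve_id, 3L)
})

test_that("non-collinear tips never splice, even when unopposed", {
  jx <- ft_junction(1L, 0L, c(0, 0, 0), tips = list(
    straight_tip(1L, c(1, 0, 0)), straight_tip(2L, c(0, 1, 0))))
  pg <- match_tips_at_junction(jx)
  expect_length(pg$pairs, 0L)
  expect_length(pg$unpaired, 2L)
})

test_that("splicing concatenates chains and conserves points", {
  c1 <- ft_curve(cbind(0:5, rep(0, 6)), id = 1L)
  c2 <- ft_curve(cbind(5:10, rep(0, 6)), id = 2L)
  fr <- ft_frame(0L, curves = list(c1, c2))
  pairing <- structure(list(junction_id = 1L, pairs = list(list(
    ft_tip(1L, "tail", c(5, 0, 0), c(1, 0, 0)),
    ft_tip(2L, "head", c(5, 0, 0), c(-1, 0, 0)))),
    unpaired = list()), class = "ft_tip_pairing")
  sp <- splice_curves(fr, list(pairing))
  expect_length(sp$curves, 1L)
  expect_equal(nrow(sp$curves[[1L]]$points), 11L)  # shared point deduplicated
  expect_equal(curve_length(sp$curves[[1L]]), 10)
  expect_equal(unname(sp$splice_map[c("1", "2")]), c(1L, 1L))
  # point conservation: spliced points = union of segment points
  seg_pts <- unique(do.call(rbind, lapply(sp$segments, `[[`, "points")))
  spl_pts <- do.call(rbind, lapply(sp$curves, `[[`, "points"))
  expect_setequal(apply(spl_pts, 1L, paste, collapse = ","),
                  apply(seg_pts, 1L, paste, collapse = ","))
})

test_that("a pairing chain that closes on itself yields a ring", {
  c1 <- ft_curve(rbind(c(0, 0), c(1, 1), c(2, 0)), id = 1L)
  c2 <- ft_curve(rbind(c(0, 0), c(1, -1), c(2, 0)), id = 2L)
  fr <- ft_frame(0L, curves = list(c1, c2))
  pairings <- list(
    structure(list(junction_id = 1L, pairs = list(list(
      ft_tip(1L, "head", c(0, 0, 0), c(-1, 1, 0)),
      ft_tip(2L, "head", c(0, 0, 0), c(-1, -1, 0)))),
      unpaired = list()), class = "ft_tip_pairing"),
    structure(list(junction_id = 2L, pairs = list(list(
      ft_tip(1L, "tail", c(2, 0, 0), c(1, 1, 0)),
      ft_tip(2L, "tail", c(2, 0, 0), c(1, -1, 0)))),
      unpaired = list()), class = "ft_tip_pairing"))
  sp <- splice_curves(fr, pairings)
  expect_length(sp$curves, 1L)
  expect_true(sp$curves[[1L]]$closed)
  expect_equal(nrow(sp$curves[[1L]]$points), 4L)  # shared ends deduplicated
})

test_that("a filament abutting another is spliced through end to end", {
  img <- multi_line_image(list(list(c(10, 32), c(54, 32)),
                               list(c(32, 10), c(32, 31))))
  fr <- detect_frame(img)
  spliced <- local_match_frame(fr)
  lens <- sort(vapply(spliced$curves, curve_length, numeric(1)))
  expect_length(lens, 2L)
  expect_lt(abs(lens[2L] - 44), 2.5)   # through-line stays whole
  expect_lt(abs(lens[1L] - 21), 2.5)   # the abutting spur
})
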