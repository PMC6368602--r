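test_that("length series follow tracks through their frames", {
  mk <- function(fr, id, len) ft_curve(cbind(seq(0, len), rep(id, len + 1)),
                                       id = id, frame = fr)
  frames <- list(ft_frame(0L, curves = list(mk(0L, 1L, 10L))),
                 ft_frame(1L, curves = list(mk(1L, 1L, 14L))))
  ser <- length_series(list(ft_track(1L, 0:1, c(1L, 1L))), frames)
  expect_length(ser, 1L)
  expect_equal(ser[[1L]]$lengths, c(10, 14))
  expect_error(
    length_series(list(ft_track(1L, 0:1, c(1L, 9L))), frames),
    "missing curve")
})

test_that("the histogram Gaussian fit ignores the stall peak and tails", {
  set.seed(31)
  dl <- c(rnorm(600, 12, 2), runif(200, -1, 1), rep(c(-40, 45), 15L))
  series <- lapply(seq_along(dl), function(i) {
    list(track_id = i, frames = 0:1, lengths = c(100, 100 + dl[i]))
  })
  fit <- fit_elongation_rate(series)
  expect_equal(fit$mean, 12, tolerance = 0.5)
  expect_gte(fit$n_excluded, 200L)
  expect_equal(fit$n_used + fit$n_excluded, length(dl))
  expect_error(fit_elongation_rate(series[1:3]), "insufficient data")
})

test_that("rate conversion reproduces the documented example", {
  # 20.8 px per 120 s at 0.17 um/px and 370 subunits/um
  rate <- convert_elongation_rate(20.8, 120, 0.17, 370)
  expect_equal(round(rate, 1), 10.9)
  expect_error(convert_elongation_rate(1, 0, 0.17, 370), "positive")
})

test_that("constriction rate is the exact least-squares slope", {
  ser <- list(frames = 0:5, lengths = 100 - 2.5 * (0:5))
  expect_equal(constriction_rate(ser), -2.5, tolerance = 1e-12)
  expect_error(constriction_rate(list(frames = 0:1, lengths = c(1, 2))),
               "insufficient data")
})

test_that("nematic order distinguishes aligned, mixed and isotropic sets", {
  par <- matrix(rep(c(1, 2, 3), 50), ncol = 3, byrow = TRUE)
  expect_equal(nematic_order(par), 1, tolerance = 1e-9)
  two_pop <- rbind(matrix(rep(c(1, 0, 0), 100), ncol = 3, byrow = TRUE),
                   matrix(rep(c(0, 1, 0), 100), ncol = 3, byrow = TRUE))
  expect_equal(nematic_order(two_pop), 0.25, tolerance = 1e-12)
  set.seed(8)
  iso <- matrix(rnorm(3 * 20000), ncol = 3)
  expect_lt(abs(nematic_order(iso)), 0.02)
  # rotation invariance
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(nematic_order(two_pop %*% t(R)), 0.25, tolerance = 1e-9)
})

test_that("psi is zero for exact affine motion and 90 for orthogonal", {
  A <- deformation_matrix(deform_params("shear", lam = 0.05))
  v <- c(10, 4, 7)
  expect_equal(angular_deviation_psi(v, as.numeric(A %*% v), A), 0,
               tolerance = 1e-6)
  expect_equal(angular_deviation_psi(c(1, 0, 0), c(0, 1, 0), diag(3)), 90)
  # axis sign is ignored
  expect_equal(angular_deviation_psi(v, -as.numeric(A %*% v), A), 0,
               tolerance = 1e-6)
})

test_that("azimuth drift unwraps across the axis-symmetry boundary", {
  angs <- 85 + 5 * (0:4)   # crosses 90 degrees, where the axis flips sign
  curves <- lapply(0:4, function(t) {
    a <- angs[t + 1L] * pi / 180
    ft_curve(cbind(c(0, 30 * cos(a)), c(0, 30 * sin(a)), c(0, 0)),
             id = 1L, frame = t)
  })
  frames <- lapply(0:4, function(t) ft_frame(t, curves = curves[t + 1L]))
  dr <- angle_drift(list(ft_track(1L, 0:4, rep(1L, 5L))), frames)
  expect_equal(dr$dphi, rep(5, 4L), tolerance = 1e-9)
  expect_equal(dr$dtheta, rep(0, 4L), tolerance = 1e-9)
})

test_that("affine recovery is exact on noiseless ground truth", {
  A <- deformation_matrix(deform_params("shear", lam = 0.05))
  ctr <- rep(49.5, 3L)
  tt <- affine_truth_tracks(A, ctr, seed = 2L)
  set.seed(3)
  rec <- recover_affine(tt$tracks, tt$frames, frame_k = 0L, n_triplets = 10L)
  expect_lt(max(abs(rec$A - A)), 1e-6)
  set.seed(3)
  rec2 <- recover_affine(tt$tracks, tt$frames, frame_k = 0L,
                         n_triplets = 10L, normalize = "none",
                         average = "mean")
  expect_lt(max(abs(rec2$A - A)), 1e-6)
  R <- deformation_matrix(deform_params("rotation", theta_deg = 3.5))
  tr <- affine_truth_tracks(R, ctr, seed = 4L)
  set.seed(5)
  recR <- recover_affine(tr$tracks, tr$frames, frame_k = 0L)
  expect_lt(max(abs(recR$A - R)), 1e-6)
})

test_that("precision and recall count each truth link once", {
  links <- function(m) {
    data.frame(frame_a = m[, 1L], key_a = m[, 2L],
               frame_b = m[, 3L], key_b = m[, 4L])
  }
  truth <- links(rbind(c(0, 1, 1, 1), c(0, 2, 1, 2)))
  pred <- links(rbind(c(0, 1, 1, 1), c(0, 1, 1, 1), c(0, 3, 1, 3)))
  pr <- precision_recall(pred, truth)
  expect_equal(pr$TP, 1L)
  expect_equal(pr$recall, 0.5)          # duplicates cannot inflate recall
  expect_equal(pr$precision, 2 / 3)     # both duplicates are correct links
  expect_equal(pr$FN, 1L)
  empty <- precision_recall(links(matrix(numeric(), 0, 4)), truth)
  expect_true(is.na(empty$precision))
  expect_equal(empty$recall, 0)
})
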