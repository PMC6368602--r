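#' Growth-model parameters for elongating 2D filaments
#'
#' Filaments are discrete semiflexible random walks: segments of constant
#' length `delta` are appended at one end (the fast-growing barbed end), each
#' turning by a Gaussian angle of standard deviation `sigma_theta` relative
#' to the previous one, which gives persistence length delta/sigma_theta^2
#' (222 px at the defaults). Per frame, `attempts_per_frame` additions are
#' attempted and each accepted with `accept_prob`, so the mean elongation
#' rate is attempts * p * delta (12 px/frame at the defaults).
#'
#' @param delta segment length in pixels.
#' @param sigma_theta per-segment angular standard deviation (radians).
#' @param attempts_per_frame segment addition attempts per frame.
#' @param accept_prob acceptance probability per attempt.
#' @param brightness mean brightness deposited per segment.
#' @param brightness_jitter fractional uniform jitter of segment brightness.
#' @param psf_sigma Gaussian rendering kernel sigma in pixels.
#' @param noise_max per-pixel additive noise is Uniform(0, noise_max).
#' @param image_size integer (width, height) of the rendered frames.
#' @param n_frames number of frames.
#' @param n_initial filaments nucleated before the first frame.
#' @param nucleation_rate Poisson mean of new filaments per frame.
#' @param seed RNG seed used by [simulate_filament_sequence].
#' @return A `ft_growth_params` list.
#' @export
growth_params <- function(delta = 0.05, sigma_theta = 0.015,
                          attempts_per_frame = 300L, accept_prob = 0.8,
                          brightness = 5, brightness_jitter = 0.10,
                          psf_sigma = 1.5, noise_max = 10,
                          image_size = c(256L, 256L), n_frames = 15L,
                          n_initial = 4L, nucleation_rate = 0.3,
                          seed = 1L) {
  stopifnot(delta > 0, sigma_theta >= 0, accept_prob >= 0, accept_prob <= 1)
  structure(list(delta = delta, sigma_theta = sigma_theta,
                 attempts_per_frame = as.integer(attempts_per_frame),
                 accept_prob = accept_prob, brightness = brightness,
                 brightness_jitter = brightness_jitter,
                 psf_sigma = psf_sigma, noise_max = noise_max,
                 image_size = as.integer(rep_len(image_size, 2L)),
                 n_frames = as.integer(n_frames),
                 n_initial = as.integer(n_initial),
                 nucleation_rate = nucleation_rate,
                 seed = as.integer(seed)),
            class = "ft_growth_params")
}

#' Nucleate a filament growth state
#'
#' @param origin length-2 (x, y) nucleation position in pixels.
#' @param angle initial heading in radians.
#' @param params [growth_params] (supplies brightness and its jitter).
#' @return A filament state for [grow_filament_step]: list with `points`,
#'   `angle` and per-segment `brightness`.
#' @export
new_filament_state <- function(origin, angle, params) {
  list(points = matrix(c(origin, 0), nrow = 1L,
                       dimnames = list(NULL, c("x", "y", "z"))),
       angle = angle,
       brightness = params$brightness *
         runif(1, 1 - params$brightness_jitter, 1 + params$brightness_jitter))
}

#' Grow a filament by one frame of segment additions
#'
#' Attempts `attempts_per_frame` segment additions, each accepted with
#' probability `accept_prob`; every accepted segment of length `delta` turns
#' by a fresh Normal(0, sigma_theta) angle. Growth happens at one end only.
#'
#' @param state filament state: list with `points` (n x 3 matrix), `angle`
#'   (current heading, radians) and per-segment `brightness` vector.
#' @param params [growth_params].
#' @return Updated state; the number of segments added is in `$n_added`.
#' @export
grow_filament_step <- function(state, params) {
  k <- rbinom(1L, params$attempts_per_frame, params$accept_prob)
  state$n_added <- k
  if (k == 0L) return(state)
  turns <- rnorm(k, 0, params$sigma_theta)
  angles <- state$angle + cumsum(turns)
  last <- state$points[nrow(state$points), 1:2]
  xs <- last[1] + cumsum(params$delta * cos(angles))
  ys <- last[2] + cumsum(params$delta * sin(angles))
  jit <- runif(k, 1 - params$brightness_jitter, 1 + params$brightness_jitter)
  state$points <- rbind(state$points, cbind(xs, ys, 0))
  state$brightness <- c(state$brightness, params$brightness * jit)
  state$angle <- angles[k]
  state
}

#' Estimate persistence length from tangent-tangent correlation
#'
#' For a 2D semiflexible walk, the mean cosine of the tangent angle change
#' over contour distance s decays as exp(-s / (2 l_p)). The estimate is the
#' slope of a log-linear fit of the pooled correlation over lags where the
#' correlation still exceeds 0.5.
#'
#' @param trajectories one n x >=2 point matrix or a list of them (uniform
#'   segment length assumed, as produced by the growth model).
#' @param max_lag_frac largest lag as a fraction of the shortest trajectory.
#' @return Persistence length in pixels (`Inf` for a perfectly straight
#'   walk).
#' @export
estimate_persistence_length <- function(trajectories, max_lag_frac = 0.2) {
  if (is.matrix(trajectories)) trajectories <- list(trajectories)
  n_seg <- vapply(trajectories, nrow, integer(1)) - 1L
  if (sum(n_seg) < 1000L) {
    stop("insufficient data: need at least 1000 segments in total")
  }
  # segment length (assumed constant) from the first trajectory
  p1 <- trajectories[[1L]]
  delta <- mean(sqrt(rowSums((p1[-1L, 1:2, drop = FALSE] -
                                p1[-nrow(p1), 1:2, drop = FALSE])^2)))
  max_lag <- max(2L, floor(min(n_seg) * max_lag_frac))
  lags <- unique(round(seq(1L, max_lag, length.out = min(60L, max_lag))))
  corr <- vapply(lags, function(k) {
    num <- 0; cnt <- 0
    for (p in trajectories) {
      seg <- p[-1L, 1:2, drop = FALSE] - p[-nrow(p), 1:2, drop = FALSE]
      ang <- atan2(seg[, 2L], seg[, 1L])
      m <- length(ang) - k
      if (m < 1L) next
      num <- num + sum(cos(ang[(1L + k):(m + k)] - ang[1:m]))
      cnt <- cnt + m
    }
    num / cnt
  }, numeric(1))
  keep <- corr > 0.5
  if (sum(keep) < 2L) keep <- corr > 0.2
  if (all(corr[keep] > 1 - 1e-12)) return(Inf)
  fit <- lm(log(corr[keep]) ~ I(lags[keep] * delta))
  slope <- coef(fit)[2L]
  if (slope >= 0) return(Inf)
  as.numeric(-1 / (2 * slope))
}

# deposit weighted points into a 2D pixel grid (nearest pixel)
deposit_points_2d <- function(points, weights, nx, ny) {
  img <- matrix(0, nrow = ny, ncol = nx)
  col <- round(points[, 1L]) + 1L
  row <- round(points[, 2L]) + 1L
  keep <- col >= 1L & col <= nx & row >= 1L & row <= ny
  if (!any(keep)) return(img)
  idx <- (col[keep] - 1L) * ny + row[keep]
  agg <- rowsum(weights[keep], idx)
  img[as.integer(rownames(agg))] <- agg
  img
}

#' Render one synthetic 2D frame
#'
#' Deposits each filament's walk points (with their per-segment brightness)
#' onto the pixel grid, convolves with a normalized Gaussian kernel of sigma
#' `psf_sigma`, and adds independent Uniform(0, noise_max) noise per pixel.
#'
#' @param filaments list of filament states (see [grow_filament_step]) or of
#'   point matrices (then unit brightness is used).
#' @param params [growth_params].
#' @return Matrix of size `image_size[2]` x `image_size[1]` (rows = y).
#' @export
render_frame_2d <- function(filaments, params = growth_params()) {
  nx <- params$image_size[1L]; ny <- params$image_size[2L]
  img <- matrix(0, nrow = ny, ncol = nx)
  for (f in filaments) {
    pts <- if (is.matrix(f)) f else f$points
    w <- if (is.matrix(f)) rep(1, nrow(pts)) else {
      b <- f$brightness
      if (length(b) < nrow(pts)) b <- c(b, rep(b[length(b)], nrow(pts) - length(b)))
      b[seq_len(nrow(pts))]
    }
    img <- img + deposit_points_2d(pts, w, nx, ny)
  }
  img <- gaussian_smooth_zero(img, params$psf_sigma)
  if (params$noise_max > 0) {
    img <- img + matrix(runif(nx * ny, 0, params$noise_max), ny, nx)
  }
  img
}

# Gaussian smoothing with zero padding (mass-preserving in the interior),
# used for rendering; detection uses the edge-replicating variant
gaussian_smooth_zero <- function(image, sigma) {
  d <- dim(image); nd <- length(d)
  sigma <- rep_len(sigma, nd)
  out <- image
  for (dd in seq_len(nd)) {
    s <- sigma[dd]
    if (s <= 0 || d[dd] == 1L) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-(seq(-r, r))^2 / (2 * s^2)); w <- w / sum(w)
    acc <- array(0, d)
    for (k in seq(-r, r)) acc <- acc + w[k + r + 1L] * shift_zero(out, k, dd)
    out <- acc
  }
  out
}

shift_zero <- function(a, k, dim) {
  d <- dim(a); n <- d[dim]
  src <- seq_len(n) - k
  ok <- src >= 1L & src <= n
  idx <- ifelse(ok, src, 1L)
  res <- shift_pick(a, idx, dim)
  zero_pick(res, !ok, dim)
}

shift_pick <- function(a, idx, dim) {
  d <- dim(a)
  if (length(d) == 2L) {
    if (dim == 1L) a[idx, , drop = FALSE] else a[, idx, drop = FALSE]
  } else {
    if (dim == 1L) a[idx, , , drop = FALSE]
    else if (dim == 2L) a[, idx, , drop = FALSE]
    else a[, , idx, drop = FALSE]
  }
}

zero_pick <- function(a, mask, dim) {
  if (!any(mask)) return(a)
  d <- dim(a)
  if (length(d) == 2L) {
    if (dim == 1L) a[mask, ] <- 0 else a[, mask] <- 0
  } else {
    if (dim == 1L) a[mask, , ] <- 0
    else if (dim == 2L) a[, mask, ] <- 0
    else a[, , mask] <- 0
  }
  a
}

#' Simulate a time-lapse movie of elongating filaments
#'
#' Nucleates `n_initial` filaments at uniform random positions and
#' orientations, grows every filament each frame by the acceptance process
#' of [grow_filament_step], nucleates Poisson(`nucleation_rate`) new
#' filaments per frame, and renders each frame. Ground-truth centerlines
#' (resampled at 1 px) and the filament identity per frame are returned
#' alongside the images.
#'
#' @param params [growth_params]; `params$seed` seeds the RNG.
#' @return List with `images` (list of matrices), `truth` (class
#'   `ft_ground_truth`: per-frame lists of ground-truth [ft_curve] whose ids
#'   are filament identities), and `states` (final filament states).
#' @export
simulate_filament_sequence <- function(params = growth_params()) {
  set.seed(params$seed)
  nx <- params$image_size[1L]; ny <- params$image_size[2L]
  margin <- 10
  nucleate <- function(n) {
    lapply(seq_len(n), function(i) {
      new_filament_state(c(runif(1, margin, nx - 1 - margin),
                           runif(1, margin, ny - 1 - margin)),
                         runif(1, 0, 2 * pi), params)
    })
  }
  states <- nucleate(params$n_initial)
  images <- vector("list", params$n_frames)
  truth_frames <- vector("list", params$n_frames)
  next_id <- length(states)
  ids <- seq_len(next_id)
  for (t in seq_len(params$n_frames)) {
    if (t > 1L) {
      n_new <- rpois(1L, params$nucleation_rate)
      if (n_new > 0L) {
        states <- c(states, nucleate(n_new))
        ids <- c(ids, next_id + seq_len(n_new))
        next_id <- next_id + n_new
      }
    }
    states <- lapply(states, grow_filament_step, params = params)
    images[[t]] <- render_frame_2d(states, params)
    gt <- list()
    for (i in seq_along(states)) {
      pts <- states[[i]]$points
      if (nrow(pts) < 2L) next
      # ground truth covers only what is rendered: clip the centerline at
      # the first point that leaves the field of view (filaments grow in
      # one direction from an in-bounds origin)
      inb <- pts[, 1L] >= 0 & pts[, 1L] <= nx - 1 &
             pts[, 2L] >= 0 & pts[, 2L] <= ny - 1
      first_out <- match(FALSE, inb)
      if (!is.na(first_out)) {
        if (first_out < 3L) next
        pts <- pts[seq_len(first_out - 1L), , drop = FALSE]
      }
      cv <- ft_curve(pts, id = ids[i], frame = t - 1L)
      if (curve_length(cv) < 2) next
      gt[[length(gt) + 1L]] <- resample_curve(cv, 1)
    }
    truth_frames[[t]] <- gt
  }
  truth <- structure(list(frames = truth_frames), class = "ft_ground_truth")
  list(images = images, truth = truth, states = states)
}
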