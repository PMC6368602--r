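#' Parameters of the geometric 3D fiber-network generator
#'
#' A static network of quasi-straight fibers placed at random positions and
#' orientations in a cubic box, rendered as a confocal-like stack. The
#' generator stands in for a physical network simulation: the deformation
#' analyses only require a set of trackable, quasi-straight segments.
#'
#' @param box_size cube side in voxels.
#' @param n_fibers number of fibers.
#' @param fiber_length mean fiber length in voxels.
#' @param fiber_length_spread standard deviation of fiber length.
#' @param wiggle_sigma per-segment direction wiggle (radians, segments of
#'   1 voxel).
#' @param line_density deposited intensity per unit fiber length.
#' @param deposit_spacing spacing of deposited points along fibers (voxels).
#' @param psf_sigma length-3 Gaussian PSF sigma (x, y, z) in voxels.
#' @param noise_max per-voxel additive noise is Uniform(0, noise_max).
#' @param seed RNG seed.
#' @return A `ft_network_params` list.
#' @export
network_gen_params <- function(box_size = 100, n_fibers = 30L,
                               fiber_length = 35, fiber_length_spread = 10,
                               wiggle_sigma = 0.02, line_density = 400,
                               deposit_spacing = 0.25,
                               psf_sigma = c(1.5, 1.5, 1.5), noise_max = 10,
                               seed = 1L) {
  stopifnot(box_size > 0, fiber_length > 0)
  structure(list(box_size = box_size, n_fibers = as.integer(n_fibers),
                 fiber_length = fiber_length,
                 fiber_length_spread = fiber_length_spread,
                 wiggle_sigma = wiggle_sigma, line_density = line_density,
                 deposit_spacing = deposit_spacing,
                 psf_sigma = rep_len(psf_sigma, 3L), noise_max = noise_max,
                 seed = as.integer(seed)),
            class = "ft_network_params")
}

#' Deformation parameters
#'
#' @param mode `"shear"` (x' = x + lam * z per step) or `"rotation"`
#'   (rotation by theta_deg about the z axis per step).
#' @param lam shear magnitude per step.
#' @param theta_deg rotation angle per step in degrees.
#' @param n_steps number of deformation steps (frames = n_steps + 1).
#' @return A `ft_deform_params` list.
#' @export
deform_params <- function(mode = c("shear", "rotation"), lam = 0.05,
                          theta_deg = 3.5, n_steps = 4L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, lam = lam, theta_deg = theta_deg,
                 n_steps = as.integer(n_steps)),
            class = "ft_deform_params")
}

#' Per-step deformation matrix
#'
#' @param def [deform_params].
#' @return 3 x 3 matrix: the simple shear `[[1,0,lam],[0,1,0],[0,0,1]]` or
#'   the z-rotation by `theta_deg`.
#' @export
deformation_matrix <- function(def) {
  if (def$mode == "shear") {
    matrix(c(1, 0, 0, 0, 1, 0, def$lam, 0, 1), 3L, 3L)
  } else {
    th <- def$theta_deg * pi / 180
    matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L, 3L)
  }
}

#' Apply one shear step to points
#'
#' @param points n x 3 matrix. @param lam shear magnitude.
#' @param center optional length-3 fixed point (default origin).
#' @return Transformed n x 3 matrix: x' = x + lam * z, y and z unchanged.
#' @export
shear_step <- function(points, lam, center = c(0, 0, 0)) {
  p <- sweep(as.matrix(points), 2L, center)
  p[, 1L] <- p[, 1L] + lam * p[, 3L]
  sweep(p, 2L, center, "+")
}

#' Apply one z-rotation step to points
#'
#' @param points n x 3 matrix. @param theta_deg angle in degrees.
#' @param center optional length-3 fixed point (default origin).
#' @return Rotated n x 3 matrix.
#' @export
rotate_step <- function(points, theta_deg, center = c(0, 0, 0)) {
  th <- theta_deg * pi / 180
  p <- sweep(as.matrix(points), 2L, center)
  out <- p
  out[, 1L] <- cos(th) * p[, 1L] - sin(th) * p[, 2L]
  out[, 2L] <- sin(th) * p[, 1L] + cos(th) * p[, 2L]
  sweep(out, 2L, center, "+")
}

#' Generate a random quasi-straight fiber network
#'
#' Fibers are polylines grown in 1-voxel segments from a random center along
#' a random 3D direction, with a Normal(0, wiggle_sigma) angular wiggle per
#' segment, truncated to the box.
#'
#' @param params [network_gen_params]. The caller controls seeding.
#' @return List of n x 3 point matrices (one per fiber).
#' @export
generate_network <- function(params = network_gen_params()) {
  b <- params$box_size
  fibers <- list()
  for (i in seq_len(params$n_fibers)) {
    len <- max(5, rnorm(1, params$fiber_length, params$fiber_length_spread))
    n_seg <- max(2L, round(len))
    dir <- random_unit_vector()
    ctr <- runif(3, 0.15 * b, 0.85 * b)
    pts <- matrix(0, n_seg + 1L, 3L)
    pts[1L, ] <- ctr - dir * len / 2
    d <- dir
    for (s in seq_len(n_seg)) {
      if (params$wiggle_sigma > 0) d <- wiggle_direction(d, params$wiggle_sigma)
      pts[s + 1L, ] <- pts[s, ] + d * (len / n_seg)
    }
    inb <- pts[, 1L] >= 0 & pts[, 1L] <= b - 1 &
           pts[, 2L] >= 0 & pts[, 2L] <= b - 1 &
           pts[, 3L] >= 0 & pts[, 3L] <= b - 1
    run <- longest_true_run(inb)
    if (length(run) < 2L) next
    fibers[[length(fibers) + 1L]] <- pts[run, , drop = FALSE]
  }
  fibers
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# rotate `dir` by an angle ~ N(0, sigma) about a random perpendicular axis
wiggle_direction <- function(dir, sigma) {
  a <- rnorm(1, 0, sigma)
  u <- rnorm(3)
  u <- u - sum(u * dir) * dir
  nu <- sqrt(sum(u^2))
  if (nu == 0) return(dir)
  u <- u / nu
  d <- cos(a) * dir + sin(a) * u
  d / sqrt(sum(d^2))
}

longest_true_run <- function(x) {
  if (!any(x)) return(integer())
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  true_runs <- which(r$values)
  best <- true_runs[which.max(r$lengths[true_runs])]
  starts[best]:ends[best]
}

#' Render a 3D fiber network as a confocal-like stack
#'
#' Deposits points densely along each fiber (spacing `deposit_spacing`,
#' weight `line_density * deposit_spacing`), convolves with an anisotropic
#' Gaussian PSF, and adds Uniform(0, noise_max) noise per voxel.
#'
#' @param fibers list of n x 3 point matrices.
#' @param params [network_gen_params].
#' @return 3D array `[y, x, z]` of side `box_size`.
#' @export
render_stack <- function(fibers, params = network_gen_params()) {
  b <- round(params$box_size)
  vol <- array(0, c(b, b, b))
  w <- params$line_density * params$deposit_spacing
  for (f in fibers) {
    if (nrow(f) < 2L) next
    cv <- ft_curve(f)
    dense <- resample_curve(cv, params$deposit_spacing)$points
    col <- round(dense[, 1L]) + 1L
    row <- round(dense[, 2L]) + 1L
    slc <- round(dense[, 3L]) + 1L
    keep <- col >= 1L & col <= b & row >= 1L & row <= b &
            slc >= 1L & slc <= b
    if (!any(keep)) next
    idx <- (slc[keep] - 1L) * b * b + (col[keep] - 1L) * b + row[keep]
    agg <- rowsum(rep(w, sum(keep)), idx)
    vol[as.integer(rownames(agg))] <- vol[as.integer(rownames(agg))] + agg
  }
  vol <- gaussian_smooth_zero(vol, params$psf_sigma[c(2L, 1L, 3L)])
  if (params$noise_max > 0) {
    vol <- vol + array(runif(length(vol), 0, params$noise_max), dim(vol))
  }
  vol
}

#' Simulate an affinely deforming 3D network movie
#'
#' Generates a network, applies the per-step deformation matrix cumulatively
#' about the box center, and renders a stack after the initial state and
#' after every step. Ground truth is the exact fiber coordinates per frame
#' with identity correspondence across frames.
#'
#' @param net [network_gen_params]; `net$seed` seeds the RNG.
#' @param def [deform_params].
#' @return List with `stacks` (list of 3D arrays), `truth`
#'   (`ft_ground_truth` of per-frame [ft_curve] lists, ids = fiber ids),
#'   `fibers` (frame-0 point matrices), `matrix` (the per-step 3 x 3
#'   deformation matrix) and `center` (its fixed point).
#' @export
simulate_deformation_sequence <- function(net = network_gen_params(),
                                          def = deform_params()) {
  set.seed(net$seed)
  fibers <- generate_network(net)
  A <- deformation_matrix(def)
  center <- rep((net$box_size - 1) / 2, 3L)
  n_frames <- def$n_steps + 1L
  stacks <- vector("list", n_frames)
  truth_frames <- vector("list", n_frames)
  cur <- fibers
  for (t in seq_len(n_frames)) {
    if (t > 1L) {
      cur <- lapply(cur, function(p) {
        sweep(sweep(p, 2L, center) %*% t(A), 2L, center, "+")
      })
    }
    stacks[[t]] <- render_stack(cur, net)
    truth_frames[[t]] <- lapply(seq_along(cur), function(i) {
      ft_curve(cur[[i]], id = i, frame = t - 1L)
    })
  }
  list(stacks = stacks,
       truth = structure(list(frames = truth_frames),
                         class = "ft_ground_truth"),
       fibers = fibers, matrix = A, center = center)
}
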