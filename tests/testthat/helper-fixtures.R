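## Shared fixtures, computed once per test run on first use. The simulation
## seeds are fixed at 1 throughout by convention.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, maker(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

## 15-frame 256x256 elongating-filament movie, detected and tracked
sim2d_fixture <- function() fixture("sim2d", function() {
  sim <- simulate_filament_sequence(growth_params(seed = 1L))
  list(sim = sim, res = track_network(sim$images))
})

## sheared 3D network, four shear steps, detected and tracked
shear_fixture <- function() fixture("shear", function() {
  sim <- simulate_deformation_sequence(network_gen_params(seed = 1L),
                                       deform_params("shear", n_steps = 4L))
  list(sim = sim, res = track_network(sim$stacks))
})

## rotated 3D network, four z-rotation steps, detected and tracked
rotation_fixture <- function() fixture("rotation", function() {
  sim <- simulate_deformation_sequence(network_gen_params(seed = 1L),
                                       deform_params("rotation", n_steps = 4L))
  list(sim = sim, res = track_network(sim$stacks))
})

## render a straight 2D line segment as a noise-free synthetic image
line_image <- function(p0, p1, size = 64L, density = 100, spacing = 0.05,
                       psf_sigma = 1.5, noise_max = 0) {
  n <- max(2L, ceiling(sqrt(sum((p1 - p0)^2)) / spacing))
  ts <- seq(0, 1, length.out = n)
  pts <- cbind(p0[1L] + ts * (p1[1L] - p0[1L]),
               p0[2L] + ts * (p1[2L] - p0[2L]), 0)
  params <- growth_params(image_size = c(size, size), psf_sigma = psf_sigma,
                          noise_max = noise_max)
  render_frame_2d(list(list(points = pts,
                            brightness = rep(density * spacing, n))),
                  params)
}

## render several point matrices together (unit-spacing weights)
multi_line_image <- function(point_sets, size = 64L, density = 100,
                             spacing = 0.05, psf_sigma = 1.5,
                             noise_max = 0) {
  fil <- lapply(point_sets, function(pp) {
    p0 <- pp[[1L]]; p1 <- pp[[2L]]
    n <- max(2L, ceiling(sqrt(sum((p1 - p0)^2)) / spacing))
    ts <- seq(0, 1, length.out = n)
    list(points = cbind(p0[1L] + ts * (p1[1L] - p0[1L]),
                        p0[2L] + ts * (p1[2L] - p0[2L]), 0),
         brightness = rep(density * spacing, n))
  })
  params <- growth_params(image_size = c(size, size), psf_sigma = psf_sigma,
                          noise_max = noise_max)
  render_frame_2d(fil, params)
}

## largest distance from each row of `pts` to the infinite line p0 + t*(p1-p0)
max_line_deviation <- function(pts, p0, p1) {
  d <- c(p1 - p0, 0)[1:3]
  d <- d / sqrt(sum(d^2))
  rel <- sweep(pts, 2L, c(p0, 0)[1:3])
  perp <- rel - outer(as.numeric(rel %*% d), d)
  max(sqrt(rowSums(perp^2)))
}

## brute-force minimum of the path-cover objective by enumerating successor
## assignments (each vertex: at most one successor, at most one predecessor)
enumerate_path_cover_cost <- function(graph) {
  n <- nrow(graph$vertices)
  eta <- graph$eta
  edges_from <- lapply(seq_len(n), function(v) {
    which(graph$edges$from == v)
  })
  best <- Inf
  used <- rep(FALSE, n)
  rec <- function(v, acc) {
    if (acc >= best) return(invisible())
    if (v > n) { best <<- acc; return(invisible()) }
    for (k in edges_from[[v]]) {
      tv <- graph$edges$to[k]
      if (!used[tv]) {
        used[tv] <<- TRUE
        rec(v + 1L, acc + graph$edges$weight[k])
        used[tv] <<- FALSE
      }
    }
    rec(v + 1L, acc + eta)  # v ends its track
  }
  rec(1L, 0)
  best
}

## random small multi-frame curve instance for path-cover enumeration
random_cover_instance <- function(seed) {
  set.seed(seed)
  n_frames <- sample(2:4, 1L)
  frames <- lapply(seq_len(n_frames) - 1L, function(t) {
    n_curves <- sample(1:4, 1L)
    curves <- lapply(seq_len(n_curves), function(i) {
      p0 <- runif(2, 0, 30)
      ang <- runif(1, 0, 2 * pi)
      len <- runif(1, 3, 10)
      ts <- seq(0, 1, length.out = 4L)
      ft_curve(cbind(p0[1L] + ts * len * cos(ang),
                     p0[2L] + ts * len * sin(ang)),
               id = i, frame = t)
    })
    ft_frame(t, curves = curves)
  })
  params <- tracking_params(eta = runif(1, 4, 15),
                            c = runif(1, 0, 1.5),
                            max_frame_gap = sample(1:3, 1L))
  list(frames = frames, params = params)
}

## a set of synthetic straight-fiber tracks undergoing an exact affine map
affine_truth_tracks <- function(A, center, seed = 1L, n = 12L) {
  set.seed(seed)
  curves0 <- list(); curves1 <- list()
  for (i in seq_len(n)) {
    p0 <- runif(3, 20, 80)
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    len <- runif(1, 30, 50)
    ts <- seq(0, 1, length.out = 12L)
    pts <- sweep(outer(ts * len, d), 2L, p0, "+")
    curves0[[i]] <- ft_curve(pts, id = i, frame = 0L)
    pts1 <- sweep(sweep(pts, 2L, center) %*% t(A), 2L, center, "+")
    curves1[[i]] <- ft_curve(pts1, id = i, frame = 1L)
  }
  frames <- list(ft_frame(0L, curves = curves0),
                 ft_frame(1L, curves = curves1))
  tracks <- lapply(seq_len(n), function(i) ft_track(i, c(0L, 1L), c(i, i)))
  list(frames = frames, tracks = tracks)
}
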