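## Quantitative readouts of tracks: growth, constriction, alignment,
## deformation recovery, and tracking accuracy.

curve_lookup <- function(frames, grouping = TRUE) {
  env <- new.env(parent = emptyenv())
  for (fr in frames) {
    cs <- if (grouping) fr$curves else fr$segments
    for (cv in cs) assign(paste0(fr$frame, ":", cv$id), cv, envir = env)
  }
  env
}

get_curve <- function(lookup, frame, id) {
  key <- paste0(frame, ":", id)
  if (!exists(key, envir = lookup)) {
    stop("track references missing curve ", key)
  }
  get(key, envir = lookup)
}

#' Per-track length versus time
#'
#' @param tracks list of [ft_track].
#' @param frames list of [ft_frame] (or a `ft_ground_truth`).
#' @param grouping whether tracks reference spliced curves (`TRUE`) or
#'   dissected segments.
#' @return List of length series: each a list with `track_id`, `frames` and
#'   `lengths` (pixels).
#' @export
length_series <- function(tracks, frames, grouping = TRUE) {
  if (inherits(frames, "ft_ground_truth")) {
    frames <- lapply(seq_along(frames$frames), function(t) {
      ft_frame(t - 1L, curves = frames$frames[[t]])
    })
  }
  lk <- curve_lookup(frames, grouping)
  lapply(tracks, function(tr) {
    lens <- vapply(seq_along(tr$frames), function(k) {
      curve_length(get_curve(lk, tr$frames[k], tr$curve_ids[k]))
    }, numeric(1))
    list(track_id = tr$id, frames = tr$frames, lengths = lens)
  })
}

#' Gaussian fit of the per-frame length-change distribution
#'
#' Collects all per-frame length changes dL from the series (length
#' difference divided by frame gap), drops the stalled-track contamination
#' peak |dL| < `exclusion_halfwidth`, and fits a Gaussian to the histogram
#' of the retained values by least squares. Fitting the histogram rather
#' than taking sample moments makes the estimate follow the central
#' elongation peak instead of the heavy tails produced by transient
#' detection dropouts at filament crossings.
#'
#' @param series list of length series from [length_series].
#' @param exclusion_halfwidth half-width of the excluded band around 0
#'   (pixels/frame).
#' @param bin_width histogram bin width (pixels/frame).
#' @return List with `mean`, `sigma`, `n_used`, `n_excluded` and the
#'   retained `dl` values.
#' @export
fit_elongation_rate <- function(series, exclusion_halfwidth = 3,
                                bin_width = 2) {
  dl <- unlist(lapply(series, function(s) {
    if (length(s$frames) < 2L) return(numeric())
    diff(s$lengths) / diff(s$frames)
  }))
  if (length(dl) < 10L) stop("insufficient data: need at least 10 dL samples")
  keep <- abs(dl) >= exclusion_halfwidth
  if (!any(keep)) stop("insufficient data: all dL samples excluded")
  x <- dl[keep]
  brk <- seq(floor(min(x)) - bin_width, ceiling(max(x)) + bin_width,
             by = bin_width)
  h <- hist(x, breaks = brk, plot = FALSE)
  mids <- h$mids; cnt <- h$counts
  mu0 <- mids[which.max(cnt)]
  sd0 <- max(bin_width, sqrt(sum(cnt * (mids - mu0)^2) / sum(cnt)) / 2)
  fit <- tryCatch(
    stats::nls(cnt ~ a * exp(-(mids - mu)^2 / (2 * s^2)),
               start = list(a = max(cnt), mu = mu0, s = sd0),
               control = stats::nls.control(maxiter = 500, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    est <- c(mu = mu0, s = sd0)  # fall back to the histogram mode
  } else {
    est <- stats::coef(fit)[c("mu", "s")]
  }
  list(mean = unname(est[1L]), sigma = abs(unname(est[2L])),
       n_used = length(x), n_excluded = sum(!keep), dl = x)
}

#' Convert an elongation rate to subunits per second
#'
#' @param px_per_frame rate in pixels per frame.
#' @param frame_interval_s seconds between frames.
#' @param um_per_px pixel size in micrometers.
#' @param subunits_per_um subunits per micrometer of polymer (370 for
#'   actin).
#' @return Rate in subunits per second.
#' @export
convert_elongation_rate <- function(px_per_frame, frame_interval_s,
                                    um_per_px, subunits_per_um) {
  if (frame_interval_s <= 0 || um_per_px <= 0 || subunits_per_um <= 0) {
    stop("conversion factors must be positive")
  }
  px_per_frame / frame_interval_s * um_per_px * subunits_per_um
}

#' Constriction (or growth) rate of a length series
#'
#' Ordinary least-squares slope of length versus frame; negative for a
#' constricting ring.
#'
#' @param series one length series (list with `frames`, `lengths`).
#' @return Slope in length units per frame.
#' @export
constriction_rate <- function(series) {
  if (length(series$frames) < 3L) {
    stop("insufficient data: need at least 3 points")
  }
  unname(coef(lm(series$lengths ~ series$frames))[2L])
}

#' Nematic order parameter of a set of directions
#'
#' Largest eigenvalue of the Q-tensor Q = (3/2) <u u'> - (1/2) I over unit
#' axis directions u, which is independent of the mean orientation: 1 for
#' perfect alignment, 0 for an isotropic 3D distribution. Curves contribute
#' one direction per resampled segment; 2D directions are embedded with
#' z = 0.
#'
#' @param x an n x 2 or n x 3 matrix of direction vectors (not necessarily
#'   unit), or a list of [ft_curve] (segment directions at `spacing`).
#' @param spacing resampling spacing when `x` is a curve list.
#' @return S in [-0.5, 1].
#' @export
nematic_order <- function(x, spacing = 2) {
  if (is.list(x) && !is.matrix(x)) {
    dirs <- do.call(rbind, lapply(x, function(cv) {
      p <- resample_curve(cv, spacing)$points
      p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
    }))
  } else {
    dirs <- as.matrix(x)
    if (ncol(dirs) == 2L) dirs <- cbind(dirs, 0)
  }
  nrm <- sqrt(rowSums(dirs^2))
  dirs <- dirs[nrm > 0, , drop = FALSE] / nrm[nrm > 0]
  if (nrow(dirs) < 2L) stop("insufficient data: need at least 2 directions")
  q <- 1.5 * crossprod(dirs) / nrow(dirs) - 0.5 * diag(3L)
  max(eigen(q, symmetric = TRUE, only.values = TRUE)$values)
}

# end-to-end axis vectors of the curves of each track, sign-aligned along
# the track; closed curves yield NA rows
track_axes <- function(tracks, frames, grouping = TRUE) {
  lk <- curve_lookup(frames, grouping)
  lapply(tracks, function(tr) {
    ax <- matrix(NA_real_, length(tr$frames), 3L)
    for (k in seq_along(tr$frames)) {
      cv <- get_curve(lk, tr$frames[k], tr$curve_ids[k])
      if (cv$closed) next
      v <- cv$points[nrow(cv$points), ] - cv$points[1L, ]
      if (sum(v^2) == 0) next
      if (k > 1L && !anyNA(ax[k - 1L, ]) && sum(v * ax[k - 1L, ]) < 0) v <- -v
      ax[k, ] <- v
    }
    list(track_id = tr$id, frames = tr$frames, axes = ax)
  })
}

#' Recover the per-frame affine transformation from tracked curves
#'
#' Each tracked curve is approximated by the straight line through its two
#' ends. For a random triplet of tracks present in frames k and k+1, the
#' end-to-end vectors form 3 x 3 matrices X (frame k) and X' (frame k+1)
#' and X' = A X is solved exactly; the elements of A are averaged over
#' `n_triplets` triplets (ill-conditioned triplets, condition number above
#' `cond_max`, are redrawn). With `normalize = "unit"` both vectors of a
#' track are divided by the frame-k vector length, so the frame-k columns
#' are unit vectors while the relation X' = A X is preserved exactly
#' (scaling both sides of a linear equation by the same factor changes
#' nothing); `"none"` keeps raw lengths. Both choices are exact under a
#' noiseless affine deformation.
#'
#' @param tracks list of [ft_track]. @param frames list of [ft_frame].
#' @param frame_k first frame of the pair.
#' @param n_triplets triplets to average over.
#' @param normalize `"unit"` or `"none"`.
#' @param cond_max condition-number rejection threshold.
#' @param average `"median"` (default) or `"mean"` over triplets. The
#'   element-wise median is robust to the occasional corrupted track axis
#'   (a curve spliced differently in the two frames), which contaminates
#'   every triplet it is drawn into and would bias the mean arbitrarily.
#' @param grouping see [length_series].
#' @param min_axis_length tracks whose end-to-end axis is shorter than this
#'   are ignored (degenerate direction estimates).
#' @param max_length_change tracks whose axis length changes by more than
#'   this fraction between the two frames are ignored; a drastic length
#'   change means the detected curve covers different material in the two
#'   frames, so its end-to-end vector does not transform affinely.
#' @param max_angle_change tracks whose axis direction swings by more than
#'   this many degrees between the two frames are ignored for the same
#'   reason; set it well above the rotation any plausible per-frame
#'   deformation could impose.
#' @return List with `A` (element-wise mean), `se` (element-wise standard
#'   error), `n_triplets`, `n_tracks`.
#' @export
recover_affine <- function(tracks, frames, frame_k, n_triplets = 10L,
                           normalize = c("unit", "none"), cond_max = 100,
                           grouping = TRUE, min_axis_length = 15,
                           max_length_change = 0.1,
                           max_angle_change = 20,
                           average = c("median", "mean")) {
  normalize <- match.arg(normalize)
  average <- match.arg(average)
  axes <- track_axes(tracks, frames, grouping)
  xs <- list(); x1s <- list()
  for (a in axes) {
    i <- match(frame_k, a$frames); j <- match(frame_k + 1L, a$frames)
    if (is.na(i) || is.na(j) || j != i + 1L) next
    v0 <- a$axes[i, ]; v1 <- a$axes[j, ]
    if (anyNA(v0) || anyNA(v1)) next
    l0 <- sqrt(sum(v0^2)); l1 <- sqrt(sum(v1^2))
    if (l0 < min_axis_length || l1 < min_axis_length) next
    if (abs(l1 - l0) / l0 > max_length_change) next
    swing <- acos(min(1, abs(sum(v0 * v1)) / (l0 * l1))) * 180 / pi
    if (swing > max_angle_change) next
    if (normalize == "unit") {
      v0 <- v0 / l0; v1 <- v1 / l0
    }
    xs[[length(xs) + 1L]] <- v0; x1s[[length(x1s) + 1L]] <- v1
  }
  n <- length(xs)
  if (n < 3L) stop("insufficient data: need at least 3 usable tracks")
  mats <- vector("list", n_triplets)
  got <- 0L; attempts <- 0L
  while (got < n_triplets && attempts < 200L * n_triplets) {
    attempts <- attempts + 1L
    sel <- sample.int(n, 3L)
    X <- do.call(cbind, xs[sel])
    if (kappa(X, exact = TRUE) > cond_max) next
    X1 <- do.call(cbind, x1s[sel])
    got <- got + 1L
    mats[[got]] <- X1 %*% solve(X)
  }
  if (got < n_triplets) stop("could not draw enough well-conditioned triplets")
  arr <- simplify2array(mats)
  avg <- if (average == "median") stats::median else mean
  list(A = apply(arr, c(1L, 2L), avg),
       se = apply(arr, c(1L, 2L), sd) / sqrt(n_triplets),
       n_triplets = n_triplets, n_tracks = n)
}

#' Angular deviation between a detected axis and its affine prediction
#'
#' Angle between the frame k+1 axis of a tracked curve and the image of its
#' frame k axis under the imposed transformation matrix; axis sign is
#' ignored, so the result lies in [0, 90] degrees. Zero means the detected
#' motion is exactly the imposed affine deformation.
#'
#' @param axis_k,axis_k1 length-3 end-to-end vectors at frames k and k+1.
#' @param imposed_matrix 3 x 3 per-step transformation.
#' @return Angle in degrees.
#' @export
angular_deviation_psi <- function(axis_k, axis_k1, imposed_matrix) {
  pred <- as.numeric(imposed_matrix %*% axis_k)
  np <- sqrt(sum(pred^2)); nd <- sqrt(sum(axis_k1^2))
  if (np == 0 || nd == 0) stop("degenerate zero-length axis")
  ct <- abs(sum(pred * axis_k1)) / (np * nd)
  acos(min(1, ct)) * 180 / pi
}

#' Angular deviations psi over all tracked frame pairs
#'
#' @param tracks list of [ft_track]. @param frames list of [ft_frame].
#' @param imposed_matrix per-step 3 x 3 matrix.
#' @param grouping see [length_series].
#' @param min_axis_length skip axes shorter than this (pixels).
#' @return Numeric vector of psi angles (degrees), one per consecutive
#'   tracked pair.
#' @export
track_psi_angles <- function(tracks, frames, imposed_matrix,
                             grouping = TRUE, min_axis_length = 5) {
  axes <- track_axes(tracks, frames, grouping)
  out <- numeric()
  for (a in axes) {
    for (k in seq_len(length(a$frames) - 1L)) {
      if (a$frames[k + 1L] != a$frames[k] + 1L) next
      v0 <- a$axes[k, ]; v1 <- a$axes[k + 1L, ]
      if (anyNA(v0) || anyNA(v1)) next
      if (sqrt(sum(v0^2)) < min_axis_length ||
          sqrt(sum(v1^2)) < min_axis_length) next
      out <- c(out, angular_deviation_psi(v0, v1, imposed_matrix))
    }
  }
  out
}

#' Per-frame azimuthal and polar angle drift of tracked axes
#'
#' Spherical angles of each track's end-to-end axis per frame: the azimuth
#' phi = atan2(y, x) is defined modulo 180 degrees (axis symmetry) and
#' frame-to-frame differences are unwrapped into (-90, 90]; the polar angle
#' theta = acos(|z| / r) lies in [0, 90]. Differences are divided by the
#' frame gap.
#'
#' @param tracks list of [ft_track]. @param frames list of [ft_frame].
#' @param grouping see [length_series].
#' @param min_axis_length skip axes shorter than this (pixels).
#' @param max_length_change axis pairs whose length changes by more than
#'   this fraction between the two frames are skipped: the detected curve
#'   then covers different material in the two frames and its apparent
#'   rotation is a tracking artifact, not motion.
#' @return List with `dphi` and `dtheta` (all per-frame differences in
#'   degrees), and their means and standard deviations.
#' @export
angle_drift <- function(tracks, frames, grouping = TRUE,
                        min_axis_length = 5, max_length_change = 0.1) {
  axes <- track_axes(tracks, frames, grouping)
  dphi <- numeric(); dtheta <- numeric()
  for (a in axes) {
    ok <- !apply(a$axes, 1L, anyNA) &
      sqrt(rowSums(a$axes^2)) >= min_axis_length
    if (sum(ok) < 2L) next
    v <- a$axes[ok, , drop = FALSE]
    f <- a$frames[ok]
    len <- sqrt(rowSums(v^2))
    phi <- atan2(v[, 2L], v[, 1L]) * 180 / pi
    theta <- acos(pmin(1, abs(v[, 3L]) / len)) * 180 / pi
    for (k in seq_len(nrow(v) - 1L)) {
      if (abs(len[k + 1L] - len[k]) / len[k] > max_length_change) next
      gap <- f[k + 1L] - f[k]
      d <- (phi[k + 1L] - phi[k]) %% 180
      if (d > 90) d <- d - 180
      dphi <- c(dphi, d / gap)
      dtheta <- c(dtheta, (theta[k + 1L] - theta[k]) / gap)
    }
  }
  list(dphi = dphi, dtheta = dtheta,
       dphi_mean = mean(dphi), dphi_sd = sd(dphi),
       dtheta_mean = mean(dtheta), dtheta_sd = sd(dtheta))
}

#' Precision and recall of correspondence links
#'
#' Both arguments are link tables: data frames with columns `frame_a`,
#' `key_a`, `frame_b`, `key_b`, one row per frame-to-frame correspondence
#' (keys identify the underlying object, e.g. the ground-truth filament).
#' TP is the number of predicted links present in the truth table.
#'
#' @param predicted_links,truth_links link data frames.
#' @return List with `TP`, `P`, `FN`, `precision` (NA when P = 0) and
#'   `recall`.
#' @export
precision_recall <- function(predicted_links, truth_links) {
  link_key <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(character())
    paste(df$frame_a, df$key_a, df$frame_b, df$key_b, sep = "|")
  }
  pk <- link_key(predicted_links); tk <- link_key(truth_links)
  # each truth link counts at most once towards recall, so duplicate
  # predicted links (several tracks claiming the same correspondence)
  # cannot push recall above 1
  tp <- sum(tk %in% pk)
  p <- length(pk); tpfn <- length(tk)
  list(TP = tp, P = p, FN = tpfn - tp,
       precision = if (p == 0L) NA_real_ else sum(pk %in% tk) / p,
       recall = if (tpfn == 0L) NA_real_ else tp / tpfn)
}

#' Map detected curves to ground-truth filaments
#'
#' Each detected curve is assigned to the ground-truth filament nearest to
#' the majority of its points (within `tolerance` pixels); curves with no
#' majority support get NA.
#'
#' @param frames list of [ft_frame]. @param truth `ft_ground_truth`.
#' @param tolerance point match tolerance in pixels.
#' @param grouping see [length_series].
#' @return Named integer vector keyed `"frame:id"`.
#' @export
map_curves_to_truth <- function(frames, truth, tolerance = 2,
                                grouping = TRUE) {
  out <- integer(); labels <- character()
  for (fr in frames) {
    t_idx <- fr$frame + 1L
    gt <- if (t_idx <= length(truth$frames)) truth$frames[[t_idx]] else list()
    cs <- if (grouping) fr$curves else fr$segments
    for (cv in cs) {
      best <- NA_integer_
      if (length(gt) > 0L) {
        votes <- integer(length(gt))
        mind <- matrix(Inf, n_points(cv), length(gt))
        for (g in seq_along(gt)) {
          dm <- point_dist_matrix(cv$points, gt[[g]]$points)
          mind[, g] <- apply(dm, 1L, min)
        }
        nearest <- max.col(-mind, ties.method = "first")
        within <- mind[cbind(seq_len(nrow(mind)), nearest)] <= tolerance
        if (any(within)) {
          tab <- table(nearest[within])
          win <- as.integer(names(tab)[which.max(tab)])
          if (tab[which.max(tab)] > n_points(cv) / 2) {
            best <- gt[[win]]$id
          }
        }
      }
      out <- c(out, best)
      labels <- c(labels, paste0(fr$frame, ":", cv$id))
    }
  }
  setNames(out, labels)
}

#' Evaluate tracking against ground truth
#'
#' Predicted links are consecutive members of each track mapped to
#' ground-truth filaments via [map_curves_to_truth]; truth links are the
#' filament identities present in pairs of adjacent ground-truth frames.
#'
#' @param tracks list of [ft_track]. @param frames list of [ft_frame].
#' @param truth `ft_ground_truth`. @param tolerance match tolerance (px).
#' @param grouping see [length_series].
#' @return See [precision_recall].
#' @export
evaluate_tracking <- function(tracks, frames, truth, tolerance = 2,
                              grouping = TRUE) {
  mp <- map_curves_to_truth(frames, truth, tolerance, grouping)
  pred <- NULL
  for (tr in tracks) {
    if (length(tr$frames) < 2L) next
    for (k in seq_len(length(tr$frames) - 1L)) {
      ka <- mp[[paste0(tr$frames[k], ":", tr$curve_ids[k])]]
      kb <- mp[[paste0(tr$frames[k + 1L], ":", tr$curve_ids[k + 1L])]]
      pred <- rbind(pred, data.frame(
        frame_a = tr$frames[k],
        key_a = if (is.na(ka)) -tr$curve_ids[k] else ka,
        frame_b = tr$frames[k + 1L],
        key_b = if (is.na(kb)) -1000000L - tr$curve_ids[k + 1L] else kb))
    }
  }
  tru <- NULL
  for (t in seq_len(length(truth$frames) - 1L)) {
    ids_a <- vapply(truth$frames[[t]], `[[`, integer(1), "id")
    ids_b <- vapply(truth$frames[[t + 1L]], `[[`, integer(1), "id")
    common <- intersect(ids_a, ids_b)
    if (length(common) > 0L) {
      tru <- rbind(tru, data.frame(frame_a = t - 1L, key_a = common,
                                   frame_b = t, key_b = common))
    }
  }
  precision_recall(pred, tru)
}
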