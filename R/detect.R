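## Per-frame network extraction: centerline tracing on intensity ridges,
## junction detection by collision clustering, dissection at junctions.
##
## Image convention: a 2D image is a matrix [row, col] and a 3D stack an
## array [row, col, slice]; pixel-center coordinates are 0-based with
## x = col - 1, y = row - 1, z = slice - 1.

# shift an array along one dimension with edge replication
shift_clamp <- function(a, k, dim) {
  d <- dim(a); n <- d[dim]
  idx <- pmin(pmax(seq_len(n) - k, 1L), n)
  if (length(d) == 2L) {
    if (dim == 1L) a[idx, , drop = FALSE] else a[, idx, drop = FALSE]
  } else {
    if (dim == 1L) a[idx, , , drop = FALSE]
    else if (dim == 2L) a[, idx, , drop = FALSE]
    else a[, , idx, drop = FALSE]
  }
}

#' Separable Gaussian smoothing of a 2D or 3D image
#'
#' @param image numeric matrix or 3D array.
#' @param sigma scalar or per-dimension vector of Gaussian sigmas (pixels);
#'   0 skips that dimension.
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth <- function(image, sigma) {
  d <- dim(image)
  nd <- length(d)
  sigma <- rep_len(sigma, nd)
  out <- image
  for (dd in seq_len(nd)) {
    s <- sigma[dd]
    if (s <= 0 || d[dd] == 1L) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-(seq(-r, r))^2 / (2 * s^2)); w <- w / sum(w)
    acc <- array(0, d)
    for (k in seq(-r, r)) {
      acc <- acc + w[k + r + 1L] * shift_clamp(out, k, dd)
    }
    out <- acc
  }
  out
}

# n-linear interpolation at 0-based (x, y, z) coordinates, edge-clamped
interp_image <- function(image, xyz) {
  d <- dim(image)
  is3d <- length(d) == 3L
  # convert to 1-based fractional array indices
  iy <- pmin(pmax(xyz[2] + 1, 1), d[1])
  ix <- pmin(pmax(xyz[1] + 1, 1), d[2])
  y0 <- floor(iy); x0 <- floor(ix)
  y1 <- min(y0 + 1, d[1]); x1 <- min(x0 + 1, d[2])
  fy <- iy - y0; fx <- ix - x0
  if (!is3d) {
    v00 <- image[y0, x0]; v01 <- image[y0, x1]
    v10 <- image[y1, x0]; v11 <- image[y1, x1]
    return((1 - fy) * ((1 - fx) * v00 + fx * v01) +
           fy * ((1 - fx) * v10 + fx * v11))
  }
  iz <- pmin(pmax(xyz[3] + 1, 1), d[3])
  z0 <- floor(iz); z1 <- min(z0 + 1, d[3]); fz <- iz - z0
  vals <- 0
  for (dz in 0:1) {
    zz <- if (dz == 0) z0 else z1
    wz <- if (dz == 0) 1 - fz else fz
    if (wz == 0) next
    v00 <- image[y0, x0, zz]; v01 <- image[y0, x1, zz]
    v10 <- image[y1, x0, zz]; v11 <- image[y1, x1, zz]
    vals <- vals + wz * ((1 - fy) * ((1 - fx) * v00 + fx * v01) +
                           fy * ((1 - fx) * v10 + fx * v11))
  }
  vals
}

# local intensity-weighted principal direction and transverse centroid
# offset around 0-based position p; returns NULL when the neighborhood
# carries no weight
local_orientation <- function(image, p, radius, floor_level) {
  d <- dim(image); is3d <- length(d) == 3L
  r <- radius
  y0 <- max(1L, floor(p[2] + 1 - r)); y1 <- min(d[1], ceiling(p[2] + 1 + r))
  x0 <- max(1L, floor(p[1] + 1 - r)); x1 <- min(d[2], ceiling(p[1] + 1 + r))
  if (is3d) {
    z0 <- max(1L, floor(p[3] + 1 - r)); z1 <- min(d[3], ceiling(p[3] + 1 + r))
    sub <- image[y0:y1, x0:x1, z0:z1, drop = FALSE]
    gz <- rep((z0:z1) - 1, each = (y1 - y0 + 1) * (x1 - x0 + 1))
  } else {
    sub <- image[y0:y1, x0:x1, drop = FALSE]
    gz <- 0
  }
  gy <- rep((y0:y1) - 1, times = length(sub) / (y1 - y0 + 1))
  gx <- rep(rep((x0:x1) - 1, each = y1 - y0 + 1),
            length.out = length(sub))
  w <- pmax(as.vector(sub) - floor_level, 0)
  sw <- sum(w)
  if (sw <= 0) return(NULL)
  off <- cbind(gx - p[1], gy - p[2], gz - p[3])
  keep <- sqrt(rowSums(off^2)) <= r + 0.5
  w <- w[keep]; off <- off[keep, , drop = FALSE]
  sw <- sum(w)
  if (sw <= 0) return(NULL)
  ctr <- colSums(off * w) / sw
  offc <- sweep(off, 2L, ctr)
  cov <- crossprod(offc * sqrt(w)) / sw
  ev <- eigen(cov, symmetric = TRUE)
  list(dir = ev$vectors[, 1L], centroid = ctr,
       anisotropy = if (ev$values[1L] > 0) ev$values[2L] / ev$values[1L]
                    else 1)
}

# ridge-pixel candidates: above threshold and local maximum along at least
# `min_axes` coordinate axes
ridge_candidates <- function(sm, threshold, min_axes) {
  d <- dim(sm)
  cnt <- array(0L, d)
  for (dd in seq_along(d)) {
    if (d[dd] < 3L) next
    up <- shift_clamp(sm, 1L, dd); dn <- shift_clamp(sm, -1L, dd)
    cnt <- cnt + ((sm >= up & sm > dn) | (sm > up & sm >= dn))
  }
  which(sm >= threshold & cnt >= min_axes, arr.ind = TRUE)
}

#' Extract centerline curves from an image
#'
#' Traces intensity ridges of the Gaussian-smoothed image: starting from the
#' brightest untraced ridge pixel, steps of `point_spacing` follow the local
#' intensity-weighted principal direction with transverse re-centering, and
#' stop when the intensity falls below `ridge_threshold`, the path turns by
#' more than 60 degrees per step, leaves the image, or collides with an
#' already traced curve. Curves are resampled at `point_spacing` and those
#' shorter than `min_curve_length` discarded.
#'
#' @param image 2D matrix or 3D array of intensities.
#' @param params [detection_params].
#' @return List of [ft_curve] (ids 1..n, frame 0).
#' @export
extract_centerlines <- function(image, params = detection_params()) {
  d <- dim(image)
  if (is.null(d) || any(!is.finite(image))) stop("image must be a finite array")
  is3d <- length(d) == 3L && d[3] > 1L
  if (length(d) == 3L && d[3] == 1L) { image <- image[, , 1L]; d <- dim(image); is3d <- FALSE }
  sm <- gaussian_smooth(image, params$smoothing_sigma)
  cand <- ridge_candidates(sm, params$ridge_threshold, if (is3d) 2L else 1L)
  if (length(cand) == 0L) return(list())
  if (is.null(dim(cand))) cand <- matrix(cand, ncol = length(d))
  vals <- sm[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  visited <- array(0L, d)
  nb_radius <- max(2, ceiling(2 * params$smoothing_sigma))
  floor_level <- 0.5 * params$ridge_threshold
  turn_cos <- cos(60 * pi / 180)
  curves <- list()
  mark_visited <- function(pts, cid) {
    for (k in seq_len(nrow(pts))) {
      y <- round(pts[k, 2]) + 1; x <- round(pts[k, 1]) + 1
      ys <- max(1, y - 1):min(d[1], y + 1)
      xs <- max(1, x - 1):min(d[2], x + 1)
      if (is3d) {
        z <- round(pts[k, 3]) + 1
        zs <- max(1, z - 1):min(d[3], z + 1)
        visited[ys, xs, zs] <<- cid
      } else visited[ys, xs] <<- cid
    }
  }
  visited_at <- function(p) {
    y <- round(p[2]) + 1; x <- round(p[1]) + 1
    if (y < 1 || y > d[1] || x < 1 || x > d[2]) return(-1L)
    if (is3d) {
      z <- round(p[3]) + 1
      if (z < 1 || z > d[3]) return(-1L)
      visited[y, x, z]
    } else visited[y, x]
  }
  in_bounds <- function(p) {
    p[1] >= 0 && p[1] <= d[2] - 1 && p[2] >= 0 && p[2] <= d[1] - 1 &&
      (!is3d || (p[3] >= 0 && p[3] <= d[3] - 1))
  }
  trace_dir <- function(p0, dir0, cid, own) {
    pts <- NULL
    p <- p0; dir <- dir0
    reason <- "maxsteps"
    for (step in seq_len(5000L)) {
      p_new <- p + params$point_spacing * dir
      lo <- local_orientation(sm, p_new, nb_radius, floor_level)
      if (is.null(lo)) {
        reason <- "ridge_end"
        break
      }
      # transverse re-centering toward the ridge, capped at 1 px
      perp <- lo$centroid - sum(lo$centroid * dir) * dir
      pn <- sqrt(sum(perp^2))
      if (pn > 1) perp <- perp / pn
      p_new <- p_new + perp
      if (!in_bounds(p_new)) {
        reason <- "bounds"
        break
      }
      if (interp_image(sm, p_new) < params$ridge_threshold) {
        reason <- "ridge_end"
        break
      }
      newdir <- lo$dir
      if (sum(newdir * dir) < 0) newdir <- -newdir
      if (sum(newdir * dir) < turn_cos) {
        reason <- "ridge_end"
        break
      }
      vid <- visited_at(p_new)
      if (vid > 0L && vid != cid) {
        # collided with another curve: keep the colliding point so the tip
        # reaches the other centerline and the collision registers as a
        # junction
        pts <- rbind(pts, p_new)
        reason <- "collision"
        break
      }
      # loop closure onto own earlier trail
      if (!is.null(own) && nrow(own) > 8L) {
        dd2 <- rowSums(sweep(own[seq_len(nrow(own) - 8L), , drop = FALSE],
                             2L, p_new)^2)
        if (min(dd2) < (0.7 * params$point_spacing)^2) {
          reason <- "loop"
          break
        }
      }
      pts <- rbind(pts, p_new)
      own <- rbind(own, p_new)
      p <- p_new; dir <- newdir
    }
    list(pts = pts, reason = reason)
  }
  # replace the wobbly final points of a free (ridge-end) tip with the
  # sub-voxel threshold crossing along a ray anchored on stable interior
  # points, so trace endpoints do not jitter between frames
  refine_tail <- function(pts) {
    n <- nrow(pts)
    drop_k <- 4L
    span <- min(14L, n - drop_k - 2L)
    if (span < 4L) return(pts)
    seg <- pts[(n - drop_k - span):(n - drop_k), , drop = FALSE]
    ctr <- colMeans(seg)
    sv <- svd(sweep(seg, 2L, ctr))
    dir <- sv$v[, 1L]
    if (sum(dir * (seg[nrow(seg), ] - seg[1L, ])) < 0) dir <- -dir
    # anchor: projection of the last kept point onto the fitted line
    a <- ctr + sum((pts[n - drop_k, ] - ctr) * dir) * dir
    t_lo <- 0; t_hi <- NA
    for (t in seq(0.25, drop_k + 4, by = 0.25)) {
      q <- a + t * dir
      if (!in_bounds(q) || interp_image(sm, q) < params$ridge_threshold) {
        t_hi <- t
        break
      }
      t_lo <- t
    }
    if (is.na(t_hi)) return(pts)  # never crossed: keep the traced tip
    for (it in 1:10) {
      mid <- (t_lo + t_hi) / 2
      q <- a + mid * dir
      if (in_bounds(q) && interp_image(sm, q) >= params$ridge_threshold) {
        t_lo <- mid
      } else t_hi <- mid
    }
    if (t_lo <= 0.2) return(pts[seq_len(n - drop_k), , drop = FALSE])
    rbind(pts[seq_len(n - drop_k), , drop = FALSE], a + t_lo * dir)
  }
  for (k in seq_len(nrow(cand))) {
    rc <- cand[k, ]
    p0_full <- if (is3d) c(rc[2] - 1, rc[1] - 1, rc[3] - 1)
               else c(rc[2] - 1, rc[1] - 1, 0)
    if (visited_at(p0_full) > 0L) next
    lo <- local_orientation(sm, p0_full, nb_radius, floor_level)
    if (is.null(lo)) next
    cid <- length(curves) + 1L
    fw <- trace_dir(p0_full, lo$dir, cid, own = matrix(p0_full, nrow = 1L))
    fwd <- fw$pts
    own <- rbind(matrix(p0_full, nrow = 1L), fwd)
    bw <- trace_dir(p0_full, -lo$dir, cid, own = own)
    bwd <- bw$pts
    pts <- rbind(if (!is.null(bwd)) bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
                 matrix(p0_full, nrow = 1L), fwd)
    if (nrow(pts) < 2L) next
    if (fw$reason == "ridge_end") pts <- refine_tail(pts)
    if (bw$reason == "ridge_end") {
      pts <- refine_tail(pts[rev(seq_len(nrow(pts))), , drop = FALSE])
      pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
    }
    if (nrow(pts) < 2L) next
    cv <- ft_curve(pts, id = cid, frame = 0L)
    if (curve_length(cv) < params$min_curve_length) next
    cv <- resample_curve(cv, params$point_spacing)
    curves[[cid]] <- cv
    mark_visited(cv$points, cid)
  }
  # ids may have gaps if short traces were dropped mid-way; renumber
  curves <- Filter(Negate(is.null), curves)
  for (i in seq_along(curves)) curves[[i]]$id <- i
  curves
}

#' Detect junctions among a set of curves
#'
#' Every location where a point of one curve passes within `junction_radius`
#' of a point of another curve (or of a non-adjacent point of the same
#' curve) yields a collision point; collision points within twice the radius
#' of each other are merged by single linkage into one junction at their
#' centroid.
#'
#' @param curves list of [ft_curve] from one frame.
#' @param params [detection_params].
#' @return List of [ft_junction] (tips filled in by
#'   [dissect_at_junctions]); each junction carries an `events` attribute
#'   with the contributing (curve id, point index) rows.
#' @export
detect_junctions <- function(curves, params = detection_params()) {
  if (length(curves) < 1L) return(list())
  rad <- params$junction_radius
  ev_curve <- integer(); ev_index <- integer(); ev_pos <- NULL
  n <- length(curves)
  for (i in seq_len(n)) {
    pi_ <- curves[[i]]$points
    # self-collisions, excluding near-diagonal band
    excl <- max(3L, ceiling(2 * rad / params$point_spacing))
    if (nrow(pi_) > excl + 1L) {
      dm <- point_dist_matrix(pi_, pi_)
      idx <- which(dm <= rad, arr.ind = TRUE)
      idx <- idx[idx[, 1L] < idx[, 2L] - excl, , drop = FALSE]
      if (curves[[i]]$closed && nrow(idx) > 0L) {
        # wrap-around neighbors of a ring are adjacent, not collisions
        idx <- idx[idx[, 2L] - idx[, 1L] < nrow(pi_) - excl, , drop = FALSE]
      }
      if (nrow(idx) > 0L) {
        mid <- (pi_[idx[, 1L], , drop = FALSE] + pi_[idx[, 2L], , drop = FALSE]) / 2
        ev_curve <- c(ev_curve, rep(curves[[i]]$id, 2L * nrow(idx)))
        ev_index <- c(ev_index, idx[, 1L], idx[, 2L])
        ev_pos <- rbind(ev_pos, mid, mid)
      }
    }
    if (i == n) next
    for (j in seq((i + 1L), n)) {
      pj <- curves[[j]]$points
      dm <- point_dist_matrix(pi_, pj)
      idx <- which(dm <= rad, arr.ind = TRUE)
      if (nrow(idx) == 0L) next
      mid <- (pi_[idx[, 1L], , drop = FALSE] + pj[idx[, 2L], , drop = FALSE]) / 2
      ev_curve <- c(ev_curve, rep(curves[[i]]$id, nrow(idx)),
                    rep(curves[[j]]$id, nrow(idx)))
      ev_index <- c(ev_index, idx[, 1L], idx[, 2L])
      ev_pos <- rbind(ev_pos, mid, mid)
    }
  }
  if (length(ev_curve) == 0L) return(list())
  cl <- single_linkage_clusters(ev_pos, 2 * rad)
  frame <- curves[[1L]]$frame
  junctions <- list()
  for (g in sort(unique(cl))) {
    sel <- cl == g
    pos <- colMeans(ev_pos[sel, , drop = FALSE])
    jn <- ft_junction(length(junctions) + 1L, frame, pos)
    attr(jn, "events") <- data.frame(curve_id = ev_curve[sel],
                                     index = ev_index[sel])
    junctions[[length(junctions) + 1L]] <- jn
  }
  junctions
}

# single-linkage clustering of points with a distance cutoff
single_linkage_clusters <- function(pts, cutoff) {
  n <- nrow(pts)
  if (n == 1L) return(1L)
  hc <- stats::hclust(stats::dist(pts), method = "single")
  stats::cutree(hc, h = cutoff)
}

#' Dissect curves at detected junctions
#'
#' Every curve passing through a junction is split at its point closest to
#' the junction position (the cut point is duplicated into both halves).
#' Closed curves are opened at their first cut. Junction tips are the tips
#' of the resulting segments lying at the junction, with outward tangents.
#'
#' @param curves list of [ft_curve].
#' @param junctions list of [ft_junction] from [detect_junctions].
#' @return List with `curves` (the dissected segments, renumbered 1..n) and
#'   `junctions` (with `tips` filled in).
#' @export
dissect_at_junctions <- function(curves, junctions) {
  if (length(junctions) == 0L) {
    return(list(curves = curves, junctions = junctions))
  }
  # per curve: junction cut indices
  cuts <- list()      # curve id -> data.frame(junction, index)
  all_ids <- vapply(curves, `[[`, integer(1), "id")
  for (jn in junctions) {
    ev <- attr(jn, "events")
    for (cid in unique(ev$curve_id)) {
      cv <- curves[[which(all_ids == cid)]]
      d2 <- rowSums(sweep(cv$points, 2L, jn$position)^2)
      # one cut per strand of the curve passing the junction: event indices
      # separated by a long index run belong to different strands
      run_gap <- max(6L, 2L * ceiling(4 / max(1e-9, mean(sqrt(rowSums(
        (cv$points[-1L, , drop = FALSE] -
           cv$points[-nrow(cv$points), , drop = FALSE])^2))))))
      idxs <- sort(unique(ev$index[ev$curve_id == cid]))
      grp <- cumsum(c(1L, diff(idxs) > run_gap))
      key <- as.character(cid)
      snap <- 3L  # cuts this close to a tip snap to it (no sliver segment)
      np <- nrow(cv$points)
      for (g in unique(grp)) {
        ig <- idxs[grp == g]
        cut_idx <- ig[which.min(d2[ig])]
        if (!cv$closed) {
          if (cut_idx <= snap) cut_idx <- 1L
          if (cut_idx > np - snap) cut_idx <- np
        }
        cuts[[key]] <- rbind(cuts[[key]],
                             data.frame(junction = jn$id, index = cut_idx))
      }
    }
  }
  segments <- list()
  seg_meta <- NULL  # data.frame: seg index, end, junction id (NA = free tip)
  add_segment <- function(pts, head_j, tail_j) {
    if (nrow(pts) < 2L) return(invisible(NULL))
    sid <- length(segments) + 1L
    segments[[sid]] <<- ft_curve(pts, id = sid, frame = curves[[1L]]$frame)
    seg_meta <<- rbind(seg_meta,
                       data.frame(seg = sid, end = c("head", "tail"),
                                  junction = c(head_j, tail_j)))
    invisible(NULL)
  }
  for (cv in curves) {
    key <- as.character(cv$id)
    cc <- cuts[[key]]
    if (is.null(cc)) {
      add_segment(cv$points, NA_integer_, NA_integer_)
      next
    }
    cc <- cc[order(cc$index), , drop = FALSE]
    cc <- cc[!duplicated(cc$index), , drop = FALSE]
    p <- cv$points
    n <- nrow(p)
    if (cv$closed) {
      # open the ring at the first cut, then treat as open with shifted cuts
      first <- cc$index[1L]
      ordr <- c(first:n, if (first > 1L) 1:(first - 1L))
      p <- p[ordr, , drop = FALSE]
      p <- rbind(p, p[1L, , drop = FALSE])  # duplicate cut point at both ends
      shift <- function(i) ((i - first) %% n) + 1L
      cc$index <- vapply(cc$index, shift, integer(1))
      cc <- cc[order(cc$index), , drop = FALSE]
      n <- nrow(p)
    }
    bounds <- c(1L, cc$index[cc$index > 1L & cc$index < n], n)
    jn_at <- c(if (cv$closed) cc$junction[1L] else {
                 j <- cc$junction[cc$index == 1L]
                 if (length(j)) j[1L] else NA_integer_
               },
               cc$junction[cc$index > 1L & cc$index < n],
               if (cv$closed) cc$junction[1L] else {
                 j <- cc$junction[cc$index == n]
                 if (length(j)) j[1L] else NA_integer_
               })
    for (s in seq_len(length(bounds) - 1L)) {
      i0 <- bounds[s]; i1 <- bounds[s + 1L]
      add_segment(p[i0:i1, , drop = FALSE], jn_at[s], jn_at[s + 1L])
    }
  }
  # attach tips to junctions
  jn_out <- lapply(junctions, function(jn) { jn$tips <- list(); jn })
  jid_of <- vapply(junctions, `[[`, integer(1), "id")
  for (r in seq_len(nrow(seg_meta))) {
    jid <- seg_meta$junction[r]
    if (is.na(jid)) next
    sid <- seg_meta$seg[r]
    tips <- curve_tips(segments[[sid]])
    tip <- if (seg_meta$end[r] == "head") tips[[1L]] else tips[[2L]]
    slot <- which(jid_of == jid)
    jn_out[[slot]]$tips <- c(jn_out[[slot]]$tips, list(tip))
  }
  list(curves = segments, junctions = jn_out)
}

#' Close near-ring open curves
#'
#' An open curve whose two tips lie within `loop_close_gap` of each other and
#' whose outward tip tangents point toward each other (angle above 2*pi/3) is
#' marked closed.
#'
#' @param curves list of [ft_curve].
#' @param params [detection_params].
#' @return The curve list with qualifying curves closed.
#' @export
close_loops <- function(curves, params = detection_params()) {
  lapply(curves, function(cv) {
    if (cv$closed || n_points(cv) < 6L) return(cv)
    # tracing a full ring overshoots slightly and retraces the first few
    # points on a parallel strand; drop end points that lie on top of the
    # opposite end before judging the closing gap
    tol <- 0.75 * params$point_spacing
    p <- cv$points
    overlap <- function(end_pt, other) {
      min(sqrt(rowSums(sweep(other, 2L, end_pt)^2))) < tol
    }
    repeat {
      n <- nrow(p)
      if (n < 6L) break
      head_band <- p[seq_len(min(8L, n - 2L)), , drop = FALSE]
      if (overlap(p[n, ], head_band)) { p <- p[-n, , drop = FALSE]; next }
      tail_band <- p[seq(max(1L, n - 7L), n), , drop = FALSE]
      if (overlap(p[1L, ], tail_band)) { p <- p[-1L, , drop = FALSE]; next }
      break
    }
    if (nrow(p) < 6L) return(cv)
    gap <- sqrt(sum((p[1L, ] - p[nrow(p), ])^2))
    if (gap > params$loop_close_gap) return(cv)
    trimmed <- ft_curve(p, id = cv$id, frame = cv$frame)
    tips <- curve_tips(trimmed)
    ct <- sum(tips[[1L]]$tangent * tips[[2L]]$tangent)
    if (acos(min(1, max(-1, ct))) > 2 * pi / 3) {
      trimmed$closed <- TRUE
      return(trimmed)
    }
    cv
  })
}

#' Detect the curve network of one frame
#'
#' Runs centerline extraction, loop closing, junction detection and
#' dissection; the result is ready for [local_match_frame].
#'
#' @param image 2D matrix or 3D array.
#' @param frame frame index stored on the curves.
#' @param params [detection_params].
#' @return An [ft_frame] with dissected curves and junctions.
#' @export
detect_frame <- function(image, frame = 0L, params = detection_params()) {
  curves <- extract_centerlines(image, params)
  curves <- close_loops(curves, params)
  for (i in seq_along(curves)) curves[[i]]$frame <- as.integer(frame)
  junctions <- detect_junctions(curves, params)
  dis <- dissect_at_junctions(curves, junctions)
  for (i in seq_along(dis$curves)) dis$curves[[i]]$frame <- as.integer(frame)
  for (i in seq_along(dis$junctions)) dis$junctions[[i]]$frame <- as.integer(frame)
  ft_frame(frame, curves = dis$curves, junctions = dis$junctions)
}
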