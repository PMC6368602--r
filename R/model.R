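#' @importFrom stats rnorm runif rbinom rpois sd coef lm setNames approx
#' @importFrom utils head tail
NULL

#' Construct a curve
#'
#' A curve ("snake") is an ordered sequence of points in pixel coordinates,
#' open or closed, belonging to one time frame. Curves are the unit that is
#' detected per frame, dissected at junctions, spliced back together by local
#' matching, and finally linked across frames into tracks.
#'
#' @param points numeric matrix with one row per point and 2 or 3 columns
#'   (x, y[, z]); a 2-column matrix is padded with z = 0.
#' @param id integer curve identifier, unique within a frame.
#' @param frame non-negative integer frame index.
#' @param closed logical; `TRUE` for a ring (the last point connects back to
#'   the first).
#' @return An object of class `ft_curve`.
#' @export
ft_curve <- function(points, id = 1L, frame = 0L, closed = FALSE) {
  points <- as.matrix(points)
  if (ncol(points) == 2L) points <- cbind(points, 0)
  if (ncol(points) != 3L) stop("points must have 2 or 3 columns")
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) stop("curve points must be finite")
  colnames(points) <- c("x", "y", "z")
  structure(list(id = as.integer(id), frame = as.integer(frame),
                 points = points, closed = isTRUE(closed)),
            class = "ft_curve")
}

#' @export
print.ft_curve <- function(x, ...) {
  cat(sprintf("<curve %d frame %d: %d points, %s, length %.2f px>\n",
              x$id, x$frame, nrow(x$points),
              if (x$closed) "closed" else "open", curve_length(x)))
  invisible(x)
}

n_points <- function(curve) nrow(curve$points)

#' Arc length of a curve
#'
#' Sum of Euclidean distances between consecutive points; for a closed curve
#' the segment from the last point back to the first is included.
#'
#' @param curve an [ft_curve].
#' @return Non-negative length in pixels.
#' @export
curve_length <- function(curve) {
  p <- curve$points
  if (nrow(p) < 2L) stop("curve must have at least 2 points")
  d <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  len <- sum(d)
  if (curve$closed) len <- len + sqrt(sum((p[1L, ] - p[nrow(p), ])^2))
  len
}

cumulative_arclength <- function(points, closed = FALSE) {
  if (closed) points <- rbind(points, points[1L, , drop = FALSE])
  d <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  c(0, cumsum(d))
}

#' Resample a curve at uniform arc-length spacing
#'
#' Linear interpolation along the polyline; endpoints are preserved for open
#' curves. For closed curves the point at arc length 0 is preserved and the
#' curve remains closed.
#'
#' @param curve an [ft_curve].
#' @param spacing target spacing in pixels (> 0).
#' @return A resampled [ft_curve] with the same id, frame and closed flag.
#' @export
resample_curve <- function(curve, spacing) {
  stopifnot(spacing > 0)
  p <- curve$points
  s <- cumulative_arclength(p, curve$closed)
  total <- s[length(s)]
  if (total <= 0) stop("cannot resample a zero-length curve")
  pts <- if (curve$closed) rbind(p, p[1L, , drop = FALSE]) else p
  if (curve$closed) {
    n_new <- max(3L, round(total / spacing))
    # closed: n_new points, last implicit segment closes the loop
    targets <- seq(0, total, length.out = n_new + 1L)[seq_len(n_new)]
  } else {
    n_new <- max(2L, round(total / spacing) + 1L)
    targets <- seq(0, total, length.out = n_new)
  }
  out <- cbind(approx_vec(s, pts[, 1L], targets),
               approx_vec(s, pts[, 2L], targets),
               approx_vec(s, pts[, 3L], targets))
  ft_curve(out, id = curve$id, frame = curve$frame, closed = curve$closed)
}

approx_vec <- function(x, y, xout) {
  # duplicate abscissae (repeated points) are tolerated
  keep <- c(TRUE, diff(x) > 0)
  stats::approx(x[keep], y[keep], xout = xout, rule = 2)$y
}

#' Per-point unit tangents of a curve
#'
#' Central differences in the interior, one-sided at the endpoints of an open
#' curve; wrapped differences for closed curves.
#'
#' @param curve an [ft_curve].
#' @return n x 3 matrix of unit tangent vectors.
#' @export
curve_tangents <- function(curve) {
  p <- curve$points
  n <- nrow(p)
  if (n < 2L) stop("curve must have at least 2 points")
  if (curve$closed) {
    nxt <- p[c(2:n, 1L), , drop = FALSE]
    prv <- p[c(n, 1:(n - 1L)), , drop = FALSE]
    tg <- nxt - prv
  } else {
    tg <- rbind(p[2L, ] - p[1L, ],
                if (n > 2L) p[3:n, , drop = FALSE] - p[1:(n - 2L), , drop = FALSE],
                p[n, ] - p[n - 1L, ])
  }
  normalize_rows(tg)
}

normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Curve tips with outward tangents
#'
#' Returns the two tips (head = first point, tail = last point) of an open
#' curve. The tip tangent is estimated by a principal-direction fit over the
#' outermost `min(5, ceiling(n/2))` points and oriented outward, away from
#' the curve body; a single-segment difference is too noise-dominated for
#' junction matching.
#'
#' @param curve an open [ft_curve].
#' @return List of two `ft_tip` objects.
#' @export
curve_tips <- function(curve) {
  if (curve$closed) return(list())
  p <- curve$points
  n <- nrow(p)
  k <- max(2L, min(5L, ceiling(n / 2)))
  head_dir <- end_direction(p[seq_len(k), , drop = FALSE], outward_first = TRUE)
  tail_dir <- end_direction(p[seq(n - k + 1L, n), , drop = FALSE],
                            outward_first = FALSE)
  list(
    ft_tip(curve$id, "head", p[1L, ], head_dir),
    ft_tip(curve$id, "tail", p[n, ], tail_dir)
  )
}

# principal direction of a short run of points, oriented so that it points
# out of the curve at the first (outward_first) or last row
end_direction <- function(p, outward_first) {
  ctr <- colMeans(p)
  q <- sweep(p, 2L, ctr)
  sv <- svd(q, nu = 0L, nv = 1L)
  dir <- sv$v[, 1L]
  ref <- if (outward_first) p[1L, ] - p[nrow(p), ] else p[nrow(p), ] - p[1L, ]
  if (sum(dir * ref) < 0) dir <- -dir
  nrm <- sqrt(sum(dir^2))
  if (nrm == 0) stop("degenerate tip: coincident points")
  dir / nrm
}

#' Construct a curve tip
#'
#' @param curve_id id of the parent curve.
#' @param end `"head"` or `"tail"`.
#' @param position numeric length-3 position.
#' @param tangent unit 3-vector pointing outward from the curve body.
#' @return An `ft_tip` object.
#' @export
ft_tip <- function(curve_id, end, position, tangent) {
  end <- match.arg(end, c("head", "tail"))
  tangent <- as.numeric(tangent)
  nrm <- sqrt(sum(tangent^2))
  if (!is.finite(nrm) || nrm == 0) stop("tip tangent must be a nonzero vector")
  structure(list(curve_id = as.integer(curve_id), end = end,
                 position = as.numeric(position), tangent = tangent / nrm),
            class = "ft_tip")
}

#' Construct a network junction
#'
#' A junction is a cluster of collision points between curves, carrying the
#' tips of the dissected curve segments incident to it.
#'
#' @param id junction id. @param frame frame index.
#' @param position numeric length-3 centroid of the cluster.
#' @param tips list of [ft_tip] objects incident at the junction.
#' @return An `ft_junction` object.
#' @export
ft_junction <- function(id, frame, position, tips = list()) {
  structure(list(id = as.integer(id), frame = as.integer(frame),
                 position = as.numeric(position), tips = tips),
            class = "ft_junction")
}

#' Construct a network frame
#'
#' Holds all curves of one timepoint. `curves` are the working curves at the
#' current pipeline stage (dissected segments before splicing, spliced curves
#' after); `segments` retains the dissected segments, `splice_map` maps each
#' dissected segment id to the spliced curve id containing it.
#'
#' @param frame frame index.
#' @param curves list of [ft_curve].
#' @param junctions list of [ft_junction].
#' @param segments list of [ft_curve] dissected segments (optional).
#' @param splice_map named integer vector, names = dissected ids.
#' @return An `ft_frame` object.
#' @export
ft_frame <- function(frame, curves = list(), junctions = list(),
                     segments = NULL, splice_map = NULL) {
  ids <- vapply(curves, `[[`, integer(1), "id")
  if (anyDuplicated(ids)) stop("curve ids must be unique within a frame")
  structure(list(frame = as.integer(frame), curves = curves,
                 junctions = junctions,
                 segments = if (is.null(segments)) curves else segments,
                 splice_map = splice_map),
            class = "ft_frame")
}

#' @export
print.ft_frame <- function(x, ...) {
  cat(sprintf("<frame %d: %d curves, %d junctions>\n",
              x$frame, length(x$curves), length(x$junctions)))
  invisible(x)
}

#' Tracking parameters
#'
#' @param eta maximum edge weight in pixels; curve pairs farther apart than
#'   this (in space or time) are indistinguishable and never linked.
#' @param c per-frame gap penalty factor; the weight of a link across a gap of
#'   g frames is inflated by exp(c * (g - 1)). Values up to about 1/frame
#'   favor continuity across consecutive frames.
#' @param grouping logical; `TRUE` tracks whole spliced filaments, `FALSE`
#'   tracks the dissected inter-junction segments.
#' @param max_frame_gap largest frame gap for which correspondence edges are
#'   built; beyond it the gap factor saturates the weight at eta anyway.
#' @param pair_cost_max junction tip pairs with dissimilarity at or above
#'   this value stay unpaired. The default 1.2 accepts a strongly collinear
#'   pair (orientation dissimilarity up to about 0.2) even when the two
#'   curves had different nearest predecessors (temporal term 1), as happens
#'   the first time a growing filament crosses another; poorly aligned pairs
#'   without temporal support are still rejected.
#' @return A `ft_tracking_params` list.
#' @export
tracking_params <- function(eta = 20, c = 1.0, grouping = TRUE,
                            max_frame_gap = 3L, pair_cost_max = 1.2) {
  stopifnot(eta > 0, c >= 0, max_frame_gap >= 1)
  structure(list(eta = eta, c = c, grouping = isTRUE(grouping),
                 max_frame_gap = as.integer(max_frame_gap),
                 pair_cost_max = pair_cost_max),
            class = "ft_tracking_params")
}

#' Detection parameters
#'
#' @param ridge_threshold minimum smoothed intensity for a centerline point.
#' @param smoothing_sigma Gaussian pre-smoothing scale in pixels.
#' @param point_spacing spacing of curve points in pixels.
#' @param junction_radius collision distance for junction detection in pixels.
#' @param min_curve_length curves shorter than this are discarded (pixels).
#' @param loop_close_gap maximum tip-to-tip gap for closing a near-ring.
#' @return A `ft_detection_params` list.
#' @export
detection_params <- function(ridge_threshold = 12, smoothing_sigma = 1.0,
                             point_spacing = 1, junction_radius = 2,
                             min_curve_length = 5, loop_close_gap = 3) {
  vals <- c(ridge_threshold, smoothing_sigma, point_spacing,
            junction_radius, min_curve_length, loop_close_gap)
  if (any(vals <= 0)) stop("all detection parameters must be positive")
  structure(list(ridge_threshold = ridge_threshold,
                 smoothing_sigma = smoothing_sigma,
                 point_spacing = point_spacing,
                 junction_radius = junction_radius,
                 min_curve_length = min_curve_length,
                 loop_close_gap = loop_close_gap),
            class = "ft_detection_params")
}

#' Construct a track
#'
#' @param id track id.
#' @param frames integer vector of frame indices, strictly increasing.
#' @param curve_ids integer vector of curve ids, same length as `frames`.
#' @return An `ft_track` object.
#' @export
ft_track <- function(id, frames, curve_ids) {
  frames <- as.integer(frames); curve_ids <- as.integer(curve_ids)
  if (length(frames) != length(curve_ids)) stop("frames/curve_ids mismatch")
  if (length(frames) < 1L) stop("a track has at least one member")
  if (any(diff(frames) <= 0L)) stop("track frames must be strictly increasing")
  structure(list(id = as.integer(id), frames = frames, curve_ids = curve_ids),
            class = "ft_track")
}

#' @export
print.ft_track <- function(x, ...) {
  cat(sprintf("<track %d: frames %s>\n", x$id,
              paste(x$frames, collapse = ",")))
  invisible(x)
}

# full pairwise Euclidean distance matrix between two point matrices
point_dist_matrix <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  m <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  m[m < 0] <- 0
  sqrt(m)
}
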