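#' Detect and track a whole image sequence
#'
#' The full pipeline: per-frame centerline extraction, junction detection
#' and dissection, temporally consistent local matching against the previous
#' frame, then global k-partite correspondence across all frames.
#'
#' @param images list of 2D matrices or 3D arrays (one per frame).
#' @param detection [detection_params].
#' @param tracking [tracking_params]; `grouping` selects whether tracks run
#'   over spliced filaments or dissected inter-junction segments.
#' @return List with `frames` (spliced [ft_frame] per timepoint), `graph`
#'   and `tracks`.
#' @export
track_network <- function(images, detection = detection_params(),
                          tracking = tracking_params()) {
  frames <- vector("list", length(images))
  prev <- NULL
  for (t in seq_along(images)) {
    raw <- detect_frame(images[[t]], frame = t - 1L, params = detection)
    frames[[t]] <- local_match_frame(raw, prev, tracking)
    prev <- frames[[t]]
  }
  track_frames(frames, tracking)
}

#' Track pre-extracted curve frames
#'
#' @param frames list of spliced [ft_frame] (from [local_match_frame] or
#'   assembled by the caller).
#' @param tracking [tracking_params].
#' @return List with `frames`, `graph`, `tracks`.
#' @export
track_frames <- function(frames, tracking = tracking_params()) {
  graph <- build_graph(frames, tracking)
  tracks <- solve_path_cover(graph, tracking)
  list(frames = frames, graph = graph, tracks = tracks)
}

#' Build dissected, locally matched frames from bare per-frame curve lists
#'
#' Convenience for tracking externally produced curves: runs junction
#' detection, dissection and local matching on each frame's curves.
#'
#' @param curves_by_frame list (one element per frame) of lists of
#'   [ft_curve].
#' @param detection [detection_params].
#' @param tracking [tracking_params].
#' @return List of spliced [ft_frame].
#' @export
frames_from_curves <- function(curves_by_frame,
                               detection = detection_params(),
                               tracking = tracking_params()) {
  out <- vector("list", length(curves_by_frame))
  prev <- NULL
  for (t in seq_along(curves_by_frame)) {
    cs <- curves_by_frame[[t]]
    for (i in seq_along(cs)) {
      cs[[i]]$frame <- t - 1L
      cs[[i]]$id <- i
    }
    junctions <- detect_junctions(cs, detection)
    dis <- dissect_at_junctions(cs, junctions)
    for (i in seq_along(dis$curves)) dis$curves[[i]]$frame <- t - 1L
    raw <- ft_frame(t - 1L, curves = dis$curves, junctions = dis$junctions)
    out[[t]] <- local_match_frame(raw, prev, tracking)
    prev <- out[[t]]
  }
  out
}
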