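#' Average symmetric distance between two curves
#'
#' Mean over the points of each curve of the distance to the nearest point of
#' the other curve, averaged over both directions:
#' d(a, b) = 1/(2|a|) sum_x min_y ||x - y|| + 1/(2|b|) sum_y min_x ||y - x||.
#'
#' @param a,b [ft_curve] objects (or bare point matrices).
#' @return Non-negative distance in pixels.
#' @export
curve_distance <- function(a, b) {
  pa <- if (inherits(a, "ft_curve")) a$points else as.matrix(a)
  pb <- if (inherits(b, "ft_curve")) b$points else as.matrix(b)
  if (nrow(pa) < 1L || nrow(pb) < 1L) stop("curves must be non-empty")
  dm <- point_dist_matrix(pa, pb)
  mean(apply(dm, 1L, min)) / 2 + mean(apply(dm, 2L, min)) / 2
}

#' Correspondence edge weight between curves of different frames
#'
#' For a curve in frame l and one in frame m > l, the weight is
#' exp(c * (m - l - 1)) * d(a, b) when that value is below eta, and eta
#' otherwise. eta is the dissimilarity ceiling beyond which curves are not
#' worth distinguishing; a link across a frame gap is penalized
#' exponentially.
#'
#' @param a,b [ft_curve] objects with `frame(a) < frame(b)`.
#' @param params [tracking_params].
#' @return Weight in (0, eta].
#' @export
edge_weight <- function(a, b, params = tracking_params()) {
  if (a$frame >= b$frame) stop("edge must point forward in time")
  w <- exp(params$c * (b$frame - a$frame - 1)) * curve_distance(a, b)
  min(w, params$eta)
}

#' Build the k-partite correspondence graph
#'
#' Vertices are the curves of all frames (spliced curves when grouping is on,
#' dissected segments when off); directed edges run forward in time between
#' frames at most `max_frame_gap` apart. Edges whose weight would reach eta
#' are omitted: they are indistinguishable from "no correspondence".
#'
#' @param frames list of [ft_frame].
#' @param params [tracking_params].
#' @return A `ft_graph` list with elements `vertices` (data.frame: vid,
#'   frame, curve_id) , `edges` (data.frame: from, to, weight; vertex
#'   indices), and `curves` (list of the vertex curves).
#' @export
build_graph <- function(frames, params = tracking_params()) {
  stopifnot(length(frames) >= 1L)
  curves <- list(); vframe <- integer(); vcid <- integer()
  for (fr in frames) {
    cs <- if (params$grouping) fr$curves else fr$segments
    for (cv in cs) {
      curves[[length(curves) + 1L]] <- cv
      vframe <- c(vframe, cv$frame)
      vcid <- c(vcid, cv$id)
    }
  }
  n <- length(curves)
  vertices <- data.frame(vid = seq_len(n), frame = vframe, curve_id = vcid)
  # cheap lower bound on curve_distance: centroid separation minus radii
  cent <- t(vapply(curves, function(cv) colMeans(cv$points), numeric(3)))
  radius <- vapply(seq_len(n), function(i) {
    sqrt(max(rowSums(sweep(curves[[i]]$points, 2L, cent[i, ])^2)))
  }, numeric(1))
  from <- integer(); to <- integer(); wt <- numeric()
  for (i in seq_len(n)) {
    gap <- vframe - vframe[i]
    cand <- which(gap >= 1L & gap <= params$max_frame_gap)
    for (j in cand) {
      gapfac <- exp(params$c * (vframe[j] - vframe[i] - 1))
      lb <- sqrt(sum((cent[i, ] - cent[j, ])^2)) - radius[i] - radius[j]
      if (lb > 0 && gapfac * lb >= params$eta) next
      w <- edge_weight(curves[[i]], curves[[j]], params)
      if (w < params$eta) {
        from <- c(from, i); to <- c(to, j); wt <- c(wt, w)
      }
    }
  }
  structure(list(vertices = vertices,
                 edges = data.frame(from = from, to = to, weight = wt),
                 curves = curves, eta = params$eta),
            class = "ft_graph")
}

#' Solve the minimum path cover of the correspondence graph
#'
#' The path cover minimizing total edge weight is found by bipartite
#' reduction: two copies of the vertex set form a complete bipartite graph
#' whose (i, j) cost is the edge weight for a forward edge and eta for
#' missing, intra-frame or backward pairs; a minimum-cost perfect matching
#' (Hungarian algorithm) then yields successor links wherever the matched
#' cost is below eta. Matches at cost eta are track breaks, so an isolated
#' curve forms a zero-length track.
#'
#' @param graph a `ft_graph` from [build_graph].
#' @param params [tracking_params].
#' @return List of [ft_track], in order of first appearance.
#' @export
solve_path_cover <- function(graph, params = tracking_params()) {
  n <- nrow(graph$vertices)
  if (n == 0L) return(list())
  eta <- graph$eta
  succ <- rep(NA_integer_, n)
  if (n > 1L && nrow(graph$edges) > 0L) {
    cost <- matrix(eta, n, n)
    cost[cbind(graph$edges$from, graph$edges$to)] <- graph$edges$weight
    sol <- clue::solve_LSAP(cost, maximum = FALSE)
    match_to <- as.integer(sol)
    keep <- cost[cbind(seq_len(n), match_to)] < eta
    succ[keep] <- match_to[keep]
  }
  # chains of successor links are the tracks
  has_pred <- rep(FALSE, n)
  has_pred[succ[!is.na(succ)]] <- TRUE
  ord <- order(graph$vertices$frame, graph$vertices$curve_id)
  tracks <- list()
  for (v in ord) {
    if (has_pred[v]) next
    chain <- v
    while (!is.na(succ[chain[length(chain)]])) {
      chain <- c(chain, succ[chain[length(chain)]])
    }
    tracks[[length(tracks) + 1L]] <- ft_track(
      id = length(tracks) + 1L,
      frames = graph$vertices$frame[chain],
      curve_ids = graph$vertices$curve_id[chain])
  }
  tracks
}

#' Objective value of a path cover
#'
#' Sum of the weights of the successor links realized by the tracks plus eta
#' for every unlinked vertex copy (track break) -- exactly the cost of the
#' corresponding perfect matching in the bipartite reduction, so solutions
#' can be compared against enumeration.
#'
#' @param tracks list of [ft_track]. @param graph `ft_graph`.
#' @return Total objective value.
#' @export
path_cover_cost <- function(tracks, graph) {
  key <- paste(graph$vertices$frame, graph$vertices$curve_id)
  vid_of <- setNames(graph$vertices$vid, key)
  wmat <- new.env()
  for (k in seq_len(nrow(graph$edges))) {
    assign(paste(graph$edges$from[k], graph$edges$to[k]),
           graph$edges$weight[k], envir = wmat)
  }
  total <- 0; n_links <- 0L
  for (tr in tracks) {
    if (length(tr$frames) < 2L) next
    for (k in seq_len(length(tr$frames) - 1L)) {
      a <- vid_of[[paste(tr$frames[k], tr$curve_ids[k])]]
      b <- vid_of[[paste(tr$frames[k + 1L], tr$curve_ids[k + 1L])]]
      kk <- paste(a, b)
      w <- if (exists(kk, envir = wmat)) get(kk, envir = wmat) else graph$eta
      total <- total + w
      n_links <- n_links + 1L
    }
  }
  total + graph$eta * (nrow(graph$vertices) - n_links)
}
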