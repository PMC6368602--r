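#' Orientation dissimilarity between two curve tips
#'
#' Two tips of the same curve get the maximum value 1 (a curve should not be
#' spliced to itself at a junction). Otherwise the value is 1 - theta/pi,
#' where theta in [0, pi] is the angle between the outward tip tangents: tips
#' facing each other across a junction (theta near pi) have low
#' dissimilarity.
#'
#' @param tip_i,tip_j [ft_tip] objects.
#' @return Dissimilarity in [0, 1].
#' @export
d_ori <- function(tip_i, tip_j) {
  if (tip_i$curve_id == tip_j$curve_id) return(1)
  ct <- sum(tip_i$tangent * tip_j$tangent)
  ct <- min(1, max(-1, ct))
  1 - acos(ct) / pi
}

#' One-way distance between two curves
#'
#' Asymmetric curve-to-curve distance combining proximity and orientation:
#' for each point y of `u`, the distance to the nearest point z of `r` is
#' weighted by exp(-|cos phi|), with phi the angle between the tangents at y
#' and z. Parallel well-aligned curves at distance d score d/e; misaligned
#' ones score the full d.
#'
#' @param u,r [ft_curve] objects.
#' @return Non-negative one-way distance.
#' @export
one_way_distance <- function(u, r) {
  if (n_points(u) < 1L || n_points(r) < 1L) stop("curves must be non-empty")
  if (n_points(u) < 2L || n_points(r) < 2L) {
    # tangents undefined for singletons: orientation factor drops to 1
    dm <- point_dist_matrix(u$points, r$points)
    return(mean(apply(dm, 1L, min)))
  }
  tu <- curve_tangents(u)
  tr <- curve_tangents(r)
  dm <- point_dist_matrix(u$points, r$points)
  nearest <- max.col(-dm, ties.method = "first")
  dmin <- dm[cbind(seq_len(nrow(dm)), nearest)]
  cosphi <- abs(rowSums(tu * tr[nearest, , drop = FALSE]))
  mean(dmin * exp(-pmin(1, cosphi)))
}

#' Closest curve of the previous frame
#'
#' Argmin of the one-way distance from `u` to the already locally matched
#' curves of the previous frame. Ties break toward the smaller curve id.
#'
#' @param u an [ft_curve].
#' @param prev_frame an [ft_frame] (spliced), or `NULL`.
#' @return List with `curve` (the closest [ft_curve] or `NULL`), `f` (its
#'   one-way distance) and `id`.
#' @export
closest_prev_curve <- function(u, prev_frame) {
  if (is.null(prev_frame) || length(prev_frame$curves) == 0L) {
    return(list(curve = NULL, f = NA_real_, id = NA_integer_))
  }
  ids <- vapply(prev_frame$curves, `[[`, integer(1), "id")
  ord <- order(ids)
  fs <- vapply(prev_frame$curves[ord], function(r) one_way_distance(u, r),
               numeric(1))
  best <- which.min(fs)   # first minimum = smallest id on ties
  list(curve = prev_frame$curves[[ord[best]]], f = fs[best],
       id = ids[ord[best]])
}

#' Temporal dissimilarity between two curve tips
#'
#' If the two tips' curves are closest to different curves of the previous
#' frame, the dissimilarity is 1. If they share the same closest previous
#' curve, it is |f_i - f_j|, the difference of their one-way distances to
#' that common curve, clamped to [0, 1] so it never exceeds the
#' different-predecessor penalty.
#'
#' @param tip_i,tip_j [ft_tip] objects.
#' @param prev_assign named list keyed by curve id (as character), each
#'   element a list with `id` and `f` from [closest_prev_curve].
#' @return Dissimilarity in [0, 1].
#' @export
d_tem <- function(tip_i, tip_j, prev_assign) {
  ai <- prev_assign[[as.character(tip_i$curve_id)]]
  aj <- prev_assign[[as.character(tip_j$curve_id)]]
  if (is.null(ai) || is.null(aj) || is.na(ai$id) || is.na(aj$id)) return(0)
  if (ai$id != aj$id) return(1)
  min(1, abs(ai$f - aj$f))
}

# closest-previous-curve assignment for every distinct curve incident at the
# given junctions
build_prev_assign <- function(curves, prev_frame) {
  out <- list()
  for (cv in curves) {
    key <- as.character(cv$id)
    if (is.null(out[[key]])) {
      cp <- closest_prev_curve(cv, prev_frame)
      out[[key]] <- list(id = cp$id, f = cp$f)
    }
  }
  out
}

#' Match curve tips at a junction
#'
#' Computes the pairwise dissimilarity D = D_ori + D_tem (D_ori alone when
#' there is no previous frame) between the tips incident at a junction and
#' solves the exact minimum-cost matching in which every tip either joins
#' one partner (admissible only when D is below `pair_cost_max`) or stays
#' single at cost `pair_cost_max / 2`, so a pair forms exactly when it beats
#' leaving both tips single.
#'
#' @param junction an [ft_junction].
#' @param curves list of [ft_curve] of the current frame (for D_tem).
#' @param prev_frame previous [ft_frame] (spliced) or `NULL`.
#' @param params [tracking_params].
#' @param prev_assign optional precomputed assignment cache
#'   (see [closest_prev_curve]); computed on the fly when missing.
#' @return A `ft_tip_pairing`: list with `junction_id`, `pairs` (list of
#'   2-element tip lists) and `unpaired` (list of tips).
#' @export
match_tips_at_junction <- function(junction, curves = list(),
                                   prev_frame = NULL,
                                   params = tracking_params(),
                                   prev_assign = NULL) {
  tips <- junction$tips
  t_n <- length(tips)
  if (t_n < 2L) {
    return(structure(list(junction_id = junction$id, pairs = list(),
                          unpaired = tips), class = "ft_tip_pairing"))
  }
  use_tem <- !is.null(prev_frame) && length(prev_frame$curves) > 0L
  if (use_tem && is.null(prev_assign)) {
    ids <- vapply(tips, `[[`, integer(1), "curve_id")
    inc <- curves[vapply(curves, function(cv) cv$id %in% ids, logical(1))]
    prev_assign <- build_prev_assign(inc, prev_frame)
  }
  cost <- matrix(0, t_n, t_n)
  admissible <- matrix(FALSE, t_n, t_n)
  for (i in seq_len(t_n)) {
    for (j in seq_len(t_n)) {
      if (i == j) next
      ori <- d_ori(tips[[i]], tips[[j]])
      d <- ori
      if (use_tem) d <- d + d_tem(tips[[i]], tips[[j]], prev_assign)
      cost[i, j] <- d
      # a splice continues a filament through the junction, so beyond the
      # dissimilarity budget the outward tip tangents must at least be
      # obtuse (d_ori < 0.5); without this gate, junctions with an odd tip
      # count happily splice fibers that cross at moderate angles
      admissible[i, j] <- d < params$pair_cost_max && ori < 0.5
    }
  }
  # exact minimum-cost matching: each tip either joins one partner (at the
  # pair's dissimilarity, admissible only below pair_cost_max) or stays
  # single at price pair_cost_max / 2, so a pair is formed exactly when it
  # beats two singles. An assignment-problem relaxation is unsuitable here:
  # on junctions with an odd tip count its optimum can be a cyclic
  # permutation that contains no usable pair at all.
  single <- params$pair_cost_max / 2
  best_cost <- t_n * single + 1
  best_pairs <- list()
  rec <- function(avail, acc, cur) {
    if (acc >= best_cost) return(invisible())
    if (length(avail) == 0L) {
      best_cost <<- acc
      best_pairs <<- cur
      return(invisible())
    }
    i <- avail[1L]; rest <- avail[-1L]
    for (j in rest) {
      if (admissible[i, j]) {
        rec(rest[rest != j], acc + cost[i, j], c(cur, list(c(i, j))))
      }
    }
    rec(rest, acc + single, cur)  # tip i stays single
  }
  rec(seq_len(t_n), 0, list())
  paired <- rep(FALSE, t_n)
  pairs <- lapply(best_pairs, function(pr) {
    paired[pr] <<- TRUE
    list(tips[[pr[1L]]], tips[[pr[2L]]])
  })
  structure(list(junction_id = junction$id, pairs = pairs,
                 unpaired = tips[!paired]),
            class = "ft_tip_pairing")
}

#' Splice dissected curves through matched tip pairs
#'
#' Curves connected through paired tips are concatenated transitively into
#' spliced curves; a pairing chain that closes on itself yields a closed
#' curve (ring). Unpaired curves pass through unchanged. The returned frame
#' keeps the dissected segments and records which spliced curve each segment
#' ended up in.
#'
#' @param frame an [ft_frame] whose `curves` are dissected segments.
#' @param pairings list of `ft_tip_pairing` from [match_tips_at_junction].
#' @return A new [ft_frame] with spliced `curves`, original `segments`, and
#'   `splice_map`.
#' @export
splice_curves <- function(frame, pairings) {
  curves <- frame$curves
  ids <- vapply(curves, `[[`, integer(1), "id")
  idx_of <- setNames(seq_along(curves), ids)
  # tip slots: (curve index, end); partner[slot] = paired slot or NA
  slot <- function(ci, end) 2L * ci - (end == "head")
  partner <- rep(NA_integer_, 2L * length(curves))
  for (pg in pairings) {
    for (pr in pg$pairs) {
      s1 <- slot(idx_of[[as.character(pr[[1]]$curve_id)]], pr[[1]]$end)
      s2 <- slot(idx_of[[as.character(pr[[2]]$curve_id)]], pr[[2]]$end)
      if (!is.na(partner[s1]) || !is.na(partner[s2])) {
        stop("inconsistent pairing: a tip appears in more than one pair")
      }
      partner[s1] <- s2; partner[s2] <- s1
    }
  }
  other_end <- function(s) if (s %% 2L == 0L) s - 1L else s + 1L
  curve_of_slot <- function(s) (s + 1L) %/% 2L
  visited <- rep(FALSE, length(curves))
  spliced <- list(); splice_map <- integer()
  new_id <- 0L
  # walk a chain starting at entry slot `s0` of an unvisited curve
  walk <- function(s0) {
    pts <- NULL; members <- integer(); s <- s0; closed <- FALSE
    repeat {
      ci <- curve_of_slot(s)
      members <- c(members, ci)
      visited[ci] <<- TRUE
      p <- curves[[ci]]$points
      if (s %% 2L == 0L) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]  # enter at tail
      if (!is.null(pts) && nrow(pts) > 0L &&
          sum(abs(pts[nrow(pts), ] - p[1L, ])) < 1e-9) {
        p <- p[-1L, , drop = FALSE]  # deduplicate shared cut point
      }
      pts <- rbind(pts, p)
      s_exit <- other_end(s)
      s_next <- partner[s_exit]
      if (is.na(s_next)) break
      if (curve_of_slot(s_next) == curve_of_slot(s0) && s_next == s0) {
        closed <- TRUE
        break
      }
      s <- s_next
    }
    list(points = pts, members = members, closed = closed)
  }
  for (ci in order(ids)) {
    if (visited[ci]) next
    if (curves[[ci]]$closed) {  # already-closed curves pass through
      visited[ci] <- TRUE
      new_id <- new_id + 1L
      spliced[[new_id]] <- ft_curve(curves[[ci]]$points, id = new_id,
                                    frame = frame$frame, closed = TRUE)
      splice_map[as.character(ids[ci])] <- new_id
      next
    }
    # find a free entry slot, else the chain is a cycle: start anywhere
    s_head <- slot(ci, "head"); s_tail <- slot(ci, "tail")
    s0 <- if (is.na(partner[s_head])) s_head
          else if (is.na(partner[s_tail])) s_tail
          else s_head
    # for open chains, make sure we start at the free end of the whole chain
    if (!is.na(partner[s0])) {
      s <- s0; steps <- 0L
      repeat {
        prv <- partner[s]
        if (is.na(prv)) break
        s <- other_end(prv)
        steps <- steps + 1L
        if (curve_of_slot(s) == ci && s == s0) break  # cycle
        if (steps > 2L * length(curves)) stop("pairing graph is malformed")
      }
      s0 <- s
    }
    if (visited[curve_of_slot(s0)]) next
    res <- walk(s0)
    if (res$closed && nrow(res$points) > 1L &&
        sum(abs(res$points[1L, ] - res$points[nrow(res$points), ])) < 1e-9) {
      res$points <- res$points[-nrow(res$points), , drop = FALSE]
    }
    new_id <- new_id + 1L
    spliced[[new_id]] <- ft_curve(res$points, id = new_id,
                                  frame = frame$frame, closed = res$closed)
    for (m in res$members) splice_map[as.character(ids[m])] <- new_id
  }
  ft_frame(frame$frame, curves = spliced, junctions = frame$junctions,
           segments = curves, splice_map = splice_map)
}

#' Locally match and splice one frame
#'
#' Runs [match_tips_at_junction] at every junction of the frame (sharing one
#' closest-previous-curve cache) and splices the dissected curves through the
#' accepted pairs.
#'
#' @param frame an [ft_frame] with dissected `curves` and `junctions`.
#' @param prev_frame the previous, already spliced [ft_frame], or `NULL` for
#'   the first frame (orientation cue only).
#' @param params [tracking_params].
#' @return The spliced [ft_frame].
#' @export
local_match_frame <- function(frame, prev_frame = NULL,
                              params = tracking_params()) {
  if (length(frame$junctions) == 0L) {
    return(ft_frame(frame$frame, curves = frame$curves,
                    junctions = frame$junctions, segments = frame$curves,
                    splice_map = setNames(
                      vapply(frame$curves, `[[`, integer(1), "id"),
                      vapply(frame$curves, `[[`, integer(1), "id"))))
  }
  prev_assign <- NULL
  if (!is.null(prev_frame) && length(prev_frame$curves) > 0L) {
    inc_ids <- unique(unlist(lapply(frame$junctions, function(j) {
      vapply(j$tips, `[[`, integer(1), "curve_id")
    })))
    inc <- frame$curves[vapply(frame$curves,
                               function(cv) cv$id %in% inc_ids, logical(1))]
    prev_assign <- build_prev_assign(inc, prev_frame)
  }
  pairings <- lapply(frame$junctions, function(j) {
    match_tips_at_junction(j, curves = frame$curves, prev_frame = prev_frame,
                           params = params, prev_assign = prev_assign)
  })
  splice_curves(frame, pairings)
}
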