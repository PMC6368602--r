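## Text and TIFF I/O. Native curve/track format: line-oriented sections
##   #frame <index>
##   #curve <id> <closed 0|1> <npoints>   followed by npoints "x y z" lines
##   #junctions <n>                       followed by n "x y z" lines
##   #tracks <n>                          followed by n track rows:
##   <track id> <frame>:<curve id> ...

# intensities are stored in 32-bit TIFF scaled into [0, 1] by this factor
INTENSITY_SCALE <- 4096

#' Write an image sequence as TIFF
#'
#' A list of 2D matrices is written as one multi-page TIFF; a list of 3D
#' arrays is written as per-timepoint multi-page stacks `t000.tif`,
#' `t001.tif`, ... inside `path` (created as a directory).
#'
#' @param images list of matrices or 3D arrays.
#' @param path output file (2D) or directory (3D).
#' @return `path`, invisibly.
#' @export
write_image_sequence <- function(images, path) {
  stopifnot(length(images) >= 1L)
  is3d <- length(dim(images[[1L]])) == 3L
  if (!is3d) {
    tiff::writeTIFF(lapply(images, function(m) m / INTENSITY_SCALE),
                    path, bits.per.sample = 32L)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (t in seq_along(images)) {
      a <- images[[t]]
      slices <- lapply(seq_len(dim(a)[3L]),
                       function(z) a[, , z] / INTENSITY_SCALE)
      tiff::writeTIFF(slices,
                      file.path(path, sprintf("t%03d.tif", t - 1L)),
                      bits.per.sample = 32L)
    }
  }
  invisible(path)
}

#' Read an image sequence
#'
#' A single multi-page TIFF yields a list of 2D frames; a directory of
#' per-timepoint multi-page TIFF stacks (read in file-name order) yields a
#' list of 3D arrays.
#'
#' @param path TIFF file or directory of TIFF stacks.
#' @return List of matrices or 3D arrays, in temporal order.
#' @export
read_image_sequence <- function(path) {
  read_stack <- function(f) {
    pages <- tiff::readTIFF(f, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1L]  # drop extra channels
      p * INTENSITY_SCALE
    })
    pages
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF files found in ", path)
    stacks <- lapply(files, function(f) {
      pages <- read_stack(f)
      array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
    })
    nd <- vapply(stacks, function(s) length(dim(s)), integer(1))
    if (length(unique(nd)) != 1L) stop("mixed dimensionality in ", path)
    stacks
  } else {
    if (!file.exists(path)) stop("cannot read image file ", path)
    read_stack(path)
  }
}

fmt_point <- function(p) sprintf("%.6f %.6f %.6f", p[1L], p[2L], p[3L])

#' Write frames and tracks to the native text format
#'
#' @param path output file.
#' @param frames list of [ft_frame] (the curves referenced by the tracks are
#'   written).
#' @param tracks list of [ft_track] (optional).
#' @param grouping write spliced curves (`TRUE`) or dissected segments.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(path, frames, tracks = list(), grouping = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(sprintf("#frame %d", fr$frame), con)
    cs <- if (grouping) fr$curves else fr$segments
    for (cv in cs) {
      writeLines(sprintf("#curve %d %d %d", cv$id,
                         as.integer(cv$closed), nrow(cv$points)), con)
      writeLines(apply(cv$points, 1L, fmt_point), con)
    }
    writeLines(sprintf("#junctions %d", length(fr$junctions)), con)
    for (jn in fr$junctions) writeLines(fmt_point(jn$position), con)
  }
  writeLines(sprintf("#tracks %d", length(tracks)), con)
  for (tr in tracks) {
    writeLines(paste(tr$id, paste(sprintf("%d:%d", tr$frames, tr$curve_ids),
                                  collapse = " ")), con)
  }
  invisible(path)
}

#' Read frames and tracks from the native text format
#'
#' @param path input file written by [write_tracks] (the `#tracks` section
#'   is optional).
#' @return List with `frames` (list of [ft_frame]) and `tracks`.
#' @export
read_tracks <- function(path) {
  lines <- readLines(path)
  parse_err <- function(i, what) {
    stop(sprintf("parse error at line %d: %s", i, what))
  }
  frames <- list(); tracks <- list()
  cur_frame <- NULL; cur_curves <- list(); cur_junctions <- list()
  flush_frame <- function() {
    if (!is.null(cur_frame)) {
      frames[[length(frames) + 1L]] <<- ft_frame(cur_frame, cur_curves,
                                                 cur_junctions)
    }
    cur_curves <<- list(); cur_junctions <<- list()
  }
  read_point <- function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
    if (length(v) != 3L || anyNA(v)) parse_err(i, "expected 'x y z'")
    v
  }
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (startsWith(ln, "#frame")) {
      flush_frame()
      cur_frame <- as.integer(strsplit(ln, "\\s+")[[1L]][2L])
      if (is.na(cur_frame)) parse_err(i, "bad #frame header")
      i <- i + 1L
    } else if (startsWith(ln, "#curve")) {
      f <- strsplit(ln, "\\s+")[[1L]]
      if (length(f) != 4L) parse_err(i, "bad #curve header")
      id <- as.integer(f[2L]); closed <- as.integer(f[3L])
      np <- as.integer(f[4L])
      if (anyNA(c(id, closed, np))) parse_err(i, "bad #curve header")
      if (i + np > length(lines)) parse_err(i, "truncated curve")
      pts <- t(vapply((i + 1L):(i + np), read_point, numeric(3)))
      cur_curves[[length(cur_curves) + 1L]] <-
        ft_curve(pts, id = id, frame = cur_frame, closed = closed == 1L)
      i <- i + np + 1L
    } else if (startsWith(ln, "#junctions")) {
      nj <- as.integer(strsplit(ln, "\\s+")[[1L]][2L])
      if (is.na(nj)) parse_err(i, "bad #junctions header")
      for (k in seq_len(nj)) {
        cur_junctions[[k]] <- ft_junction(k, cur_frame, read_point(i + k))
      }
      i <- i + nj + 1L
    } else if (startsWith(ln, "#tracks")) {
      flush_frame(); cur_frame <- NULL
      nt <- as.integer(strsplit(ln, "\\s+")[[1L]][2L])
      if (is.na(nt)) parse_err(i, "bad #tracks header")
      for (k in seq_len(nt)) {
        f <- strsplit(trimws(lines[i + k]), "\\s+")[[1L]]
        id <- as.integer(f[1L])
        pairs <- strsplit(f[-1L], ":")
        fr_v <- as.integer(vapply(pairs, `[[`, character(1), 1L))
        cid_v <- as.integer(vapply(pairs, `[[`, character(1), 2L))
        if (anyNA(c(id, fr_v, cid_v))) parse_err(i + k, "bad track row")
        tracks[[k]] <- ft_track(id, fr_v, cid_v)
      }
      i <- i + nt + 1L
    } else {
      parse_err(i, paste0("unexpected content '", substr(ln, 1, 30), "'"))
    }
  }
  flush_frame()
  list(frames = frames, tracks = tracks)
}
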