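# Kinematic feature extraction: from cleaned keypoints (and optionally a
# body contour) to the smoothed per-frame channels that every downstream
# statistic consumes. Image coordinates throughout: origin top-left, y
# increases downward; elevation is measured from the side view as
# (tank_floor_y - head_y) / px_per_cm.

#' Construct a feature series
#'
#' A multichannel per-frame kinematic series at a fixed frame rate. All
#' channels share the same length; units are recorded per channel.
#'
#' @param data data.frame of numeric channels, one row per frame.
#' @param frame_rate frames/s.
#' @param units named character vector of units per channel (optional).
#' @return an object of class `feature_series`.
#' @export
feature_series <- function(data, frame_rate, units = NULL) {
  stopifnot(is.data.frame(data))
  assert_scalar_num(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  if (is.null(units)) units <- stats::setNames(rep("", ncol(data)), names(data))
  structure(list(data = data, frame_rate = frame_rate, units = units),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %d frames x %d channels @ %g fps\n",
              nrow(x$data), ncol(x$data), x$frame_rate))
  cat(" channels:", paste(names(x$data), collapse = ", "), "\n")
  invisible(x)
}

#' Describe the stimulus-side geometry of an arena
#'
#' The stimulus (opponent tank or monitor) sits flush against one wall of
#' the focal tank. Orientation is measured against the inward normal of
#' that wall, and distance-to-stimulus against the wall line.
#'
#' @param side which tank wall the stimulus is behind
#'   (`"right"`, `"left"`, `"top"`, `"bottom"`, in image coordinates).
#' @param position_px coordinate of the wall line in pixels (x for
#'   left/right, y for top/bottom).
#' @param tank_floor_y for the side view: pixel y of the tank floor, used to
#'   convert head height to elevation.
#' @return a `stimulus_geometry` list.
#' @export
stimulus_geometry <- function(side = c("right", "left", "top", "bottom"),
                              position_px = 0, tank_floor_y = NA_real_) {
  side <- match.arg(side)
  normal_deg <- switch(side, right = 0, left = 180, bottom = 90, top = -90)
  structure(list(side = side, position_px = position_px,
                 normal_deg = normal_deg, tank_floor_y = tank_floor_y),
            class = "stimulus_geometry")
}

#' Tail geometry from a body contour
#'
#' Finds the contour points nearest the tracked head and tail markers, fits
#' least-squares lines through the 100 contour points surrounding each, and
#' reports the angle between the tail line and the body line plus the
#' perpendicular deviation of the contour tail point from the body line.
#'
#' @param contour two-column matrix (x, y in px) of an ordered closed body
#'   contour with at least 200 points.
#' @param head_kp,tail_kp length-2 numeric, tracked head/tail marker (px).
#' @param px_per_cm scale used for the deviation (deviation is returned in
#'   cm; pass 1 to keep pixels).
#' @param n_fit number of surrounding contour points used for each line fit
#'   (default 100, i.e. 50 on each side of the anchor).
#' @return list with `tail_angle` (deg, in \[0, 90\]), `tail_deviation`
#'   (cm), `contour_head`, `contour_tail` (each length-2 numeric).
#' @export
tail_geometry <- function(contour, head_kp, tail_kp, px_per_cm = 1,
                          n_fit = 100) {
  contour <- as.matrix(contour)
  if (ncol(contour) != 2L) stopf("`contour` must have two columns (x, y)")
  n <- nrow(contour)
  if (n < 2 * n_fit) stopf("contour needs >= %d points for the line fits", 2 * n_fit)
  nearest <- function(p) which.min((contour[, 1] - p[1])^2 + (contour[, 2] - p[2])^2)
  ih <- nearest(head_kp)
  it <- nearest(tail_kp)
  # indices of the n_fit points surrounding an anchor, wrapping around the
  # closed polygon
  surround <- function(i) ((i - n_fit %/% 2):(i + n_fit %/% 2 - 1) - 1) %% n + 1
  fit_dir <- function(idx) {
    pts <- contour[idx, , drop = FALSE]
    pts <- sweep(pts, 2, colMeans(pts))
    s <- svd(pts, nu = 0, nv = 2)
    if (s$d[1] < .Machine$double.eps^0.5) {
      warnf("degenerate contour neighbourhood; zero-angle line assumed")
      return(c(1, 0))
    }
    s$v[, 1]
  }
  dir_head <- fit_dir(surround(ih)) # body line direction
  dir_tail <- fit_dir(surround(it)) # tail line direction
  cosang <- abs(sum(dir_head * dir_tail)) # lines: direction sign-free
  tail_angle <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  # perpendicular distance from the contour tail point to the body line
  # (through the contour head point, along dir_head)
  vht <- contour[it, ] - contour[ih, ]
  perp <- vht - sum(vht * dir_head) * dir_head
  tail_deviation <- sqrt(sum(perp^2)) / px_per_cm
  list(tail_angle = tail_angle, tail_deviation = tail_deviation,
       contour_head = contour[ih, ], contour_tail = contour[it, ])
}

#' Compute kinematic features from cleaned keypoints
#'
#' Extracts the per-frame channels used by the classifier and all
#' statistics: `orientation` (unsigned angle in \[0, 180\] between the body
#' axis, centroid to nose, and the inward normal of the stimulus wall),
#' `heading` (signed body-axis angle, deg), `speed` (cm/s, from centroid
#' displacement), `turning_angle` (signed deg/frame change of heading),
#' head/centroid positions (cm), operculum geometry (`operculum_angle`:
#' angle at the nose subtended by the two operculum tips;
#' `operculum_angle_left`/`_right`: angle of each tip off the body line;
#' `operculum_midline_dist`: mean perpendicular distance of the tips from
#' the body axis, cm), `distance_to_stimulus` (cm) and, when a side view is
#' supplied, `elevation` (cm above tank floor) and z positions. Channels
#' that need the missing view are absent (not zero-filled); the attribute
#' `absent_channels` lists them.
#'
#' @param table cleaned top-view [keypoint_table()] with body parts `nose`,
#'   `left_operculum`, `right_operculum`, `centroid`, `tail` (a `head`
#'   part is used when present, else the nose).
#' @param side_table optional cleaned side-view table with a `head` part.
#' @param stimulus a [stimulus_geometry()].
#' @param contours optional list of per-frame contour matrices for the tail
#'   channels (see [tail_geometry()]); entries may be `NULL`.
#' @return a [feature_series()].
#' @export
compute_features <- function(table, side_table = NULL, stimulus,
                             contours = NULL) {
  stopifnot(inherits(table, "keypoint_table"),
            inherits(stimulus, "stimulus_geometry"))
  if (!is.finite(table$px_per_cm) || table$px_per_cm <= 0)
    stopf("`px_per_cm` must be set on the keypoint table")
  d <- table$data
  fr <- table$frame_rate
  scl <- table$px_per_cm
  need <- c("nose", "left_operculum", "right_operculum", "centroid", "tail")
  miss <- setdiff(need, table$bodyparts)
  if (length(miss)) stopf("missing body parts: %s", paste(miss, collapse = ", "))
  P <- function(bp) cbind(d[[paste0(bp, "_x")]], d[[paste0(bp, "_y")]])
  nose <- P("nose"); cent <- P("centroid"); tail <- P("tail")
  opl <- P("left_operculum"); opr <- P("right_operculum")
  head_pt <- if ("head" %in% table$bodyparts) P("head") else nose
  n <- nrow(d)

  axis <- nose - cent
  heading <- atan2(axis[, 2], axis[, 1]) * 180 / pi
  orientation <- angle_between(heading, stimulus$normal_deg)
  disp <- rbind(c(0, 0), diff(cent))
  speed <- sqrt(rowSums(disp^2)) * fr / scl
  turning <- c(0, wrap_angle(diff(heading)))

  op_angle <- vertex_angle(nose, opl, opr)
  # per-tip angle off the (backwards) body line at the nose
  back <- cent - nose
  back_pt <- nose + back
  op_left <- vertex_angle(nose, opl, back_pt)
  op_right <- vertex_angle(nose, opr, back_pt)
  axis_n <- axis / pmax(sqrt(rowSums(axis^2)), .Machine$double.eps)
  perp_dist <- function(p) {
    v <- p - cent
    along <- rowSums(v * axis_n)
    sqrt(pmax(rowSums(v^2) - along^2, 0)) / scl
  }
  op_mid <- (perp_dist(opl) + perp_dist(opr)) / 2

  dist_stim <- switch(stimulus$side,
    right = (stimulus$position_px - head_pt[, 1]),
    left = (head_pt[, 1] - stimulus$position_px),
    bottom = (stimulus$position_px - head_pt[, 2]),
    top = (head_pt[, 2] - stimulus$position_px)) / scl

  out <- data.frame(
    orientation = orientation, heading = heading, speed = speed,
    turning_angle = turning,
    head_x = head_pt[, 1] / scl, head_y = head_pt[, 2] / scl,
    centroid_x = cent[, 1] / scl, centroid_y = cent[, 2] / scl,
    tail_x = tail[, 1] / scl, tail_y = tail[, 2] / scl,
    operculum_angle = op_angle,
    operculum_angle_left = op_left, operculum_angle_right = op_right,
    operculum_midline_dist = op_mid,
    distance_to_stimulus = dist_stim)
  units <- c(orientation = "deg", heading = "deg", speed = "cm/s",
             turning_angle = "deg/frame", head_x = "cm", head_y = "cm",
             centroid_x = "cm", centroid_y = "cm", tail_x = "cm",
             tail_y = "cm", operculum_angle = "deg",
             operculum_angle_left = "deg", operculum_angle_right = "deg",
             operculum_midline_dist = "cm", distance_to_stimulus = "cm")

  if (!is.null(contours)) {
    ta <- td <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (is.null(contours[[i]])) next
      g <- tail_geometry(contours[[i]], head_pt[i, ], tail[i, ], px_per_cm = scl)
      ta[i] <- g$tail_angle; td[i] <- g$tail_deviation
    }
    out$tail_angle <- fill_gaps(ta, "tail_angle")
    out$tail_deviation <- fill_gaps(td, "tail_deviation")
    units <- c(units, tail_angle = "deg", tail_deviation = "cm")
  }

  absent <- character(0)
  if (!is.null(side_table)) {
    stopifnot(inherits(side_table, "keypoint_table"))
    if (nrow(side_table$data) != n)
      stopf("side view has %d frames, top view %d", nrow(side_table$data), n)
    sscl <- side_table$px_per_cm
    if (!is.finite(sscl) || sscl <= 0) stopf("side view `px_per_cm` must be set")
    if (!is.finite(stimulus$tank_floor_y))
      stopf("`tank_floor_y` must be set on the stimulus geometry for elevation")
    sh <- if ("head" %in% side_table$bodyparts) "head" else side_table$bodyparts[1]
    hy <- side_table$data[[paste0(sh, "_y")]]
    out$elevation <- (stimulus$tank_floor_y - hy) / sscl
    out$head_z <- out$elevation
    if ("centroid" %in% side_table$bodyparts) {
      out$centroid_z <- (stimulus$tank_floor_y -
                           side_table$data$centroid_y) / sscl
    }
    units <- c(units, elevation = "cm", head_z = "cm",
               if ("centroid" %in% side_table$bodyparts) c(centroid_z = "cm"))
  } else {
    absent <- c("elevation", "head_z", "centroid_z")
  }

  fs <- feature_series(out, frame_rate = fr, units = units)
  attr(fs, "absent_channels") <- absent
  fs
}

#' Median-smooth a feature series
#'
#' Centered sliding median per channel; edges use shrunken windows. The
#' default window of 11 frames spans 0.275 s at 40 fps.
#'
#' @param series a [feature_series()] (or plain numeric vector).
#' @param window_frames odd window width in frames (default 11).
#' @return the smoothed object, with attribute `window_s` giving the window
#'   span in seconds (for a `feature_series`).
#' @export
median_smooth <- function(series, window_frames = 11) {
  if (window_frames %% 2 == 0) stopf("`window_frames` must be odd")
  if (is.numeric(series)) return(running_median(series, window_frames))
  stopifnot(inherits(series, "feature_series"))
  out <- series
  out$data[] <- lapply(series$data, running_median, window_frames)
  attr(out, "window_s") <- window_frames / series$frame_rate
  out
}

# centered running median with shrunken edge windows
running_median <- function(x, w) {
  n <- length(x)
  if (n == 0L || w <= 1L) return(x)
  half <- w %/% 2
  core <- as.numeric(stats::runmed(x, k = min(w, if (n %% 2) n else n - 1),
                                   endrule = "keep"))
  # recompute the edges with shrunken centered windows
  edge <- function(i) stats::median(x[max(1, i - half):min(n, i + half)])
  m <- min(half, n)
  for (i in seq_len(m)) core[i] <- edge(i)
  for (i in seq.int(max(1, n - m + 1), n)) core[i] <- edge(i)
  core
}

#' Write a feature series to CSV
#'
#' Wide CSV (one column per channel, one row per frame) with a JSON sidecar
#' (`<path>.json`) for units and frame rate; or a tidy long CSV
#' (frame, channel, value).
#'
#' @param series a `feature_series`.
#' @param path output CSV path.
#' @param format `"wide"` (default) or `"tidy"`.
#' @export
write_features_csv <- function(series, path, format = c("wide", "tidy")) {
  format <- match.arg(format)
  stopifnot(inherits(series, "feature_series"))
  if (format == "wide") {
    utils::write.csv(series$data, path, row.names = FALSE)
  } else {
    long <- data.frame(
      frame = rep(seq_len(nrow(series$data)), times = ncol(series$data)),
      channel = rep(names(series$data), each = nrow(series$data)),
      value = unlist(series$data, use.names = FALSE))
    utils::write.csv(long, path, row.names = FALSE)
  }
  jsonlite::write_json(list(frame_rate = series$frame_rate,
                            units = as.list(series$units), format = format),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read body-contour polygons from a per-frame CSV
#'
#' Long CSV with columns `frame` (1-based), `x`, `y`; rows of one frame in
#' polygon order. Frames with no rows yield `NULL` entries.
#'
#' @param path CSV path.
#' @param n_frames total frames (default: the maximum frame index).
#' @return list of two-column matrices (or `NULL`), one per frame, usable
#'   as the `contours` argument of [compute_features()].
#' @export
read_contours_csv <- function(path, n_frames = NULL) {
  dat <- utils::read.csv(path)
  if (!all(c("frame", "x", "y") %in% names(dat)))
    stopf("contour CSV needs columns frame, x, y")
  if (is.null(n_frames)) n_frames <- max(dat$frame)
  out <- vector("list", n_frames)
  for (sp in split(dat, dat$frame)) {
    out[[sp$frame[1]]] <- cbind(sp$x, sp$y)
  }
  out
}

#' @rdname read_contours_csv
#' @param contours list of per-frame polygon matrices.
#' @export
write_contours_csv <- function(contours, path) {
  rows <- lapply(seq_along(contours), function(i) {
    if (is.null(contours[[i]])) return(NULL)
    data.frame(frame = i, x = contours[[i]][, 1], y = contours[[i]][, 2])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature series written by [write_features_csv()]
#' @param path CSV path (sidecar `<path>.json` must exist for metadata;
#'   otherwise `frame_rate` is required).
#' @param frame_rate fallback frame rate when no sidecar is present.
#' @return a `feature_series`.
#' @export
read_features_csv <- function(path, frame_rate = NULL) {
  meta <- NULL
  if (file.exists(paste0(path, ".json")))
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fr <- if (!is.null(meta$frame_rate)) meta$frame_rate else frame_rate
  if (is.null(fr)) stopf("no sidecar found; supply `frame_rate`")
  dat <- utils::read.csv(path)
  if (!is.null(meta$format) && meta$format == "tidy") {
    wide <- split(dat$value, dat$channel)
    dat <- as.data.frame(wide[unique(dat$channel)])
  }
  units <- if (!is.null(meta$units)) unlist(meta$units) else NULL
  feature_series(dat, frame_rate = fr, units = units)
}
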