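# Keypoint tables: the wide pose-tracker dialect (three columns per body
# part: x, y, likelihood) plus acquisition metadata. This is the raw input
# of the kinematics stage; cleaning replaces low-confidence and jumpy
# samples by linear interpolation.

#' Construct a keypoint table
#'
#' @param data data.frame with, per body part `bp`, numeric columns
#'   `bp_x`, `bp_y`, `bp_likelihood`; one row per frame.
#' @param frame_rate acquisition rate in frames/s.
#' @param view camera view, `"top"` or `"side"`.
#' @param px_per_cm spatial scale (pixels per centimeter).
#' @return an object of class `keypoint_table`.
#' @export
keypoint_table <- function(data, frame_rate = 40, view = c("top", "side"),
                           px_per_cm = NA_real_) {
  view <- match.arg(view)
  assert_scalar_num(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  if (!is.data.frame(data) || nrow(data) == 0L)
    stopf("`data` must be a non-empty data.frame")
  nms <- names(data)
  bps <- unique(sub("_(x|y|likelihood)$", "", nms[grepl("_(x|y|likelihood)$", nms)]))
  if (length(bps) == 0L) stopf("no `<bodypart>_x/_y/_likelihood` columns found")
  for (bp in bps) {
    need <- paste0(bp, c("_x", "_y", "_likelihood"))
    if (!all(need %in% nms)) stopf("body part '%s' is missing x/y/likelihood columns", bp)
    lik <- data[[paste0(bp, "_likelihood")]]
    if (any(lik < 0 | lik > 1, na.rm = TRUE))
      stopf("likelihood for '%s' outside [0,1]", bp)
  }
  structure(list(data = data, bodyparts = bps, frame_rate = frame_rate,
                 view = view, px_per_cm = px_per_cm),
            class = "keypoint_table")
}

#' @export
print.keypoint_table <- function(x, ...) {
  cat(sprintf("<keypoint_table> %d frames, %d body parts (%s view, %g fps)\n",
              nrow(x$data), length(x$bodyparts), x$view, x$frame_rate))
  cat(" body parts:", paste(x$bodyparts, collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a keypoint table
#' @param x a `keypoint_table`.
#' @export
n_frames <- function(x) nrow(x$data)

#' Clean a keypoint table
#'
#' Drops samples whose tracking confidence falls below `conf_thresh` or that
#' jump more than `jump_thresh` pixels from the previous *retained* sample,
#' then fills the holes by linear interpolation between the nearest valid
#' neighbours (leading/trailing holes take the nearest valid value). The
#' jump rule is evaluated against the last retained sample, not the raw
#' previous frame, so one outlier cannot mask subsequent good points.
#'
#' @param table a [keypoint_table()].
#' @param conf_thresh confidence threshold; samples with confidence strictly
#'   below it are dropped (default 0.8).
#' @param jump_thresh jump threshold in pixels; displacements strictly larger
#'   than it are dropped (default 15).
#' @return a cleaned `keypoint_table` (likelihood of interpolated samples is
#'   kept as recorded; an attribute `n_dropped` counts replaced samples).
#' @export
clean_keypoints <- function(table, conf_thresh = 0.8, jump_thresh = 15) {
  stopifnot(inherits(table, "keypoint_table"))
  assert_scalar_num(conf_thresh, "conf_thresh", lower = 0, upper = 1)
  assert_scalar_num(jump_thresh, "jump_thresh", lower = 0)
  d <- table$data
  n <- nrow(d)
  dropped <- 0L
  for (bp in table$bodyparts) {
    cx <- paste0(bp, "_x"); cy <- paste0(bp, "_y")
    cl <- paste0(bp, "_likelihood")
    x <- d[[cx]]; y <- d[[cy]]
    keep <- is.finite(x) & is.finite(y) & !is.na(d[[cl]]) & d[[cl]] >= conf_thresh
    # jump rule against previous retained sample
    last <- NA_integer_
    for (i in seq_len(n)) {
      if (!keep[i]) next
      if (!is.na(last)) {
        disp <- sqrt((x[i] - x[last])^2 + (y[i] - y[last])^2)
        if (disp > jump_thresh) {
          keep[i] <- FALSE
          next
        }
      }
      last <- i
    }
    if (!any(keep)) stopf("keypoint '%s' has no valid samples after cleaning", bp)
    dropped <- dropped + sum(!keep)
    x[!keep] <- NA_real_; y[!keep] <- NA_real_
    d[[cx]] <- fill_gaps(x, paste0(bp, "_x"))
    d[[cy]] <- fill_gaps(y, paste0(bp, "_y"))
  }
  out <- table
  out$data <- d
  attr(out, "n_dropped") <- dropped
  out
}

#' Write a keypoint table as CSV (wide pose-tracker dialect)
#'
#' One row per frame; columns `bodypart_x`, `bodypart_y`,
#' `bodypart_likelihood`. A JSON sidecar (`<path>.json`) records frame rate,
#' view and scale.
#'
#' @param table a `keypoint_table`.
#' @param path output CSV path.
#' @export
write_keypoints_csv <- function(table, path) {
  stopifnot(inherits(table, "keypoint_table"))
  utils::write.csv(table$data, path, row.names = FALSE)
  sidecar <- list(frame_rate = table$frame_rate, view = table$view,
                  px_per_cm = table$px_per_cm)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a keypoint table from CSV
#'
#' Accepts the plain wide dialect written by [write_keypoints_csv()] and the
#' multi-row-header dialect of common pose trackers (scorer / bodyparts /
#' coords header rows), which is flattened to `bodypart_coord` columns.
#'
#' @param path CSV path.
#' @param frame_rate,view,px_per_cm metadata; read from the JSON sidecar when
#'   present, otherwise these arguments are used.
#' @return a `keypoint_table`.
#' @export
read_keypoints_csv <- function(path, frame_rate = 40, view = "top",
                               px_per_cm = NA_real_) {
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$frame_rate)) frame_rate <- meta$frame_rate
    if (!is.null(meta$view)) view <- meta$view
    if (!is.null(meta$px_per_cm) && length(meta$px_per_cm)) px_per_cm <- meta$px_per_cm
  }
  head4 <- utils::read.csv(path, header = FALSE, nrows = 4,
                           colClasses = "character")
  lead <- tolower(head4[[1]])
  multi <- any(lead %in% c("scorer", "bodyparts", "coords"))
  if (multi) {
    # rows: scorer, bodyparts, coords, then data; first column is frame index
    bp_row <- which(tolower(head4[[1]]) == "bodyparts")
    coord_row <- which(tolower(head4[[1]]) == "coords")
    raw <- utils::read.csv(path, header = FALSE, skip = max(coord_row))
    bps <- as.character(unlist(head4[bp_row, -1]))
    coords <- as.character(unlist(head4[coord_row, -1]))
    dat <- raw[, -1, drop = FALSE]
    names(dat) <- paste0(bps, "_", coords)
    dat[] <- lapply(dat, as.numeric)
  } else {
    dat <- utils::read.csv(path)
  }
  keypoint_table(dat, frame_rate = frame_rate, view = view, px_per_cm = px_per_cm)
}
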