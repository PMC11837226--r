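# Ethograms: per-frame flaring labels (none / partial / full). Partial
# flaring = opercula off the body but not fully extended; full flaring =
# opercula at their maximum angle. "Flaring" in the binary sense combines
# partial and full.

FLARE_LEVELS <- c("none", "partial", "full")

#' Construct an ethogram
#'
#' @param labels character/factor/integer vector of per-frame labels. Integers
#'   are taken as 0 = none, 1 = partial, 2 = full.
#' @param frame_rate frames/s.
#' @param provenance `"manual"` or `"predicted"`.
#' @return object of class `ethogram`: a factor with levels
#'   `none`, `partial`, `full` and attributes `frame_rate`, `provenance`.
#' @export
ethogram <- function(labels, frame_rate = 40,
                     provenance = c("manual", "predicted")) {
  provenance <- match.arg(provenance)
  assert_scalar_num(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  if (is.numeric(labels)) labels <- FLARE_LEVELS[labels + 1L]
  f <- factor(as.character(labels), levels = FLARE_LEVELS)
  if (anyNA(f)) stopf("labels must be in {%s}", paste(FLARE_LEVELS, collapse = ", "))
  structure(f, frame_rate = frame_rate, provenance = provenance,
            class = c("ethogram", "factor"))
}

#' @export
print.ethogram <- function(x, ...) {
  tab <- table(unclass(x))
  cat(sprintf("<ethogram> %d frames @ %g fps (%s)\n", length(x),
              attr(x, "frame_rate"), attr(x, "provenance")))
  cat(sprintf(" none %d | partial %d | full %d | flaring %.1f%%\n",
              tab[1], tab[2], tab[3], 100 * mean(binary_flaring(x))))
  invisible(x)
}

#' Binary flaring indicator from an ethogram
#'
#' Partial and full flaring both count as flaring.
#'
#' @param x an `ethogram` (or a factor/character vector of labels).
#' @return integer vector of 0/1.
#' @export
binary_flaring <- function(x) as.integer(as.character(x) != "none")

#' Classify flaring from operculum angle by fixed thresholds
#'
#' Simple rule-based ethogram: the angle at the nose subtended by the two
#' operculum tips is compared against two thresholds. Used for round-trip
#' checks against the synthetic renderer and as a baseline classifier.
#'
#' @param features a [feature_series()] with an `operculum_angle` channel,
#'   or a numeric vector of angles (deg).
#' @param partial_deg threshold for partial flaring (default 32).
#' @param full_deg threshold for full flaring (default 60).
#' @return an `ethogram` with provenance `"predicted"`.
#' @export
classify_flare_by_threshold <- function(features, partial_deg = 32,
                                        full_deg = 60) {
  if (inherits(features, "feature_series")) {
    ang <- features$data$operculum_angle
    fr <- features$frame_rate
  } else {
    ang <- features
    fr <- 40
  }
  if (is.null(ang)) stopf("no `operculum_angle` channel")
  lab <- ifelse(ang >= full_deg, 2L, ifelse(ang >= partial_deg, 1L, 0L))
  ethogram(lab, frame_rate = fr, provenance = "predicted")
}

#' Convert an ethogram to a behavioral event log
#'
#' @param x an `ethogram`.
#' @return data.frame with columns `time_s`, `behavior` (`partial`/`full`),
#'   `status` (`START`/`STOP`). STOP times are exclusive (first frame after
#'   the run, in seconds).
#' @export
ethogram_to_events <- function(x) {
  stopifnot(inherits(x, "ethogram"))
  fr <- attr(x, "frame_rate")
  r <- rle(as.character(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "none"
  data.frame(
    time_s = c(rbind((starts[keep] - 1) / fr, ends[keep] / fr)),
    behavior = rep(r$values[keep], each = 2L),
    status = rep(c("START", "STOP"), sum(keep)),
    stringsAsFactors = FALSE)
}

#' Build an ethogram from a behavioral event log
#'
#' @param events data.frame with columns `time_s`, `behavior` in
#'   `{partial, full}` (or `{none, partial, full}` state rows with no
#'   `status` column), `status` in `{START, STOP}`.
#' @param n_frames total number of frames in the record.
#' @param frame_rate frames/s.
#' @param provenance label provenance.
#' @return an `ethogram`.
#' @export
events_to_ethogram <- function(events, n_frames, frame_rate = 40,
                               provenance = "manual") {
  lab <- rep(0L, n_frames)
  if (nrow(events)) {
    if (is.null(events$status)) stopf("event log needs a `status` column")
    for (beh in c("partial", "full")) {
      ev <- events[events$behavior == beh, , drop = FALSE]
      ev <- ev[order(ev$time_s), , drop = FALSE]
      st <- ev$time_s[ev$status == "START"]
      en <- ev$time_s[ev$status == "STOP"]
      if (length(st) != length(en)) stopf("unbalanced START/STOP for '%s'", beh)
      code <- if (beh == "full") 2L else 1L
      for (k in seq_along(st)) {
        i0 <- floor(st[k] * frame_rate) + 1L
        i1 <- ceiling(en[k] * frame_rate)
        if (i1 >= i0) lab[max(1L, i0):min(n_frames, i1)] <- code
      }
    }
  }
  ethogram(lab, frame_rate = frame_rate, provenance = provenance)
}

#' Write / read ethograms and event logs
#'
#' `write_ethogram_csv` writes a per-frame CSV (`frame`, `label`);
#' `write_events_csv` writes the event-log dialect (`time_s`, `behavior`,
#' `status`).
#'
#' @param x an `ethogram`.
#' @param path CSV path.
#' @export
write_ethogram_csv <- function(x, path) {
  stopifnot(inherits(x, "ethogram"))
  utils::write.csv(data.frame(frame = seq_along(x), label = as.character(x)),
                   path, row.names = FALSE)
  jsonlite::write_json(list(frame_rate = attr(x, "frame_rate"),
                            provenance = attr(x, "provenance")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ethogram_csv
#' @export
write_events_csv <- function(x, path) {
  utils::write.csv(ethogram_to_events(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ethogram_csv
#' @param frame_rate fallback frame rate when no sidecar exists.
#' @export
read_ethogram_csv <- function(path, frame_rate = 40) {
  prov <- "manual"
  if (file.exists(paste0(path, ".json"))) {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    if (!is.null(meta$frame_rate)) frame_rate <- meta$frame_rate
    if (!is.null(meta$provenance)) prov <- meta$provenance
  }
  dat <- utils::read.csv(path)
  ethogram(dat$label, frame_rate = frame_rate, provenance = prov)
}
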