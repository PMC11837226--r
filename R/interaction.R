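# Interaction dynamics: point-biserial correlations of flaring against
# opponent/stimulus features (with a shuffle control), bout-triggered
# peri-event time histograms, and the persistence (engagement-decay) curve.

#' Frames where either opponent is flaring
#'
#' Correlations between flaring and opponent features are computed only on
#' frames where at least one of the two is flaring; long mutually idle
#' stretches would otherwise inflate the correlations of low-flaring dyads.
#'
#' @param flare_a,flare_b binary (0/1) series of equal length.
#' @return logical frame mask.
#' @export
coflaring_filter <- function(flare_a, flare_b) {
  if (length(flare_a) != length(flare_b)) stopf("series lengths differ")
  flare_a == 1L | flare_b == 1L
}

#' Point-biserial correlation between flaring and a feature
#'
#' Pearson correlation with the binary flare indicator coded 0/1, evaluated
#' on the masked frames. A fish that never flares (no 1s in the masked
#' series) is assigned r = 0 by convention; a zero-variance feature makes r
#' undefined and returns `NA` with attribute `reason`.
#'
#' @param flare binary series of the focal fish.
#' @param feature numeric feature series of the opponent or stimulus.
#' @param mask logical frame mask (default: all frames).
#' @return the correlation, with attribute `zero_assigned` when the
#'   never-flares rule fired.
#' @export
flare_feature_correlation <- function(flare, feature,
                                      mask = rep(TRUE, length(flare))) {
  if (length(flare) != length(feature)) stopf("series lengths differ")
  f <- as.numeric(flare[mask])
  x <- as.numeric(feature[mask])
  if (length(f) == 0L || sum(f) == 0) {
    return(structure(0, zero_assigned = TRUE))
  }
  if (stats::var(f) == 0) return(structure(0, zero_assigned = TRUE))
  if (stats::var(x) == 0)
    return(structure(NA_real_, reason = "zero-variance feature"))
  structure(stats::cor(f, x), zero_assigned = FALSE)
}

#' Shuffle control for a flare-feature correlation
#'
#' Recomputes the correlation after randomly permuting the masked feature
#' values. A full random shuffle (not a circular shift) is appropriate
#' because the correlation does not depend on temporal structure.
#'
#' @inheritParams flare_feature_correlation
#' @param seed RNG seed.
#' @return the shuffled correlation (attributes as in
#'   [flare_feature_correlation()]).
#' @export
shuffle_control <- function(flare, feature, mask = rep(TRUE, length(flare)),
                            seed = 1) {
  set.seed(seed)
  x <- feature
  idx <- which(mask)
  x[idx] <- x[idx][sample.int(length(idx))]
  flare_feature_correlation(flare, x, mask)
}

#' Cohort correlation report with shuffle controls
#'
#' For each fish, computes the observed and shuffled correlation of its
#' flaring with each named opponent/stimulus feature on the co-flaring
#' mask, then compares observed vs shuffled across the cohort with a
#' two-sided paired t-test per feature.
#'
#' @param fish list, one element per fish: `list(flare = <0/1>,
#'   opponent_flare = <0/1>, features = <named list/data.frame of series>)`.
#' @param seed master seed (per-fish shuffle seeds are derived from it).
#' @return list with `per_fish` (data.frame: fish, feature, r_observed,
#'   r_shuffled, zero_assigned) and `tests` (data.frame: feature, mean_obs,
#'   mean_shuf, t, df, p).
#' @export
correlation_report <- function(fish, seed = 1) {
  per <- list()
  for (i in seq_along(fish)) {
    fi <- fish[[i]]
    mask <- coflaring_filter(fi$flare, fi$opponent_flare)
    for (nm in names(fi$features)) {
      r_obs <- flare_feature_correlation(fi$flare, fi$features[[nm]], mask)
      r_shf <- shuffle_control(fi$flare, fi$features[[nm]], mask,
                               seed = derive_seed(seed, i * 1000 + match(nm, names(fi$features))))
      per[[length(per) + 1L]] <- data.frame(
        fish = i, feature = nm,
        r_observed = as.numeric(r_obs), r_shuffled = as.numeric(r_shf),
        zero_assigned = isTRUE(attr(r_obs, "zero_assigned")))
    }
  }
  per <- do.call(rbind, per)
  tests <- do.call(rbind, lapply(split(per, per$feature), function(d) {
    ok <- is.finite(d$r_observed) & is.finite(d$r_shuffled)
    if (sum(ok) < 2)
      return(data.frame(feature = d$feature[1], mean_obs = NA, mean_shuf = NA,
                        t = NA, df = NA, p = NA))
    tt <- stats::t.test(d$r_observed[ok], d$r_shuffled[ok], paired = TRUE)
    data.frame(feature = d$feature[1], mean_obs = mean(d$r_observed[ok]),
               mean_shuf = mean(d$r_shuffled[ok]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }))
  rownames(tests) <- NULL
  list(per_fish = per, tests = tests)
}

#' Select isolated flare bout onsets and offsets
#'
#' A qualifying onset has no flaring in the preceding `isolation_s` seconds
#' and uninterrupted flaring for the following `isolation_s` seconds; a
#' qualifying offset is the mirror image. Events closer than `isolation_s`
#' to either record boundary never qualify (their window is incomplete).
#'
#' @param flare binary (0/1) flare series.
#' @param frame_rate frames/s.
#' @param isolation_s isolation window in seconds (default 3).
#' @return data.frame of bout events: `kind` (`onset`/`offset`), `frame`
#'   (first flaring frame for onsets; first non-flaring frame after the
#'   bout for offsets), `qualifies`.
#' @export
select_bouts <- function(flare, frame_rate = 40, isolation_s = 3) {
  flare <- as.integer(flare)
  n <- length(flare)
  w <- round(isolation_s * frame_rate)
  d <- diff(c(0L, flare, 0L))
  onsets <- which(d == 1L)          # first frame of each bout
  offsets <- which(d == -1L)        # first frame after each bout
  ev <- rbind(
    if (length(onsets)) data.frame(kind = "onset", frame = onsets),
    if (length(offsets)) data.frame(kind = "offset", frame = offsets))
  if (is.null(ev)) return(data.frame(kind = character(), frame = integer(),
                                     qualifies = logical()))
  ev <- ev[order(ev$frame, ev$kind == "offset"), , drop = FALSE]
  qual <- logical(nrow(ev))
  for (k in seq_len(nrow(ev))) {
    fr0 <- ev$frame[k]
    before <- (fr0 - w):(fr0 - 1L)
    after <- fr0:(fr0 + w - 1L)
    if (before[1] < 1L || after[w] > n) { qual[k] <- FALSE; next }
    if (ev$kind[k] == "onset") {
      qual[k] <- all(flare[before] == 0L) && all(flare[after] == 1L)
    } else {
      qual[k] <- all(flare[before] == 1L) && all(flare[after] == 0L)
    }
  }
  ev$qualifies <- qual
  rownames(ev) <- NULL
  ev
}

#' Peri-event time histogram of a feature around bout events
#'
#' Extracts `±window_s` windows of `feature` centered on each qualifying
#' event and averages them; the event frame sits at window position
#' `window_s * frame_rate + 1`.
#'
#' @param events data.frame from [select_bouts()] (only rows with
#'   `qualifies == TRUE` are used), or an integer vector of event frames.
#' @param feature numeric per-frame series.
#' @param frame_rate frames/s.
#' @param window_s half-window in seconds (default 3).
#' @param normalize normalize each window with [normalize_elevation()]
#'   before averaging (used for elevation).
#' @return a `peth` object: `traces` (events x window matrix), `mean`,
#'   `sem`, `time_s`, `n_events`; or an empty-result sentinel
#'   (`n_events = 0`) when no event qualifies.
#' @export
peth <- function(events, feature, frame_rate = 40, window_s = 3,
                 normalize = FALSE) {
  w <- round(window_s * frame_rate)
  if (is.data.frame(events)) {
    frames <- events$frame[events$qualifies]
  } else {
    frames <- as.integer(events)
  }
  n <- length(feature)
  frames <- frames[frames - w >= 1L & frames + w <= n]
  if (length(frames) == 0L) {
    return(structure(list(traces = NULL, mean = NULL, sem = NULL,
                          time_s = seq(-w, w) / frame_rate, n_events = 0L),
                     class = "peth"))
  }
  traces <- t(vapply(frames, function(f0) {
    win <- feature[(f0 - w):(f0 + w)]
    if (normalize) win <- normalize_elevation(win)
    as.numeric(win)
  }, numeric(2L * w + 1L)))
  m <- colMeans(traces)
  sem <- if (nrow(traces) > 1)
    apply(traces, 2, stats::sd) / sqrt(nrow(traces)) else rep(0, ncol(traces))
  structure(list(traces = traces, mean = m, sem = sem,
                 time_s = seq(-w, w) / frame_rate,
                 n_events = length(frames)),
            class = "peth")
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf("<peth> %d events, window %.2f..%.2f s\n", x$n_events,
              min(x$time_s), max(x$time_s)))
  invisible(x)
}

#' Min-max normalize an elevation window
#'
#' `(x - min) / (max - min)` per window, so every window spans \[0, 1\]
#' regardless of its absolute elevation. A constant window maps to all
#' zeros with attribute `degenerate = TRUE`.
#'
#' @param window numeric vector.
#' @return normalized vector.
#' @export
normalize_elevation <- function(window) {
  rng <- range(window)
  if (diff(rng) == 0)
    return(structure(rep(0, length(window)), degenerate = TRUE))
  structure((window - rng[1]) / diff(rng), degenerate = FALSE)
}

#' Persistence (engagement decay) of flaring across an exposure
#'
#' The binary flare series is smoothed with a centered rolling mean
#' (`smooth_s` wide, at frame resolution by default), binned into `bin_s`
#' bins (per-bin proportion of time flaring), averaged across fish when
#' several series are given, and fitted with a bounded-least-squares
#' exponential `y(t) = A exp(-t / tau) + c` (A >= 0, tau > 0, c >= 0,
#' multi-start in tau, deterministic given the data). The crossing time at
#' fraction f solves `y(t*) = f * (A + c)`, the fitted curve's maximum
#' height being its value at exposure start.
#'
#' @param flare binary series, or a list of binary series (one per fish).
#' @param frame_rate frames/s.
#' @param bin_s bin width in seconds (default 8).
#' @param fractions fractions of the fitted maximum at which crossing times
#'   are reported (default 3/4 and 1/2).
#' @param smooth_s rolling-mean width in seconds (default 0.357).
#' @param smooth_on `"frames"` (default): the rolling mean is applied to
#'   the frame-level series before binning; `"bins"`: applied to the bin
#'   series (the window then spans at least one bin).
#' @return a `persistence_curve`: `time_s` (bin centers), `proportion`
#'   (per-bin flare proportion, cohort mean), `fit` (A, tau, c, converged,
#'   sse), `crossings` (named vector of times, NA when the curve never
#'   crosses).
#' @export
persistence <- function(flare, frame_rate = 40, bin_s = 8,
                        fractions = c(0.75, 0.5), smooth_s = 0.357,
                        smooth_on = c("frames", "bins")) {
  smooth_on <- match.arg(smooth_on)
  series <- if (is.list(flare)) flare else list(flare)
  nb <- min(vapply(series, length, 1L)) %/% round(bin_s * frame_rate)
  if (nb < 2) stopf("record must span at least 2 bins")
  bpf <- round(bin_s * frame_rate)
  wf <- max(1L, round(smooth_s * frame_rate))
  binned <- vapply(series, function(x) {
    x <- as.numeric(x)
    if (smooth_on == "frames") x <- rolling_mean(x, wf)
    colMeans(matrix(x[seq_len(nb * bpf)], nrow = bpf))
  }, numeric(nb))
  prop <- rowMeans(as.matrix(binned))
  if (smooth_on == "bins") prop <- rolling_mean(prop, max(1L, round(smooth_s / bin_s)))
  tt <- (seq_len(nb) - 0.5) * bin_s
  fit <- fit_exponential_decay(tt, prop)
  crossings <- stats::setNames(rep(NA_real_, length(fractions)),
                               paste0("f", fractions))
  if (fit$converged && fit$A > 0) {
    ymax <- fit$A + fit$c
    for (k in seq_along(fractions)) {
      target <- fractions[k] * ymax
      if (target > fit$c)
        crossings[k] <- fit$tau * log(fit$A / (target - fit$c))
    }
  }
  structure(list(time_s = tt, proportion = prop, fit = fit,
                 crossings = crossings, bin_s = bin_s,
                 n_fish = length(series)),
            class = "persistence_curve")
}

#' @export
print.persistence_curve <- function(x, ...) {
  cat(sprintf("<persistence_curve> %d bins of %g s (%d fish)\n",
              length(x$time_s), x$bin_s, x$n_fish))
  if (x$fit$converged)
    cat(sprintf(" fit: y = %.3f exp(-t/%.1f s) + %.3f; crossings: %s\n",
                x$fit$A, x$fit$tau, x$fit$c,
                paste(sprintf("%s=%.1fs", names(x$crossings), x$crossings),
                      collapse = ", ")))
  else cat(" fit did not converge\n")
  invisible(x)
}

# Bounded least squares for y = A exp(-t/tau) + c with multi-start in tau.
fit_exponential_decay <- function(t, y, tau_starts = c(10, 60, 300)) {
  obj <- function(p) {
    sum((y - (p[1] * exp(-t / p[2]) + p[3]))^2)
  }
  best <- NULL
  y0 <- max(y[1], 1e-6)
  for (tau0 in tau_starts) {
    p0 <- c(A = max(y0 - min(y), 1e-6), tau = tau0, c = max(min(y), 0))
    res <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B",
                   lower = c(0, 1e-6, 0),
                   upper = c(1.5, Inf, 1),
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    return(list(A = NA_real_, tau = NA_real_, c = NA_real_,
                converged = FALSE, sse = NA_real_))
  list(A = unname(best$par[1]), tau = unname(best$par[2]),
       c = unname(best$par[3]), converged = best$convergence == 0,
       sse = best$value)
}
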