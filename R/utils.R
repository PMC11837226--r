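#' @keywords internal
"_PACKAGE"

# Internal validation / RNG helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower) stopf("`%s` must be > %g", name, lower)
  if (!strict_lower && x < lower) stopf("`%s` must be >= %g", name, lower)
  if (strict_upper && x >= upper) stopf("`%s` must be < %g", name, upper)
  if (!strict_upper && x > upper) stopf("`%s` must be <= %g", name, upper)
  invisible(x)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic stages take a single master seed; per-fish / per-stage
#' streams are derived with a splitmix-style integer hash so that runs are
#' reproducible and sub-streams are decorrelated. The result is always a
#' non-negative integer below 2^31.
#'
#' @param seed master seed (single integer).
#' @param index stream index (single non-negative integer).
#' @return a single integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, index) {
  assert_scalar_num(seed, "seed")
  assert_scalar_num(index, "index", lower = 0)
  # 64-bit-free splitmix variant in double precision: repeated multiply-mod
  # against two coprime moduli below 2^31.
  m <- 2147483647 # 2^31 - 1
  x <- (abs(seed) %% m)
  x <- (x * 48271 + index * 16807 + 12345) %% m
  x <- (x * 69621 + 7919) %% m
  as.integer(x)
}

# Wrap angle difference into (-180, 180].
wrap_angle <- function(d) {
  d <- (d + 180) %% 360 - 180
  d[d == -180] <- 180
  d
}

# Unsigned angle in [0, 180] between two angles given in degrees.
angle_between <- function(a, b) abs(wrap_angle(a - b))

# Angle (deg) at vertex `v` subtended by points p and q (all 2-column mats).
vertex_angle <- function(v, p, q) {
  u1 <- p - v
  u2 <- q - v
  n1 <- sqrt(rowSums(u1^2))
  n2 <- sqrt(rowSums(u2^2))
  cosang <- rowSums(u1 * u2) / pmax(n1 * n2, .Machine$double.eps)
  cosang <- pmin(pmax(cosang, -1), 1)
  acos(cosang) * 180 / pi
}

# Centered rolling mean with shrunken edge windows (width in samples).
rolling_mean <- function(x, width) {
  if (width <= 1L) return(x)
  n <- length(x)
  half <- width %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Linear interpolation over NA runs; leading/trailing NAs take the nearest
# valid value. Errors if no valid samples at all.
fill_gaps <- function(x, what = "series") {
  ok <- is.finite(x)
  if (!any(ok)) stopf("%s has no valid samples", what)
  if (all(ok)) return(x)
  idx <- which(ok)
  stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
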