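# Synthetic behavioral data with the statistical structure the analyses
# assume: two coupled semi-Markov agents that take turns flaring, an
# animation-response generator whose flaring is phase-locked to a repeating
# stimulus loop with tunable strength, and a geometric renderer from ground
# truth states to pose keypoints. Everything is seed-deterministic.

#' Configuration for a simulated dyadic encounter
#'
#' Two agents alternate opercular flaring (turn taking) while cycling
#' through four orientation states (facing, turning, lateral, turning-away)
#' as a semi-Markov chain with exponential dwell times. Flare initiation is
#' a per-frame hazard that is suppressed by a factor `(1 - coupling)` while
#' the opponent flares and transiently boosted after the opponent's flare
#' offsets, and that decays as `exp(-t / engagement_tau)` across the
#' exposure.
#'
#' @param frame_rate frames/s (default 40).
#' @param duration_s exposure duration in seconds (default 600, a 10-min
#'   test period).
#' @param dwell_means named numeric, mean dwell time (s) of the four
#'   orientation states.
#' @param turn_taking_coupling coupling in \[0, 1\]: 0 = independent agents,
#'   1 = near-deterministic alternation of flaring.
#' @param engagement_tau time constant (s) of the exponential decay of the
#'   flare-initiation hazard; `Inf` = stationary.
#' @param elevation_gain cm of extra elevation while flaring (elevation and
#'   flaring are positively coupled, as in real displays).
#' @param orientation_coupling in \[0, 1\]: how strongly a flaring agent is
#'   drawn toward (and held at) the facing orientation. 0 decouples
#'   orientation from flaring, preserving the configured dwell
#'   distributions exactly.
#' @param flare_bout_s mean flare bout duration, s (default 1.1).
#' @param flare_gap_s mean inter-flare interval at full engagement for an
#'   unperturbed agent, s (default 4; together with `flare_bout_s` this
#'   gives ~22% time flaring, typical of real encounters).
#' @param seed integer RNG seed.
#' @return a `dyad_sim_config` list.
#' @export
dyad_sim_config <- function(frame_rate = 40, duration_s = 600,
                            dwell_means = c(facing = 2, turning = 0.5,
                                            lateral = 1.5, turning_away = 0.5),
                            turn_taking_coupling = 0.9,
                            engagement_tau = Inf, elevation_gain = 3,
                            orientation_coupling = 0.7,
                            flare_bout_s = 1.1, flare_gap_s = 4, seed = 1) {
  assert_scalar_num(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  assert_scalar_num(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  if (length(dwell_means) != 4L || any(!is.finite(dwell_means)) ||
      any(dwell_means <= 0))
    stopf("`dwell_means` must be 4 positive values")
  names(dwell_means) <- c("facing", "turning", "lateral", "turning_away")
  assert_scalar_num(turn_taking_coupling, "turn_taking_coupling", 0, 1)
  if (!(is.numeric(engagement_tau) && length(engagement_tau) == 1L &&
        engagement_tau > 0))
    stopf("`engagement_tau` must be a positive number (Inf allowed)")
  assert_scalar_num(orientation_coupling, "orientation_coupling", 0, 1)
  assert_scalar_num(flare_bout_s, "flare_bout_s", lower = 0, strict_lower = TRUE)
  assert_scalar_num(flare_gap_s, "flare_gap_s", lower = 0, strict_lower = TRUE)
  structure(list(frame_rate = frame_rate, duration_s = duration_s,
                 n_orientation_states = 4L, dwell_means = dwell_means,
                 turn_taking_coupling = turn_taking_coupling,
                 engagement_tau = engagement_tau,
                 elevation_gain = elevation_gain,
                 orientation_coupling = orientation_coupling,
                 flare_bout_s = flare_bout_s, flare_gap_s = flare_gap_s,
                 seed = as.integer(seed)),
            class = "dyad_sim_config")
}

#' Configuration for a simulated animation-response trial
#'
#' A single fish watches an animation of `loop_length_s` seconds repeated
#' `n_loops` times. Per-frame flaring is Bernoulli with probability
#' `(1 - lock_strength) * base_flare_rate + lock_strength * template(t)`,
#' where the template is 1 during a fixed contiguous window covering 30% of
#' the loop (the epoch where the animated fish is lateral) and 0 elsewhere.
#' `lock_strength = 0` gives homogeneous random flaring; `lock_strength = 1`
#' gives a deterministic, perfectly phase-locked response.
#'
#' @param loop_length_s animation loop length, s (default 37).
#' @param n_loops number of complete loops (default 16; a 10-min exposure
#'   shows 16.2 loops, of which 16 are complete).
#' @param lock_strength phase-locking strength in \[0, 1\].
#' @param base_flare_rate per-frame flare probability in (0, 1).
#' @param frame_rate frames/s.
#' @param seed integer RNG seed.
#' @return an `animation_sim_config` list.
#' @export
animation_sim_config <- function(loop_length_s = 37, n_loops = 16,
                                 lock_strength = 0.5, base_flare_rate = 0.2,
                                 frame_rate = 40, seed = 1) {
  assert_scalar_num(loop_length_s, "loop_length_s", lower = 0, strict_lower = TRUE)
  assert_scalar_num(n_loops, "n_loops", lower = 2)
  assert_scalar_num(lock_strength, "lock_strength", 0, 1)
  assert_scalar_num(base_flare_rate, "base_flare_rate", 0, 1,
                    strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_num(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  structure(list(loop_length_s = loop_length_s, n_loops = as.integer(n_loops),
                 lock_strength = lock_strength,
                 base_flare_rate = base_flare_rate, frame_rate = frame_rate,
                 seed = as.integer(seed)),
            class = "animation_sim_config")
}

# per-frame flare-class series for one bout structure: when a bout starts,
# it is "full" with probability p_full, else "partial", constant within
# the bout.
assign_flare_classes <- function(flare, p_full = 0.6) {
  cls <- integer(length(flare))
  r <- rle(flare)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values == 1L)) {
    cls[starts[k]:ends[k]] <- if (stats::runif(1) < p_full) 2L else 1L
  }
  cls
}

# continuous-time semi-Markov orientation path for one agent.
# States 0..3 on the facing(0) - turning(1) - lateral(2) - turning_away(3)
# path graph; dwells exponential with the configured means; while the agent
# flares, the next state is facing with probability `ocpl` and facing
# dwells are stretched by 1/(1 - ocpl).
simulate_orientation <- function(cfg, flare) {
  fr <- cfg$frame_rate
  n <- length(flare)
  mu <- unname(cfg$dwell_means)
  ocpl <- cfg$orientation_coupling
  # embedded jump matrix of the path graph
  J <- rbind(c(0, 1, 0, 0), c(.5, 0, .5, 0), c(0, .5, 0, .5), c(0, 0, 1, 0))
  state <- integer(n)
  dwell_state <- integer(0)
  dwell_s <- numeric(0)
  t <- 0
  s <- 0L # enter facing the stimulus
  while (t < cfg$duration_s) {
    fl_now <- flare[min(n, floor(t * fr) + 1L)] == 1L
    m <- mu[s + 1L]
    if (s == 0L && fl_now && ocpl > 0 && ocpl < 1) m <- m / (1 - ocpl)
    d <- stats::rexp(1, rate = 1 / m)
    i0 <- floor(t * fr) + 1L
    i1 <- min(n, ceiling((t + d) * fr))
    if (i1 >= i0 && i0 <= n) state[i0:i1] <- s
    dwell_state <- c(dwell_state, s)
    dwell_s <- c(dwell_s, d)
    t <- t + d
    fl_now <- flare[min(n, floor(t * fr) + 1L)] == 1L
    s <- if (fl_now && stats::runif(1) < ocpl) 0L
         else sample.int(4L, 1L, prob = J[s + 1L, ]) - 1L
  }
  list(state = state, dwell_state = dwell_state, dwell_s = dwell_s,
       jump_matrix = J)
}

# smooth bounded random walk used for positions (cm)
reflected_walk <- function(n, dt, lo, hi, speed_cm_s, start) {
  steps <- stats::rnorm(n, 0, speed_cm_s * dt)
  # AR(1) smoothing so velocity has some persistence
  v <- stats::filter(steps, 0.9, method = "recursive") * 0.2
  x <- start + cumsum(as.numeric(v))
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Simulate a dyadic aggressive encounter
#'
#' @param config a [dyad_sim_config()].
#' @return a `sim_trial` object: per-agent ground-truth state sequences
#'   (flare class, orientation state), kinematic traces (orientation deg,
#'   elevation, position), [feature_series()] and [ethogram()]s, the drawn
#'   orientation dwell times, the config echo, and the generative
#'   parameters under `$truth`.
#' @export
simulate_dyad <- function(config) {
  stopifnot(inherits(config, "dyad_sim_config"))
  fr <- config$frame_rate
  dt <- 1 / fr
  n <- round(config$duration_s * fr)
  if (n < 2) stopf("duration too short")
  set.seed(config$seed)

  cpl <- config$turn_taking_coupling
  boost_gain <- 20
  boost_frames <- round(1 * fr) # 1-s response window after opponent offset
  p_stop <- 1 - exp(-dt / config$flare_bout_s)
  # engagement decay acts on the flaring *rate* (fraction of time flaring):
  # the initiation hazard is chosen so the stationary flare occupancy
  # tracks f0 * exp(-t / tau), inverting the bout-occupancy saturation
  # f = h*bout / (1 + h*bout)
  q0 <- config$flare_bout_s / config$flare_gap_s
  f0 <- q0 / (1 + q0)
  decay <- if (is.finite(config$engagement_tau))
    exp(-(seq_len(n) - 1) * dt / config$engagement_tau) else rep(1, n)
  f_target <- f0 * decay
  hazard <- f_target / ((1 - f_target) * config$flare_bout_s)

  fA <- integer(n); fB <- integer(n)
  a <- 0L; b <- 0L
  boostA <- 0L; boostB <- 0L # frames of boost remaining
  for (i in seq_len(n)) {
    prevA <- a; prevB <- b
    if (prevA == 1L) {
      if (stats::runif(1) < p_stop) a <- 0L
    } else {
      h <- hazard[i]
      if (prevB == 1L) h <- h * (1 - cpl)
      else if (boostA > 0L) h <- h * (1 + cpl * boost_gain)
      if (stats::runif(1) < 1 - exp(-h * dt)) a <- 1L
    }
    if (prevB == 1L) {
      if (stats::runif(1) < p_stop) b <- 0L
    } else {
      h <- hazard[i]
      if (prevA == 1L) h <- h * (1 - cpl)
      else if (boostB > 0L) h <- h * (1 + cpl * boost_gain)
      if (stats::runif(1) < 1 - exp(-h * dt)) b <- 1L
    }
    boostA <- if (prevB == 1L && b == 0L) boost_frames else max(0L, boostA - 1L)
    boostB <- if (prevA == 1L && a == 0L) boost_frames else max(0L, boostB - 1L)
    fA[i] <- a; fB[i] <- b
  }

  agents <- list()
  for (k in 1:2) {
    set.seed(derive_seed(config$seed, k))
    flare <- if (k == 1) fA else fB
    cls <- assign_flare_classes(flare)
    ori <- simulate_orientation(config, flare)
    base_deg <- c(22.5, 67.5, 112.5, 157.5)[ori$state + 1L]
    # real fish sweep through intermediate angles: ramp state changes over
    # ~0.25 s so rendered keypoints move smoothly between frames
    base_deg <- rolling_mean(base_deg, max(3L, round(0.275 * fr) %/% 2L * 2L + 1L))
    jit <- as.numeric(stats::filter(stats::rnorm(n, 0, 7 * sqrt(1 - 0.95^2)),
                                    0.95, method = "recursive"))
    ori_deg <- pmin(180, pmax(0, base_deg + pmin(pmax(jit, -20), 20)))
    flare_sm <- rolling_mean(flare, round(1 * fr))
    elev <- 5 + config$elevation_gain * flare_sm +
      as.numeric(stats::filter(stats::rnorm(n, 0, 0.3 * sqrt(1 - 0.98^2)),
                               0.98, method = "recursive"))
    elev <- pmin(10.5, pmax(0.5, elev))
    x <- reflected_walk(n, dt, 1.5, 11, 2, 6)
    y <- reflected_walk(n, dt, 1.5, 11, 2, 6)
    speed <- c(0, sqrt(diff(x)^2 + diff(y)^2)) * fr
    feats <- feature_series(
      data.frame(orientation = ori_deg, speed = speed,
                 turning_angle = c(0, wrap_angle(diff(ori_deg))),
                 elevation = elev, centroid_x = x, centroid_y = y),
      frame_rate = fr,
      units = c(orientation = "deg", speed = "cm/s",
                turning_angle = "deg/frame", elevation = "cm",
                centroid_x = "cm", centroid_y = "cm"))
    agents[[k]] <- list(
      flare = flare, flare_class = cls,
      orientation_state = ori$state, orientation_deg = ori_deg,
      elevation_cm = elev, x_cm = x, y_cm = y,
      dwell_state = ori$dwell_state, dwell_s = ori$dwell_s,
      jump_matrix = ori$jump_matrix,
      ethogram = ethogram(cls, frame_rate = fr, provenance = "manual"),
      features = feats)
  }

  structure(list(kind = "dyad", config = config, frame_rate = fr,
                 n_frames = n, agents = agents,
                 truth = list(coupling = cpl,
                              engagement_tau = config$engagement_tau,
                              dwell_means = config$dwell_means,
                              orientation_coupling = config$orientation_coupling)),
            class = "sim_trial")
}

#' Simulate flaring of a fish watching a looped animation
#'
#' @param config an [animation_sim_config()].
#' @return a `sim_trial` with a single agent whose binary flare series has
#'   length `n_loops * loop_length_s * frame_rate`; `$truth$lock_strength`
#'   and `$truth$template` record the generative state.
#' @export
simulate_animation_response <- function(config) {
  stopifnot(inherits(config, "animation_sim_config"))
  fr <- config$frame_rate
  T_loop <- round(config$loop_length_s * fr)
  n <- config$n_loops * T_loop
  set.seed(config$seed)
  # lateral epoch of the loop: fixed contiguous 30% window
  tmpl <- integer(T_loop)
  w0 <- floor(0.35 * T_loop) + 1L
  w1 <- w0 + ceiling(0.30 * T_loop) - 1L
  tmpl[w0:w1] <- 1L
  p <- (1 - config$lock_strength) * config$base_flare_rate +
    config$lock_strength * rep(tmpl, config$n_loops)
  flare <- as.integer(stats::runif(n) < p)
  cls <- assign_flare_classes(flare)
  agent <- list(flare = flare, flare_class = cls,
                ethogram = ethogram(cls, frame_rate = fr, provenance = "manual"))
  structure(list(kind = "animation", config = config, frame_rate = fr,
                 n_frames = n, agents = list(agent),
                 truth = list(lock_strength = config$lock_strength,
                              base_flare_rate = config$base_flare_rate,
                              template = tmpl)),
            class = "sim_trial")
}

#' @export
print.sim_trial <- function(x, ...) {
  cat(sprintf("<sim_trial> %s: %d frames @ %g fps, %d agent(s)\n",
              x$kind, x$n_frames, x$frame_rate, length(x$agents)))
  invisible(x)
}

#' Separable classifier fixture
#'
#' Labeled training data on which a working sequence classifier must
#' succeed: 3-class labels with ~1-2 s dwells, one feature channel a noisy
#' scaled copy of the label, the remaining channels pure noise. Generative
#' labels are the oracle for classifier sanity checks.
#'
#' @param n_frames total frames.
#' @param frame_rate frames/s.
#' @param n_noise number of pure-noise channels (default 2).
#' @param label_gain amplitude of the informative channel per class step.
#' @param noise_sd noise on the informative channel.
#' @param seed RNG seed.
#' @return list with `features` (a [feature_series()]) and `labels` (an
#'   [ethogram()]).
#' @export
separable_fixture <- function(n_frames, frame_rate = 40, n_noise = 2,
                              label_gain = 2, noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  lab <- integer(n_frames)
  dwell_mean <- c(2, 1, 1) * frame_rate # frames per class
  i <- 1L; cur <- 0L
  while (i <= n_frames) {
    d <- max(1L, round(stats::rexp(1, 1 / dwell_mean[cur + 1L])))
    lab[i:min(n_frames, i + d - 1L)] <- cur
    i <- i + d
    cur <- sample(setdiff(0:2, cur), 1L)
  }
  ch <- list(signal = label_gain * lab + stats::rnorm(n_frames, 0, noise_sd))
  for (j in seq_len(n_noise)) ch[[paste0("noise", j)]] <- stats::rnorm(n_frames)
  list(features = feature_series(as.data.frame(ch), frame_rate = frame_rate),
       labels = ethogram(lab, frame_rate = frame_rate, provenance = "manual"))
}

#' Render ground-truth states to pose keypoints
#'
#' Geometric inverse of the kinematics stage: emits per-frame keypoints
#' (nose, head, left/right operculum tips, centroid, tail) whose geometry
#' encodes heading (body-axis angle against the stimulus wall on the right
#' side of the image), flaring (operculum tip angle: 20 deg closed, 45 deg
#' partial, 75 deg full), position and speed. Confidence is 1.0 everywhere
#' unless corruption is requested; corruption injects i.i.d. low-confidence
#' garbage samples and isolated 20-px jumps, the two defects the cleaning
#' rules target.
#'
#' @param trial a `sim_trial` from [simulate_dyad()].
#' @param agent agent index.
#' @param view `"top"` or `"side"`.
#' @param conf_rate probability per frame/keypoint of a low-confidence
#'   corrupted sample.
#' @param jump_rate probability per frame/keypoint of an isolated 20-px
#'   jump (confidence stays 1).
#' @param px_per_cm rendering scale (default 20).
#' @param seed RNG seed for corruption and the heading-side stream.
#' @return a [keypoint_table()]; attribute `tank_floor_y` gives the side
#'   view floor line in px.
#' @export
render_keypoints <- function(trial, agent = 1, view = c("top", "side"),
                             conf_rate = 0, jump_rate = 0, px_per_cm = 20,
                             seed = trial$config$seed) {
  stopifnot(inherits(trial, "sim_trial"))
  view <- match.arg(view)
  ag <- trial$agents[[agent]]
  if (is.null(ag$orientation_deg))
    stopf("trial agent has no rendered kinematics (animation trials render nothing)")
  n <- trial$n_frames
  set.seed(derive_seed(seed, 100 + agent))

  # unsigned orientation doubles as the signed heading (the agent stays on
  # one turning side; keeps frame-to-frame keypoint motion physical)
  heading <- ag$orientation_deg # 0 deg = +x = toward stimulus
  th <- heading * pi / 180
  u <- cbind(cos(th), sin(th))

  if (view == "top") {
    pos <- cbind(ag$x_cm, ag$y_cm) * px_per_cm
  } else {
    floor_y <- 12 * px_per_cm
    pos <- cbind(ag$x_cm * px_per_cm, floor_y - ag$elevation_cm * px_per_cm)
  }
  half_len <- 2.5 * px_per_cm
  nose <- pos + half_len * u
  head <- pos + 0.68 * half_len * u
  tail <- pos - half_len * u
  alpha <- c(20, 45, 75)[ag$flare_class + 1L] + stats::rnorm(n, 0, 1.5)
  back <- th + pi
  d_op <- 1.0 * px_per_cm
  aL <- back + (alpha / 2) * pi / 180
  aR <- back - (alpha / 2) * pi / 180
  opl <- nose + d_op * cbind(cos(aL), sin(aL))
  opr <- nose + d_op * cbind(cos(aR), sin(aR))

  dat <- data.frame(
    nose_x = nose[, 1], nose_y = nose[, 2], nose_likelihood = 1,
    head_x = head[, 1], head_y = head[, 2], head_likelihood = 1,
    left_operculum_x = opl[, 1], left_operculum_y = opl[, 2],
    left_operculum_likelihood = 1,
    right_operculum_x = opr[, 1], right_operculum_y = opr[, 2],
    right_operculum_likelihood = 1,
    centroid_x = pos[, 1], centroid_y = pos[, 2], centroid_likelihood = 1,
    tail_x = tail[, 1], tail_y = tail[, 2], tail_likelihood = 1)

  bps <- c("nose", "head", "left_operculum", "right_operculum", "centroid",
           "tail")
  if (conf_rate > 0 || jump_rate > 0) {
    for (bp in bps) {
      cx <- paste0(bp, "_x"); cy <- paste0(bp, "_y")
      cl <- paste0(bp, "_likelihood")
      bad <- stats::runif(n) < conf_rate
      if (any(bad)) {
        dat[[cx]][bad] <- dat[[cx]][bad] + stats::rnorm(sum(bad), 0, 40)
        dat[[cy]][bad] <- dat[[cy]][bad] + stats::rnorm(sum(bad), 0, 40)
        dat[[cl]][bad] <- stats::runif(sum(bad), 0, 0.5)
      }
      jmp <- stats::runif(n) < jump_rate & !bad
      if (any(jmp)) {
        ang <- stats::runif(sum(jmp), 0, 2 * pi)
        dat[[cx]][jmp] <- dat[[cx]][jmp] + 20 * cos(ang)
        dat[[cy]][jmp] <- dat[[cy]][jmp] + 20 * sin(ang)
      }
    }
  }
  out <- keypoint_table(dat, frame_rate = trial$frame_rate, view = view,
                        px_per_cm = px_per_cm)
  attr(out, "tank_floor_y") <- 12 * px_per_cm
  out
}

#' Stimulus geometry matching [render_keypoints()]
#'
#' The renderer places the stimulus wall on the right edge of a 12.7-cm
#' tank; this helper returns the corresponding [stimulus_geometry()].
#' @param px_per_cm rendering scale used.
#' @export
rendered_stimulus_geometry <- function(px_per_cm = 20) {
  stimulus_geometry("right", position_px = 12.7 * px_per_cm,
                    tank_floor_y = 12 * px_per_cm)
}

#' Write a simulated trial's ground truth to disk
#'
#' Writes, per agent, the rendered keypoint CSV (wide pose-tracker dialect)
#' and the ground-truth event-log CSV (`time_s`, `behavior`, `status`).
#'
#' @param trial a `sim_trial`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_sim_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "sim_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (k in seq_along(trial$agents)) {
    ev <- file.path(dir, sprintf("agent%d_events.csv", k))
    write_events_csv(trial$agents[[k]]$ethogram, ev)
    files <- c(files, ev)
    if (!is.null(trial$agents[[k]]$orientation_deg)) {
      kp <- file.path(dir, sprintf("agent%d_keypoints_top.csv", k))
      write_keypoints_csv(render_keypoints(trial, k, "top"), kp)
      files <- c(files, kp)
    }
  }
  jsonlite::write_json(list(kind = trial$kind, seed = trial$config$seed,
                            frame_rate = trial$frame_rate,
                            n_frames = trial$n_frames),
                       file.path(dir, "trial.json"), auto_unbox = TRUE)
  invisible(files)
}
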