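# co-flaring filter, point-biserial correlations + shuffle control,
# bout selection, PETHs, persistence

test_that("coflaring_filter is the element-wise OR", {
  a <- c(1L, 1L, 0L, 0L); b <- c(1L, 0L, 1L, 0L)
  expect_equal(coflaring_filter(a, b), c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(coflaring_filter(rep(1L, 5), rep(1L, 5))))
  expect_false(any(coflaring_filter(rep(0L, 5), rep(0L, 5))))
  set.seed(1)
  x <- rbinom(200, 1, 0.3); y <- rbinom(200, 1, 0.3)
  expect_equal(sum(coflaring_filter(x, y)), sum(bitwOr(x, y)))
  expect_error(coflaring_filter(x, y[1:10]), "lengths")
})

test_that("point-biserial equals Pearson and the classical closed form", {
  set.seed(3)
  f <- rbinom(200, 1, 0.4)
  x <- rnorm(200) + 0.8 * f
  r <- flare_feature_correlation(f, x)
  expect_equal(as.numeric(r), cor(f, x))
  p <- mean(f)
  s_n <- sd(x) * sqrt(199 / 200) # population sd
  r_pb <- (mean(x[f == 1]) - mean(x[f == 0])) / s_n * sqrt(p * (1 - p))
  expect_equal(as.numeric(r), r_pb)
  # feature identical to the indicator
  expect_equal(as.numeric(flare_feature_correlation(f, f)), 1)
})

test_that("never-flaring fish is assigned r = 0; degenerate feature is NA", {
  r <- flare_feature_correlation(rep(0L, 50), rnorm(50))
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "zero_assigned"))
  r2 <- flare_feature_correlation(rbinom(50, 1, .5), rep(3, 50))
  expect_true(is.na(r2))
})

test_that("shuffle control permutes only masked values and is centered", {
  set.seed(4)
  f <- rbinom(500, 1, 0.4)
  x <- rnorm(500)
  mask <- rep(TRUE, 500)
  sh <- shuffle_control(f, x, mask, seed = 7)
  expect_equal(as.numeric(sh), as.numeric(sh)) # well-defined
  # permutation preserves the multiset of masked values
  x2 <- x
  set.seed(7); idx <- which(mask); x2[idx] <- x2[idx][sample.int(length(idx))]
  expect_equal(sort(x2), sort(x))
  rs <- vapply(1:300, function(s)
    as.numeric(shuffle_control(f, x, mask, seed = s)), 1)
  expect_lt(abs(mean(rs)), 0.02)
  # n = 2 masked frames: the only two permutations give +/- observed
  f2 <- c(0L, 1L); x3 <- c(0.3, 1.7)
  obs <- as.numeric(flare_feature_correlation(f2, x3))
  perm <- vapply(1:20, function(s) as.numeric(shuffle_control(f2, x3, seed = s)), 1)
  expect_true(all(abs(abs(perm) - abs(obs)) < 1e-12))
})

test_that("select_bouts applies the 3-s isolation rule", {
  fr <- 40
  # single 10-s bout, well isolated
  fl <- rep(0L, 30 * fr); fl[(10 * fr + 1):(20 * fr)] <- 1L
  ev <- select_bouts(fl, fr)
  expect_equal(sum(ev$qualifies[ev$kind == "onset"]), 1)
  expect_equal(sum(ev$qualifies[ev$kind == "offset"]), 1)
  # two 4-s bouts separated by 1 s: second onset and first offset fail
  fl2 <- rep(0L, 40 * fr)
  fl2[(10 * fr + 1):(14 * fr)] <- 1L
  fl2[(15 * fr + 1):(19 * fr)] <- 1L
  ev2 <- select_bouts(fl2, fr)
  on <- ev2[ev2$kind == "onset", ]; off <- ev2[ev2$kind == "offset", ]
  expect_equal(on$qualifies, c(TRUE, FALSE))
  expect_equal(off$qualifies, c(FALSE, TRUE))
  # events near record boundaries never qualify
  fl3 <- rep(0L, 10 * fr); fl3[1:(5 * fr)] <- 1L
  ev3 <- select_bouts(fl3, fr)
  expect_false(any(ev3$qualifies[ev3$kind == "onset"]))
})

test_that("select_bouts matches a brute-force window scan", {
  set.seed(6)
  fr <- 10; w <- 3 * fr
  fl <- as.integer(runif(600) < 0.35)
  ev <- select_bouts(fl, fr)
  brute <- function(kind, f0) {
    if (f0 - w < 1 || f0 + w - 1 > length(fl)) return(FALSE)
    if (kind == "onset") all(fl[(f0 - w):(f0 - 1)] == 0) && all(fl[f0:(f0 + w - 1)] == 1)
    else all(fl[(f0 - w):(f0 - 1)] == 1) && all(fl[f0:(f0 + w - 1)] == 0)
  }
  for (k in seq_len(nrow(ev)))
    expect_equal(ev$qualifies[k], brute(ev$kind[k], ev$frame[k]),
                 info = sprintf("row %d", k))
})

test_that("peth: construction oracle, single event, constant feature", {
  fr <- 40
  fl <- rep(0L, 60 * fr)
  for (s in c(10, 25, 40)) fl[(s * fr + 1):((s + 5) * fr)] <- 1L
  ev <- select_bouts(fl, fr)
  # feature steps 0 -> 1 exactly 0.5 s after every onset
  feat <- rep(0, length(fl))
  for (s in c(10, 25, 40)) feat[((s + 0.5) * fr + 1):length(fl)] <- 1
  feat[fl == 0 & seq_along(fl) > 26 * fr & seq_along(fl) <= 40 * fr] <- 0 # reset between bouts
  feat <- as.numeric(feat)
  p <- peth(ev[ev$kind == "onset", ], feat, fr)
  expect_equal(p$n_events, 3)
  i_before <- which(p$time_s == 0.4); i_after <- which(p$time_s == 0.6)
  expect_lt(p$mean[i_before], p$mean[i_after])
  expect_equal(p$mean[i_after], 1)
  # one event: mean is the single trace, SEM = 0
  p1 <- peth(ev$frame[ev$qualifies & ev$kind == "onset"][1], feat, fr)
  expect_equal(p1$n_events, 1)
  expect_true(all(p1$sem == 0))
  expect_equal(p1$mean, p1$traces[1, ])
  # constant feature: flat mean, zero SEM
  pc <- peth(ev[ev$kind == "onset", ], rep(2.5, length(fl)), fr)
  expect_true(all(pc$mean == 2.5))
  expect_true(all(pc$sem == 0))
  # no qualifying events: sentinel, not an exception
  p0 <- peth(data.frame(kind = character(0), frame = integer(0),
                        qualifies = logical(0)), feat, fr)
  expect_equal(p0$n_events, 0)
})

test_that("peth mean over identical events equals any single trace", {
  fr <- 20
  feat <- sin(seq(0, 20, length.out = 30 * fr))
  frames <- c(200, 200, 200)
  p <- peth(frames, feat, fr)
  expect_equal(p$mean, p$traces[1, ])
  expect_true(all(p$sem == 0))
})

test_that("normalize_elevation: min-max with degenerate flag", {
  expect_equal(as.numeric(normalize_elevation(c(2, 4, 6))), c(0, 0.5, 1))
  z <- normalize_elevation(rep(1.3, 7))
  expect_true(all(z == 0))
  expect_true(attr(z, "degenerate"))
  set.seed(8)
  w <- rnorm(50)
  nw <- normalize_elevation(w)
  expect_equal(as.numeric(nw[which.min(w)]), 0)
  expect_equal(as.numeric(nw[which.max(w)]), 1)
  expect_true(all(nw >= 0 & nw <= 1))
})

test_that("persistence: closed-form crossings and parameter recovery", {
  # exact exponential bins: tau = 120 s, c = 0
  fr <- 40
  n <- 600 * fr
  tsec <- (seq_len(n) - 1) / fr
  # deterministic 'flare probability' encoded as bin proportions via a
  # Bernoulli draw with many fish to keep noise tiny
  set.seed(9)
  flares <- lapply(1:30, function(i)
    as.integer(runif(n) < 0.5 * exp(-tsec / 120)))
  pc <- persistence(flares, frame_rate = fr)
  expect_lt(abs(pc$fit$tau - 120) / 120, 0.1)
  # with c ~ 0 the 3/4 crossing is tau * ln(4/3) (~34.5 s at tau = 120)
  expect_equal(unname(pc$crossings["f0.75"]), pc$fit$tau * log(4 / 3),
               tolerance = 0.05)
  # half crossing exceeds three-quarter crossing
  expect_gt(pc$crossings["f0.5"], pc$crossings["f0.75"])
  # pure closed form through the internal fitter
  tt <- (1:70 - 0.5) * 8
  y <- 0.4 * exp(-tt / 120)
  fit <- flarekit:::fit_exponential_decay(tt, y)
  expect_equal(fit$tau, 120, tolerance = 1e-3)
  expect_equal(fit$A, 0.4, tolerance = 1e-3)
  expect_equal(fit$c, 0, tolerance = 1e-4)
})

test_that("persistence bin proportions survive frame-rate resampling", {
  # same on/off times sampled at 40 and 80 fps give matching bin fractions
  on_s <- c(3, 20, 41); off_s <- c(9, 30, 55)
  mk <- function(fr) {
    fl <- rep(0L, 64 * fr)
    for (k in seq_along(on_s)) fl[(on_s[k] * fr + 1):(off_s[k] * fr)] <- 1L
    fl
  }
  p40 <- persistence(mk(40), frame_rate = 40, smooth_s = 0)
  p80 <- persistence(mk(80), frame_rate = 80, smooth_s = 0)
  expect_equal(p40$proportion, p80$proportion, tolerance = 1 / (8 * 40))
})

test_that("cohort correlation report reproduces generator sign structure", {
  # coupled dyads: flare vs opponent flare negative, vs opponent lateral
  # positive (opponents go lateral while not flaring)
  fish <- lapply(1:6, function(i) {
    tr <- simulate_dyad(dyad_sim_config(duration_s = 240,
                                        turn_taking_coupling = 0.9,
                                        orientation_coupling = 0.8,
                                        seed = derive_seed(55, i)))
    a <- tr$agents[[1]]; b <- tr$agents[[2]]
    list(flare = a$flare, opponent_flare = b$flare,
         features = list(opp_flare = as.numeric(b$flare),
                         opp_lateral = as.numeric(b$orientation_state == 2)))
  })
  rep_ <- correlation_report(fish, seed = 2)
  tests <- rep_$tests
  expect_lt(tests$mean_obs[tests$feature == "opp_flare"], 0)
  expect_gt(tests$mean_obs[tests$feature == "opp_lateral"], 0)
  expect_lt(abs(tests$mean_shuf[tests$feature == "opp_flare"]), 0.1)
  expect_true(all(c("t", "p") %in% names(tests)))
})
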