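# Shared fixtures, built in code at test time.

# tiny keypoint table: one body part moving linearly, configurable
# confidence/jump defects
kp_fixture <- function(x, y = x, lik = rep(1, length(x)), bp = "nose",
                       frame_rate = 40, px_per_cm = 10) {
  d <- data.frame(a = x, b = y, c = lik)
  names(d) <- paste0(bp, c("_x", "_y", "_likelihood"))
  keypoint_table(d, frame_rate = frame_rate, px_per_cm = px_per_cm)
}

# closed polygon around an L-shaped "fish": straight body along +x from
# (0,0) to (len,0), then a tail segment of length tail_len rotated by
# angle_deg about the peduncle (len,0). Points are spaced ~1 px along the
# path, like a pixel-dense video contour, so 100 surrounding points span a
# length much larger than the body width (the line fits need this).
bent_fish_contour <- function(angle_deg, body_len = 100, tail_len = 60,
                              width = 6, spacing = 0.9) {
  th <- angle_deg * pi / 180
  n1 <- round(body_len / spacing); n2 <- round(tail_len / spacing)
  spine_x <- c(seq(0, body_len, length.out = n1),
               body_len + seq(0, tail_len, length.out = n2) * cos(th))
  spine_y <- c(rep(0, n1), seq(0, tail_len, length.out = n2) * sin(th))
  # offset both sides to close the polygon
  top <- cbind(spine_x, spine_y + width / 2)
  bot <- cbind(rev(spine_x), rev(spine_y) - width / 2)
  rbind(top, bot)
}

# small dyad trial reused across tests (5 min keeps things fast)
cached_trial <- local({
  tr <- NULL
  function() {
    if (is.null(tr)) tr <<- simulate_dyad(dyad_sim_config(
      duration_s = 300, orientation_coupling = 0, seed = 7))
    tr
  }
})
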