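# Behavioral-state transition graphs: 8 per-fish states (flare on/off x
# orientation category), 64 dyadic states, directional transition
# probabilities over state-change events (the embedded jump chain),
# occupancy/probability filters, and a two-eigenvector spectral layout.

ORIENTATION_BANDS <- c(facing = 45, turning = 90, lateral = 135)

#' Discretize flaring and orientation into 8 per-fish states
#'
#' State id = `4 * flare + orientation_category`, with orientation
#' categories facing (0: < 45 deg), turning (1: 45-90), lateral (2:
#' 90-135), turning-away (3: > 135). These static angle bands are the
#' default; with `dynamic = TRUE`, frames in the 45-135 band whose angular
#' velocity carries the fish away from the stimulus (increasing
#' orientation faster than `turn_rate_deg_s`) are classified turning-away
#' instead, and 45-90 frames moving toward lateral are turning.
#'
#' @param flare binary (0/1) series.
#' @param orientation_deg unsigned orientation in \[0, 180\], deg.
#' @param frame_rate frames/s (used by the dynamic rule).
#' @param dynamic use the angular-velocity rule (default FALSE).
#' @param turn_rate_deg_s angular-speed threshold for the dynamic rule.
#' @return integer state sequence in 0..7.
#' @export
discretize_states <- function(flare, orientation_deg, frame_rate = 40,
                              dynamic = FALSE, turn_rate_deg_s = 30) {
  if (length(flare) != length(orientation_deg)) stopf("series lengths differ")
  o <- orientation_deg
  cat_ <- findInterval(o, c(ORIENTATION_BANDS, 181)) # 0..3
  cat_[cat_ > 3L] <- 3L
  if (dynamic) {
    # in the middle band, fast rotation away from the stimulus counts as
    # turning-away, fast rotation back toward it as turning
    vel <- c(0, diff(o)) * frame_rate # deg/s; + = orientation increasing
    mid <- o >= 45 & o <= 135
    cat_[mid & vel > turn_rate_deg_s] <- 3L
    cat_[mid & vel < -turn_rate_deg_s] <- 1L
  }
  as.integer(4L * as.integer(flare) + cat_)
}

#' Combine two per-fish state sequences into dyadic states
#'
#' @param a,b integer sequences of per-fish states in 0..7.
#' @return integer sequence of dyad state ids `8 * a + b` in 0..63.
#' @export
dyad_states <- function(a, b) {
  if (length(a) != length(b)) stopf("state sequences have different lengths")
  if (any(a < 0 | a > 7) || any(b < 0 | b > 7)) stopf("states must be in 0..7")
  as.integer(8L * as.integer(a) + as.integer(b))
}

#' Estimate a directional transition graph from state sequences
#'
#' Transitions are counted at state-change events only (self-transitions
#' excluded), giving the embedded jump chain of the semi-Markov process;
#' dwell times are recorded separately per state. Counts are pooled across
#' sequences but never across a sequence boundary. Occupancy is the
#' fraction of frames spent in each state.
#'
#' @param seqs integer state sequence, or list of sequences (pooled).
#' @param n_states size of the state space (64 for dyad states, 8 for
#'   per-fish states).
#' @param frame_rate frames/s, used to express dwell times in seconds.
#' @return a `transition_graph`: `counts` (n x n), `P` (row-stochastic over
#'   rows with outgoing transitions), `occupancy` (length n, sums to 1),
#'   `dwell_s` (list of per-state dwell samples), `retained` (node filter,
#'   all TRUE initially), `n_states`.
#' @export
transition_matrix <- function(seqs, n_states = 64, frame_rate = 40) {
  if (!is.list(seqs)) seqs <- list(seqs)
  if (length(seqs) == 0L) stopf("need at least one sequence")
  counts <- matrix(0, n_states, n_states)
  occ <- numeric(n_states)
  dwell <- vector("list", n_states)
  total <- 0L
  for (s in seqs) {
    s <- as.integer(s)
    if (any(s < 0L | s >= n_states)) stopf("state id outside 0..%d", n_states - 1L)
    total <- total + length(s)
    occ_t <- tabulate(s + 1L, nbins = n_states)
    occ <- occ + occ_t
    r <- rle(s)
    v <- r$values + 1L
    for (k in seq_along(v)) {
      dwell[[v[k]]] <- c(dwell[[v[k]]], r$lengths[k] / frame_rate)
    }
    if (length(v) > 1L) {
      from <- v[-length(v)]; to <- v[-1L]
      for (k in seq_along(from)) counts[from[k], to[k]] <- counts[from[k], to[k]] + 1
    }
  }
  rs <- rowSums(counts)
  P <- counts
  nz <- rs > 0
  P[nz, ] <- P[nz, , drop = FALSE] / rs[nz]
  structure(list(counts = counts, P = P, occupancy = occ / total,
                 dwell_s = dwell, retained = rep(TRUE, n_states),
                 n_states = n_states, frame_rate = frame_rate),
            class = "transition_graph")
}

#' @export
print.transition_graph <- function(x, ...) {
  cat(sprintf("<transition_graph> %d states (%d retained), %d transitions\n",
              x$n_states, sum(x$retained), sum(x$counts)))
  invisible(x)
}

#' Filter a transition graph by occupancy and edge probability
#'
#' Removes states occupied less than `occ_min` of the time; removes an
#' edge only when its transition probability is below `p_min` in this
#' graph AND in the `companion` graph (the second condition of a paired
#' design). Without a companion the single-graph rule applies.
#'
#' @param g a [transition_matrix()] result.
#' @param occ_min occupancy threshold (default 0.02).
#' @param p_min edge probability threshold (default 0.0025).
#' @param companion optional second `transition_graph`.
#' @return `g` with `retained` updated and `edges` (data.frame `from`,
#'   `to`, `p`, 1-based ids) attached.
#' @export
filter_graph <- function(g, occ_min = 0.02, p_min = 0.0025, companion = NULL) {
  stopifnot(inherits(g, "transition_graph"))
  retained <- g$occupancy >= occ_min
  keep_edge <- g$P >= p_min
  if (!is.null(companion)) {
    stopifnot(inherits(companion, "transition_graph"),
              companion$n_states == g$n_states)
    keep_edge <- keep_edge | (companion$P >= p_min)
  }
  keep_edge <- keep_edge & (g$P > 0)
  keep_edge[!retained, ] <- FALSE
  keep_edge[, !retained] <- FALSE
  idx <- which(keep_edge, arr.ind = TRUE)
  g$retained <- retained
  g$edges <- data.frame(from = idx[, 1], to = idx[, 2],
                        p = g$P[keep_edge])
  g$occ_min <- occ_min
  g$p_min <- p_min
  g
}

#' Two-eigenvector spectral layout of a transition graph
#'
#' Coordinates come from the two leading nontrivial eigenvectors of the
#' symmetrized transition matrix `(P + t(P)) / 2` restricted to retained
#' nodes. Connected components are laid out independently and offset along
#' x. Deterministic: each eigenvector's sign is fixed so its first nonzero
#' coordinate is positive.
#'
#' @param g a (possibly filtered) `transition_graph`.
#' @return data.frame `state` (0-based id), `x`, `y`, `occupancy`.
#' @export
spectral_layout <- function(g) {
  stopifnot(inherits(g, "transition_graph"))
  nodes <- which(g$retained)
  if (length(nodes) < 2) stopf("need at least 2 retained nodes")
  W <- (g$P[nodes, nodes, drop = FALSE] +
          t(g$P[nodes, nodes, drop = FALSE])) / 2
  gr <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  comp <- igraph::components(gr)$membership
  xy <- matrix(0, length(nodes), 2)
  for (cid in sort(unique(comp))) {
    m <- comp == cid
    k <- sum(m)
    if (k == 1) {
      coords <- matrix(0, 1, 2)
    } else {
      e <- eigen(W[m, m, drop = FALSE], symmetric = TRUE)
      vecs <- e$vectors[, seqint_safe(2, min(3, k)), drop = FALSE]
      if (ncol(vecs) < 2) vecs <- cbind(vecs, 0)
      for (j in 1:2) {
        v <- vecs[, j]
        nzi <- which(abs(v) > 1e-12)
        if (length(nzi) && v[nzi[1]] < 0) vecs[, j] <- -v
      }
      coords <- vecs[, 1:2, drop = FALSE]
    }
    # offset components so they do not overlap
    coords[, 1] <- coords[, 1] + 2.5 * (cid - 1)
    xy[m, ] <- coords
  }
  data.frame(state = nodes - 1L, x = xy[, 1], y = xy[, 2],
             occupancy = g$occupancy[nodes])
}

seqint_safe <- function(a, b) if (b < a) integer(0) else seq.int(a, b)

#' Check per-state dwell times for exponentiality
#'
#' One-sample Kolmogorov-Smirnov test of each state's dwell-time samples
#' against an exponential with that state's empirical mean. States with
#' fewer than `min_n` samples are skipped. (Using the empirical mean makes
#' the test conservative; it is a descriptive check, not a calibrated
#' goodness-of-fit test.)
#'
#' @param g a `transition_graph`.
#' @param min_n minimum dwell samples per state (default 20).
#' @param alpha rejection level reported against (default 0.01).
#' @return data.frame `state` (0-based), `n`, `mean_s`, `ks_stat`, `p`,
#'   `reject`, `skipped`.
#' @export
dwell_distribution_check <- function(g, min_n = 20, alpha = 0.01) {
  stopifnot(inherits(g, "transition_graph"))
  rows <- lapply(seq_len(g$n_states), function(i) {
    d <- g$dwell_s[[i]]
    if (length(d) < min_n)
      return(data.frame(state = i - 1L, n = length(d), mean_s = NA_real_,
                        ks_stat = NA_real_, p = NA_real_, reject = NA,
                        skipped = TRUE))
    m <- mean(d)
    kt <- suppressWarnings(stats::ks.test(d, "pexp", rate = 1 / m))
    data.frame(state = i - 1L, n = length(d), mean_s = m,
               ks_stat = unname(kt$statistic), p = kt$p.value,
               reject = kt$p.value < alpha, skipped = FALSE)
  })
  do.call(rbind, rows)
}
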