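# Independent oracles used across the suite. These deliberately avoid the
# package's geometric code paths: areas by rejection sampling, neighbour
# distances by brute-force all-pairs scans.

# Monte-Carlo estimate of every agent's cutoff-Voronoi area: sample points
# uniformly in the cutoff disk around each agent and classify each sample
# to its nearest agent. Returns estimates and their binomial standard
# errors.
mc_dod_oracle <- function(points, delta, n_samples = 1e5,
                          agents = seq_len(nrow(points))) {
  a_max <- pi * delta^2
  est <- se <- rep(NA_real_, nrow(points))
  for (i in agents) {
    r <- delta * sqrt(runif(n_samples))
    th <- runif(n_samples, 0, 2 * pi)
    sx <- points[i, 1] + r * cos(th)
    sy <- points[i, 2] + r * sin(th)
    # squared distance of every sample to every agent
    d2 <- outer(sx, points[, 1], "-")^2 + outer(sy, points[, 2], "-")^2
    wins <- max.col(-d2, ties.method = "first") == i
    p <- mean(wins)
    est[i] <- p * a_max
    se[i] <- a_max * sqrt(p * (1 - p) / n_samples)
  }
  list(areas = est, se = se)
}

# brute-force nearest-neighbour distances
bf_nn_oracle <- function(points) {
  n <- nrow(points)
  sapply(seq_len(n), function(i) {
    d <- sqrt((points[, 1] - points[i, 1])^2 + (points[, 2] - points[i, 2])^2)
    min(d[-i])
  })
}

# random non-overlapping configuration in a box
random_points <- function(n, box = 30, min_dist = 1) {
  pts <- matrix(NA_real_, n, 2)
  placed <- 0
  while (placed < n) {
    cand <- runif(2, 0, box)
    if (placed == 0 ||
        min(sqrt(colSums((t(pts[1:placed, , drop = FALSE]) - cand)^2))) >= min_dist) {
      placed <- placed + 1
      pts[placed, ] <- cand
    }
  }
  pts
}

# small config for fast desk-scale training runs
tiny_config <- function(...) {
  shh_config(n_agents = 10L, box_side = 12, steps_per_episode = 100L,
             n_episodes = 2L, minibatch = 256L, seed = 42L, ...)
}
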