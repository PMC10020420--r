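# Deterministic fixture generators: reference configurations and scripted
# trajectories with known geometry and rotational state, used by the test
# suite and available for desk checks.

#' Generate a named fixture configuration or trajectory
#'
#' \describe{
#'   \item{lattice}{square lattice, `n_side^2` agents at `spacing`,
#'     headings 0.}
#'   \item{ring}{`n_agents` on a circle of `radius` with tangential
#'     headings; `handedness` +1 (counter-clockwise), -1, or `"mixed"`
#'     (alternating).}
#'   \item{mill}{agents on concentric rings (spacing `spacing`) with
#'     tangential headings; with `n_frames > 1`, a trajectory rotating
#'     rigidly by `omega` radians per frame.}
#'   \item{gas}{random non-overlapping frames (re-scattered independently
#'     every frame when `n_frames > 1`); headings uniform.}
#'   \item{two_vortex}{two mirrored mills side by side: zero net rotation
#'     but opposite-sign local vortices.}
#' }
#' Trajectories carry per-frame domain-of-danger areas and rewards
#' computed from the configuration in `config`, so every analysis function
#' applies to them.
#'
#' @param type fixture name.
#' @param n_agents agent count (ring/gas; mills are built from rings).
#' @param n_frames 1 for a single [herd_frame()], larger for a
#'   `herd_trajectory`.
#' @param spacing lattice/ring spacing, sigma.
#' @param radius ring radius, sigma.
#' @param n_side lattice side count.
#' @param handedness +1, -1 or `"mixed"` (ring only).
#' @param omega rigid rotation per frame, radians.
#' @param seed RNG seed (gas).
#' @param config [shh_config()] used for areas/rewards of trajectories.
#' @return `herd_frame` or `herd_trajectory`.
#' @export
make_fixture <- function(type = c("lattice", "ring", "mill", "gas", "two_vortex"),
                         n_agents = 24L, n_frames = 1L, spacing = 2,
                         radius = 5, n_side = 5L, handedness = 1,
                         omega = 0.05, seed = 1L, config = shh_config()) {
  type <- match.arg(type)
  frame <- switch(type,
    lattice = {
      g <- expand.grid(x = seq_len(n_side), y = seq_len(n_side))
      herd_frame(as.matrix(g) * spacing, rep(0, nrow(g)))
    },
    ring = ring_frame(n_agents, radius, handedness),
    mill = mill_frame(n_agents, spacing, handedness),
    gas = {
      set.seed(seed)
      init_episode(n_agents, box_side = max(10, ceiling(2 * sqrt(n_agents))),
                   rng_seed = NULL)
    },
    two_vortex = {
      a <- mill_frame(ceiling(n_agents / 2), spacing, +1)
      b <- mill_frame(floor(n_agents / 2), spacing, -1)
      gap <- 2 * (max(sqrt(rowSums(a$positions^2))) + 2 * spacing)
      herd_frame(rbind(sweep(a$positions, 2, c(-gap / 2, 0), "+"),
                       sweep(b$positions, 2, c(+gap / 2, 0), "+")),
                 c(a$headings, b$headings))
    })
  if (n_frames == 1L) return(frame)

  frames <- vector("list", n_frames)
  if (type == "gas") {
    set.seed(seed)
    box <- max(10, ceiling(2 * sqrt(n_agents)))
    for (t in seq_len(n_frames))
      frames[[t]] <- init_episode(n_agents, box_side = box, rng_seed = NULL)
  } else if (type == "two_vortex") {
    # each half spins about its own core, with opposite handedness
    nh <- ceiling(n_agents / 2)
    for (t in seq_len(n_frames)) {
      a <- rotate_frame(mill_frame(nh, spacing, +1), omega * (t - 1))
      b <- rotate_frame(mill_frame(n_agents - nh, spacing, -1),
                        -omega * (t - 1))
      gap <- 2 * (max(sqrt(rowSums(a$positions^2))) + 2 * spacing)
      frames[[t]] <- herd_frame(
        rbind(sweep(a$positions, 2, c(-gap / 2, 0), "+"),
              sweep(b$positions, 2, c(+gap / 2, 0), "+")),
        c(a$headings, b$headings), t - 1L)
    }
  } else {
    for (t in seq_len(n_frames))
      frames[[t]] <- rotate_frame(frame, omega * (t - 1))
  }
  trajectory_from_frames(frames, config)
}

ring_frame <- function(n, radius, handedness) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  pos <- radius * cbind(cos(ang), sin(ang))
  hand <- if (identical(handedness, "mixed"))
    rep_len(c(1, -1), n) else rep_len(handedness, n)
  herd_frame(pos, ang + hand * pi / 2)
}

# concentric rings around one centre agent, ~6k agents on ring k
mill_frame <- function(n, spacing, handedness) {
  pos <- matrix(0, 0, 2)
  hd <- numeric(0)
  k <- 1L
  while (nrow(pos) < n) {
    m <- min(6L * k, n - nrow(pos))
    ang <- 2 * pi * (seq_len(m) - 1) / m
    pos <- rbind(pos, k * spacing * cbind(cos(ang), sin(ang)))
    hd <- c(hd, ang + handedness * pi / 2)
    k <- k + 1L
  }
  herd_frame(pos, hd)
}

rotate_frame <- function(frame, phi) {
  ctr <- colMeans(frame$positions)
  rel <- sweep(frame$positions, 2, ctr)
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  herd_frame(sweep(rel %*% t(rot), 2, ctr, "+"), frame$headings + phi)
}

#' Assemble a trajectory from a list of frames
#'
#' Computes per-frame domain-of-danger areas, nearest-neighbour distances
#' and rewards under `config`, filling scripted `stand_still` actions, so
#' externally built frame sequences can be analysed like rollouts.
#'
#' @param frames list of [herd_frame()] with constant agent count.
#' @param config [shh_config()].
#' @return `herd_trajectory`.
#' @export
trajectory_from_frames <- function(frames, config = shh_config()) {
  T_ <- length(frames)
  N <- nrow(frames[[1]]$positions)
  rpar <- reward_params(config$c, config$d0, config$delta, config$w,
                        config$sigma)
  posi <- array(0, c(T_, N, 2))
  head_ <- acts <- r_shh <- r_prox <- areas <- nnd <- matrix(0, T_, N)
  acts[] <- match("stand_still", ACTIONS)
  for (t in seq_len(T_)) {
    posi[t, , ] <- frames[[t]]$positions
    head_[t, ] <- frames[[t]]$headings
    dod <- compute_dod(frames[[t]]$positions, config$delta)
    areas[t, ] <- dod$areas
    nnd[t, ] <- dod$nn_distance
    r_shh[t, ] <- reward_shh(dod$areas, rpar)
    r_prox[t, ] <- reward_prox(dod$nn_distance, rpar)
  }
  structure(list(positions = posi, headings = head_, actions = acts,
                 r_shh = r_shh, r_prox = r_prox, reward = r_shh + r_prox,
                 areas = areas, nn_distance = nnd, config = config,
                 seed = NA_integer_, init = frames[[1]]),
            class = "herd_trajectory")
}
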