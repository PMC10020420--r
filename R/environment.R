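#' Kinematic parameters of a disk agent
#'
#' Per (non-passive) action an agent translates `step_length` = 0.25 sigma;
#' turning actions follow a circular arc of radius `turn_radius` = 0.8 sigma
#' through `turn_angle` = 18 degrees, so the arc length matches the step
#' length (0.8 * 18 * pi/180 = 0.2513 sigma). Actions are subject to
#' multiplicative Gaussian white noise with relative standard deviation
#' `noise_sd` (default 20%).
#'
#' @param step_length translation per action, sigma.
#' @param turn_radius radius of curvature of turning actions, sigma.
#' @param turn_angle turn per action, degrees.
#' @param noise_sd relative noise amplitude (dimensionless).
#' @return list of class `kinematics_params`.
#' @export
kinematics_params <- function(step_length = 0.25, turn_radius = 0.8,
                              turn_angle = 18, noise_sd = 0.2) {
  stopifnot(step_length > 0, turn_radius > 0, turn_angle > 0, noise_sd >= 0)
  if (abs(turn_radius * turn_angle * pi / 180 - step_length) > 0.01)
    warning("turn arc length deviates from step_length by more than 0.01 sigma")
  structure(list(step_length = step_length, turn_radius = turn_radius,
                 turn_angle = turn_angle, noise_sd = noise_sd),
            class = "kinematics_params")
}

#' The four agent actions
#' @format character vector: forward, turn_left, turn_right, stand_still.
#' @export
ACTIONS <- c("forward", "turn_left", "turn_right", "stand_still")

#' Construct a herd frame
#'
#' A frame is the state of all agents at one time step: positions (N x 2,
#' sigma), headings (radians, normalized to `[0, 2*pi)`), and a time index.
#'
#' @param positions N x 2 numeric matrix.
#' @param headings numeric vector of length N.
#' @param time_index non-negative integer.
#' @return object of class `herd_frame`.
#' @export
herd_frame <- function(positions, headings, time_index = 0L) {
  positions <- as_points(positions)
  headings <- as.numeric(headings) %% (2 * pi)
  stopifnot(length(headings) == nrow(positions), all(is.finite(headings)),
            time_index >= 0)
  structure(list(positions = positions, headings = headings,
                 time_index = as.integer(time_index)),
            class = "herd_frame")
}

#' @export
print.herd_frame <- function(x, ...) {
  cat(sprintf("<herd_frame> N = %d agents, t = %d\n", nrow(x$positions),
              x$time_index))
  invisible(x)
}

#' Apply one action to one agent
#'
#' `stand_still` leaves the state untouched (and consumes no noise).
#' `forward` translates `step_length * (1 + noise_sd * eta1)` along the
#' heading and adds a diffusive heading wobble `noise_sd * turn_angle *
#' eta2`. Turning actions move along a circular arc of radius `turn_radius`
#' through the signed angle `turn_angle * (1 + noise_sd * eta2)`; the
#' displacement is the chord of that arc and the heading rotates by the
#' same angle.
#'
#' @param position length-2 numeric, sigma.
#' @param heading radians.
#' @param action one of `ACTIONS`.
#' @param params [kinematics_params()].
#' @param noise_draw two standard-normal variates (eta1, eta2) supplied by
#'   the caller, so the kinematics are a deterministic function.
#' @return list with `position` and `heading`.
#' @export
apply_action <- function(position, heading, action,
                         params = kinematics_params(),
                         noise_draw = c(0, 0)) {
  if (!action %in% ACTIONS)
    stop(sprintf("invalid action '%s'", action))
  if (action == "stand_still")
    return(list(position = position, heading = heading %% (2 * pi)))
  eta1 <- noise_draw[1]; eta2 <- noise_draw[2]
  th <- heading
  if (action == "forward") {
    len <- params$step_length * (1 + params$noise_sd * eta1)
    position <- position + len * c(cos(th), sin(th))
    th <- th + params$noise_sd * params$turn_angle * pi / 180 * eta2
  } else {
    sgn <- if (action == "turn_left") 1 else -1
    alpha <- sgn * params$turn_angle * pi / 180 * (1 + params$noise_sd * eta2)
    # rotation by alpha about the centre of curvature at (0, sgn * R) in
    # the agent's own frame; the chord below, rotated into the lab frame
    C <- sgn * params$turn_radius
    local <- c(C * sin(alpha), C * (1 - cos(alpha)))
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    position <- position + as.numeric(rot %*% local)
    th <- th + alpha
  }
  list(position = position, heading = th %% (2 * pi))
}

#' Resolve hard-disk overlaps
#'
#' Iteratively pushes every overlapping pair (centre distance < sigma)
#' apart symmetrically along the centre line to contact distance sigma,
#' sweeping until the largest residual overlap is below `tol` or
#' `max_iter` sweeps have run. Non-convergence yields a warning, never an
#' error: dense transients are expected during aggregation.
#'
#' @param frame a [herd_frame()].
#' @param sigma body diameter (the length unit; default 1).
#' @param tol residual overlap tolerance, sigma.
#' @param max_iter maximum number of sweeps.
#' @return the frame with resolved positions; attribute `"displacement"`
#'   holds the per-agent total displacement applied.
#' @export
resolve_overlaps <- function(frame, sigma = 1, tol = 1e-6, max_iter = 100) {
  res <- .resolve_overlaps_cpp(frame$positions, sigma, tol, max_iter)
  if (!res$converged)
    warning(sprintf("overlap resolution did not converge in %d sweeps", max_iter))
  out <- frame
  out$positions <- res$positions
  attr(out, "displacement") <- res$displacement
  out
}

#' Initialize an episode from a random configuration
#'
#' Positions are uniform in a square of side `box_side`, rejection-sampled
#' so that all pairwise distances are at least sigma; headings are uniform
#' in `[0, 2*pi)`. Fully deterministic given the seed.
#'
#' @param n_agents number of agents (>= 2).
#' @param box_side side of the initial square, sigma (default 40).
#' @param rng_seed integer seed; `NULL` uses the current RNG state.
#' @param sigma body diameter.
#' @return a [herd_frame()] at `time_index = 0`.
#' @export
init_episode <- function(n_agents, box_side = 40, rng_seed = NULL, sigma = 1) {
  stopifnot(n_agents >= 2, box_side > 0)
  if (n_agents * pi * (sigma / 2)^2 / box_side^2 > 0.3)
    stop("infeasible density: packing fraction exceeds 0.3")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  pos <- matrix(NA_real_, n_agents, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n_agents) {
    cand <- runif(2, 0, box_side)
    ok <- placed == 0L ||
      min(sqrt(colSums((t(pos[seq_len(placed), , drop = FALSE]) - cand)^2))) >= sigma
    if (ok) {
      placed <- placed + 1L
      pos[placed, ] <- cand
    }
    tries <- tries + 1L
    if (tries > 1e5) stop("infeasible density: rejection sampling failed")
  }
  herd_frame(pos, runif(n_agents, 0, 2 * pi), 0L)
}

#' Advance the herd by one time step
#'
#' Applies one action per agent synchronously (kinematics first, using
#' fresh noise draws for every agent), then resolves overlaps globally,
#' and increments the time index.
#'
#' @param frame a [herd_frame()].
#' @param actions character or integer vector, one action per agent
#'   (integers index into `ACTIONS`).
#' @param params [kinematics_params()].
#' @param sigma body diameter.
#' @return the next [herd_frame()].
#' @export
step_herd <- function(frame, actions, params = kinematics_params(), sigma = 1) {
  n <- nrow(frame$positions)
  if (is.numeric(actions)) actions <- ACTIONS[actions]
  if (length(actions) != n) stop("need one action per agent")
  bad <- !actions %in% ACTIONS
  if (any(bad)) stop(sprintf("invalid action '%s'", actions[bad][1]))

  pos <- frame$positions
  th <- frame$headings
  nsd <- params$noise_sd
  ta <- params$turn_angle * pi / 180
  R <- params$turn_radius

  eta1 <- rnorm(n)
  eta2 <- rnorm(n)

  fw <- actions == "forward"
  if (any(fw)) {
    len <- params$step_length * (1 + nsd * eta1[fw])
    pos[fw, 1] <- pos[fw, 1] + len * cos(th[fw])
    pos[fw, 2] <- pos[fw, 2] + len * sin(th[fw])
    th[fw] <- th[fw] + nsd * ta * eta2[fw]
  }
  for (side in c("turn_left", "turn_right")) {
    tu <- actions == side
    if (!any(tu)) next
    sgn <- if (side == "turn_left") 1 else -1
    alpha <- sgn * ta * (1 + nsd * eta2[tu])
    C <- sgn * R
    lx <- C * sin(alpha)
    ly <- C * (1 - cos(alpha))
    pos[tu, 1] <- pos[tu, 1] + cos(th[tu]) * lx - sin(th[tu]) * ly
    pos[tu, 2] <- pos[tu, 2] + sin(th[tu]) * lx + cos(th[tu]) * ly
    th[tu] <- th[tu] + alpha
  }

  out <- herd_frame(pos, th, frame$time_index + 1L)
  resolve_overlaps(out, sigma = sigma)
}
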