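# Episode runner shared by training and frozen-policy rollouts: the
# observe -> policy -> sample -> step -> reward loop for all agents.
run_episode <- function(policy_fn, frame, n_steps, cfg, collect_obs = TRUE) {
  N <- nrow(frame$positions)
  S <- cfg$n_sectors
  kin <- kinematics_params(cfg$step_length, cfg$turn_radius,
                           cfg$turn_angle, cfg$noise_sd)
  rpar <- reward_params(cfg$c, cfg$d0, cfg$delta, cfg$w, cfg$sigma)
  half <- cfg$half_angle_deg * pi / 180

  obs_arr <- if (collect_obs) array(0, c(n_steps, N, S)) else NULL
  acts <- matrix(0L, n_steps, N)
  r_shh <- matrix(0, n_steps, N)
  r_prox <- matrix(0, n_steps, N)
  areas <- matrix(0, n_steps, N)
  nnd <- matrix(0, n_steps, N)
  posi <- array(0, c(n_steps, N, 2))
  head_ <- matrix(0, n_steps, N)

  for (t in seq_len(n_steps)) {
    O <- observe_all(frame, cfg$occlusion, half, S, cfg$sigma)
    a <- policy_fn(O, frame)
    frame <- step_herd(frame, a, kin, cfg$sigma)
    dod <- compute_dod(frame$positions, cfg$delta)
    rs <- reward_shh(dod$areas, rpar)
    rp <- reward_prox(dod$nn_distance, rpar)
    if (collect_obs) obs_arr[t, , ] <- O
    acts[t, ] <- a
    r_shh[t, ] <- rs
    r_prox[t, ] <- rp
    areas[t, ] <- dod$areas
    nnd[t, ] <- dod$nn_distance
    posi[t, , ] <- frame$positions
    head_[t, ] <- frame$headings
  }
  list(obs = obs_arr, actions = acts, r_shh = r_shh, r_prox = r_prox,
       rewards = r_shh + r_prox, areas = areas, nn_distance = nnd,
       positions = posi, headings = head_, final_frame = frame)
}

# wrap any accepted policy description into policy_fn(obs, frame) -> ids
as_policy_fn <- function(policy, model = NULL) {
  if (inherits(policy, "shh_policy")) {
    model <- policy$model
    function(O, frame) sample_action(policy_evaluate(model, O))
  } else if (inherits(policy, "actor_model")) {
    function(O, frame) sample_action(policy_evaluate(policy, O))
  } else if (is.function(policy)) {
    function(O, frame) {
      a <- policy(O, frame)
      if (is.character(a)) a <- match(a, ACTIONS)
      as.integer(a)
    }
  } else if (is.character(policy) && length(policy) == 1) {
    if (policy == "random") {
      function(O, frame) sample.int(4L, nrow(O), replace = TRUE)
    } else {
      id <- match(policy, ACTIONS)
      if (is.na(id)) stop(sprintf("invalid scripted action '%s'", policy))
      function(O, frame) rep(id, nrow(O))
    }
  } else stop("unsupported policy description")
}

#' Train a selfish-herd policy
#'
#' Fits the shared actor-critic policy by episodic advantage policy
#' gradient under the centralized-training, decentralized-execution
#' paradigm: every episode starts from a fresh random configuration, all
#' agents act under the current shared actor, and the pooled
#' (observable, action, reward) experience of the whole herd updates one
#' shared parameter set. Returns a fitted model object; see
#' [rollout()] / [simulate.shh_policy()] for frozen-policy simulation and
#' the analysis functions for the emergent statistics.
#'
#' @param config an [shh_config()]; its `seed` drives every source of
#'   randomness, so a run is fully reproducible from (config, seed).
#' @param init_model optional `actor_model` (or fitted `shh_policy`) to
#'   continue training from instead of a fresh initialization.
#' @param verbose print a one-line summary per episode.
#' @return object of class `shh_policy`: list with `model`
#'   (`actor_model`), `log` (per-episode data frame: mean reward, median
#'   domain-of-danger area, losses, entropy), `config`, and the final
#'   frame of the last episode.
#' @seealso [rollout()], [policy_evaluate()], [median_dod()]
#' @export
shh_train <- function(config = shh_config(), init_model = NULL,
                      verbose = FALSE) {
  validate_config(config)
  set.seed(config$seed)
  model <- if (is.null(init_model)) {
    actor_model(config$n_sectors, 4L, config$hidden)
  } else if (inherits(init_model, "shh_policy")) {
    init_model$model
  } else init_model
  N <- config$n_agents
  T_ <- config$steps_per_episode
  logs <- vector("list", config$n_episodes)

  for (ep in seq_len(config$n_episodes)) {
    frame <- init_episode(N, config$box_side, rng_seed = NULL,
                          sigma = config$sigma)
    pol <- function(O, frame) sample_action(policy_evaluate(model, O))
    epi <- run_episode(pol, frame, T_, config, collect_obs = TRUE)

    G <- discounted_returns(epi$rewards, config$gamma)
    X <- matrix(epi$obs, nrow = T_ * N)
    a <- as.vector(epi$actions)
    g <- as.vector(G)
    v <- value_evaluate(model, X)
    adv <- g - v
    if (config$normalize_advantage)
      adv <- (adv - mean(adv)) / (sd(adv) + 1e-8)

    n_tot <- length(a)
    aloss <- closs <- ent <- NA_real_
    for (epoch in seq_len(config$epochs_per_episode)) {
      idx <- sample.int(n_tot)
      starts <- seq(1L, n_tot, by = config$minibatch)
      for (s in starts) {
        take <- idx[s:min(s + config$minibatch - 1L, n_tot)]
        au <- actor_update(model, X[take, , drop = FALSE], a[take],
                           adv[take], config$lr, config$entropy_weight)
        model <- au$model
        cu <- critic_update(model, X[take, , drop = FALSE], g[take],
                            config$lr)
        model <- cu$model
        aloss <- au$loss; closs <- cu$loss; ent <- au$entropy
      }
    }
    logs[[ep]] <- data.frame(
      episode = ep,
      mean_reward = mean(epi$rewards),
      median_dod = median(epi$areas),
      final_median_dod = median(epi$areas[T_, ]),
      actor_loss = aloss, critic_loss = closs, entropy = ent)
    if (verbose)
      message(sprintf(
        "episode %2d  mean reward %7.4f  median DOD %8.2f  entropy %5.3f",
        ep, logs[[ep]]$mean_reward, logs[[ep]]$median_dod, ent))
  }
  structure(list(model = model, log = do.call(rbind, logs),
                 config = config, final_frame = epi$final_frame),
            class = "shh_policy")
}

#' Frozen-policy rollout
#'
#' Simulates the herd under a fixed policy (no learning) and records the
#' full trajectory: positions, headings, actions, reward components and
#' per-agent domain-of-danger areas at every step.
#'
#' @param policy a fitted `shh_policy`, a bare `actor_model`, a function
#'   `(obs_matrix, frame) -> action ids`, one action name for a scripted
#'   constant policy, or `"random"`.
#' @param n_steps number of steps.
#' @param config [shh_config()]; defaults to the policy's own config.
#' @param seed integer seed (`NULL`: continue the current RNG stream).
#' @param init optional initial [herd_frame()]; default: a fresh random
#'   configuration.
#' @return object of class `herd_trajectory` with arrays `positions`
#'   (T x N x 2), `headings`, `actions`, `r_shh`, `r_prox`, `reward`,
#'   `areas`, `nn_distance` (all T x N), plus `config` and `seed`.
#' @export
rollout <- function(policy, n_steps = NULL, config = NULL, seed = NULL,
                    init = NULL) {
  if (is.null(config))
    config <- if (inherits(policy, "shh_policy")) policy$config else shh_config()
  validate_config(config)
  if (is.null(n_steps)) n_steps <- config$steps_per_episode
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init))
    init <- init_episode(config$n_agents, config$box_side, rng_seed = NULL,
                         sigma = config$sigma)
  pol <- as_policy_fn(policy)
  epi <- run_episode(pol, init, n_steps, config, collect_obs = FALSE)
  structure(list(positions = epi$positions, headings = epi$headings,
                 actions = epi$actions, r_shh = epi$r_shh,
                 r_prox = epi$r_prox, reward = epi$rewards,
                 areas = epi$areas, nn_distance = epi$nn_distance,
                 config = config, seed = seed, init = init),
            class = "herd_trajectory")
}

#' Restrict a trajectory to a frame window
#'
#' Keeps frames `from:to` of every per-frame array — typically used to
#' drop the aggregation transient and analyse only the steady state.
#'
#' @param traj `herd_trajectory`.
#' @param from,to first and last frame to keep (1-based, inclusive).
#' @return a `herd_trajectory` over the window.
#' @export
window_trajectory <- function(traj, from, to = dim(traj$positions)[1]) {
  T_ <- dim(traj$positions)[1]
  stopifnot(from >= 1, to <= T_, from <= to)
  keep <- from:to
  out <- traj
  out$positions <- traj$positions[keep, , , drop = FALSE]
  for (f in c("headings", "actions", "r_shh", "r_prox", "reward",
              "areas", "nn_distance"))
    out[[f]] <- traj[[f]][keep, , drop = FALSE]
  out
}

#' @export
print.herd_trajectory <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("<herd_trajectory> %d frames x %d agents (config %s)\n",
              d[1], d[2], config_hash(x$config)))
  invisible(x)
}

#' @export
print.shh_policy <- function(x, ...) {
  cat("Selfish-herd policy (shared actor-critic)\n")
  cat(sprintf("  agents: %d   episodes: %d x %d steps   c = %.3f, d0 = %.2f\n",
              x$config$n_agents, nrow(x$log), x$config$steps_per_episode,
              x$config$c, x$config$d0))
  cat(sprintf("  mean reward: %.4f (first episode) -> %.4f (last)\n",
              x$log$mean_reward[1], tail(x$log$mean_reward, 1)))
  cat(sprintf("  median DOD at episode end:  %.1f -> %.1f sigma^2\n",
              x$log$final_median_dod[1], tail(x$log$final_median_dod, 1)))
  invisible(x)
}

#' @export
summary.shh_policy <- function(object, ...) {
  out <- list(config = object$config, log = object$log,
              n_parameters = length(coef(object)),
              reward_gain = tail(object$log$mean_reward, 1) -
                object$log$mean_reward[1])
  class(out) <- "summary.shh_policy"
  out
}

#' @export
print.summary.shh_policy <- function(x, ...) {
  cat("Selfish-herd policy fit\n")
  cat(sprintf("  %d trainable parameters; reward gain over training: %+.4f\n",
              x$n_parameters, x$reward_gain))
  print(x$log[, c("episode", "mean_reward", "median_dod", "entropy")],
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.shh_policy <- function(object, ...) {
  unlist(object$model$actor)
}

#' Action probabilities of a fitted policy
#'
#' @param object `shh_policy`.
#' @param newdata observable vector or matrix (5 sector crowdedness values
#'   per row).
#' @param type `"probs"` (default) for the action distribution,
#'   `"action"` for the most probable action name.
#' @param ... unused.
#' @export
predict.shh_policy <- function(object, newdata, type = c("probs", "action"),
                               ...) {
  type <- match.arg(type)
  P <- policy_evaluate(object$model, newdata)
  if (type == "probs") return(P)
  M <- if (is.null(dim(P))) matrix(P, 1) else P
  ACTIONS[max.col(M)]
}

#' Simulate trajectories from a fitted policy
#'
#' @param object `shh_policy`.
#' @param nsim number of independent rollouts.
#' @param seed integer seed for the first rollout (subsequent ones
#'   continue the stream).
#' @param n_steps steps per rollout (default: the training episode
#'   length).
#' @param ... unused.
#' @return a single `herd_trajectory` when `nsim = 1`, else a list of
#'   them.
#' @export
simulate.shh_policy <- function(object, nsim = 1, seed = NULL,
                                n_steps = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(i)
    rollout(object, n_steps = n_steps, config = object$config, seed = NULL))
  if (nsim == 1) out[[1]] else out
}

#' Plot training diagnostics
#'
#' Median domain-of-danger area (left axis) and mean reward (right axis)
#' per training episode -- the aggregation curve of the herd.
#'
#' @param x `shh_policy`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.shh_policy <- function(x, ...) {
  log <- x$log
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(log$episode, log$median_dod, type = "b", col = "blue",
                 xlab = "episode", ylab = expression(M[A] ~ (sigma^2)),
                 main = "aggregation during training", ...)
  graphics::par(new = TRUE)
  graphics::plot(log$episode, log$mean_reward, type = "b", col = "darkgreen",
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4, col.axis = "darkgreen")
  graphics::mtext("mean reward", side = 4, line = 2.5, col = "darkgreen")
  invisible(x)
}
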