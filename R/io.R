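#' Run configuration
#'
#' One flat, validated container for every simulation, perception, reward
#' and training parameter. Defaults are the study conditions of the herd
#' task: 100 agents, cutoff delta = 10 sigma, step 0.25 sigma, turn radius
#' 0.8 sigma, 18 degrees per turn, 20% action noise, reward weights
#' c = 0.375 with d0 = 1 sigma (strongly rotating regime; set d0 = 1.5 for
#' the weakly rotating one), episodes of 3000 steps, 30 training episodes.
#'
#' @param ... named parameters overriding the defaults; unknown names are
#'   rejected.
#' @return validated list of class `shh_config`.
#' @export
shh_config <- function(...) {
  defaults <- list(
    # herd / environment
    n_agents = 100L, box_side = 40, sigma = 1,
    step_length = 0.25, turn_radius = 0.8, turn_angle = 18, noise_sd = 0.2,
    # perception
    occlusion = TRUE, half_angle_deg = 90, n_sectors = 5L,
    # reward
    c = 0.375, d0 = 1.0, delta = 10, w = 2,
    # training schedule and optimizer
    steps_per_episode = 3000L, n_episodes = 30L,
    gamma = 0.99, lr = 3e-4, entropy_weight = 0.03,
    epochs_per_episode = 2L, minibatch = 1024L, normalize_advantage = TRUE,
    hidden = c(64L, 64L),
    # analysis
    order_form = "signed",
    # reproducibility
    seed = 1L
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- modifyList(defaults, over)
  validate_config(cfg)
  structure(cfg, class = "shh_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("config: ", msg, call. = FALSE)
  chk(cfg$n_agents >= 2, "n_agents must be >= 2")
  chk(cfg$box_side > 0, "box_side must be positive")
  chk(cfg$sigma > 0, "sigma must be positive")
  chk(cfg$step_length > 0, "step_length must be positive")
  chk(cfg$turn_radius > 0, "turn_radius must be positive")
  chk(cfg$turn_angle > 0, "turn_angle must be positive")
  chk(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  chk(cfg$half_angle_deg > 0 && cfg$half_angle_deg <= 180,
      "half_angle_deg must be in (0, 180]")
  chk(cfg$n_sectors >= 1, "n_sectors must be >= 1")
  chk(cfg$c >= 0, "c must be >= 0")
  chk(cfg$d0 > 0, "d0 must be positive")
  chk(cfg$delta > cfg$d0, "delta must exceed d0")
  chk(cfg$w > 0, "w must be positive")
  chk(cfg$steps_per_episode >= 1, "steps_per_episode must be >= 1")
  chk(cfg$n_episodes >= 1, "n_episodes must be >= 1")
  chk(cfg$gamma >= 0 && cfg$gamma < 1, "gamma must be in [0, 1)")
  chk(cfg$lr >= 0, "lr must be >= 0")
  chk(cfg$entropy_weight >= 0, "entropy_weight must be >= 0")
  chk(cfg$epochs_per_episode >= 1, "epochs_per_episode must be >= 1")
  chk(cfg$minibatch >= 1, "minibatch must be >= 1")
  chk(all(cfg$hidden >= 1), "hidden widths must be >= 1")
  chk(cfg$order_form %in% c("signed", "absolute"),
      "order_form must be 'signed' or 'absolute'")
  invisible(cfg)
}

#' Load a run configuration from a YAML file
#'
#' Unknown keys and out-of-range values are rejected with descriptive
#' errors; unspecified keys take their defaults. An empty file yields the
#' all-defaults configuration.
#'
#' @param path YAML file.
#' @return `shh_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(shh_config, vals)
}

#' Save a run configuration as YAML
#' @param config `shh_config`.
#' @param path output file.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Provenance hash of a configuration
#'
#' Polynomial rolling hash over the canonical JSON serialization, embedded
#' in every artifact (trajectory, model, analysis table) so that each can
#' be traced to its exact configuration and seed.
#'
#' @param config `shh_config` (or any serializable list).
#' @return 8-hex-digit character scalar.
#' @export
config_hash <- function(config) {
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(txt))
  # polynomial rolling hash mod the Mersenne prime 2^31 - 1 (exact in
  # double arithmetic)
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write / read a trajectory container
#'
#' The container is an RDS file holding all arrays (positions, headings,
#' actions, rewards, domain-of-danger areas), the configuration, its hash
#' and a schema version; the round trip is lossless. For interchange see
#' [export_trajectory_csv()] and [export_trajectory_xyz()].
#'
#' @param traj `herd_trajectory` from [rollout()].
#' @param path output file.
#' @export
write_trajectory <- function(traj, path) {
  payload <- list(container = "selfherd_trajectory", version = 1L,
                  hash = config_hash(traj$config), traj = unclass(traj))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @return `read_trajectory` returns the `herd_trajectory`.
#' @export
read_trajectory <- function(path) {
  payload <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    stop(sprintf("truncated or unreadable trajectory file: %s", path)))
  if (!identical(payload$container, "selfherd_trajectory"))
    stop("not a selfherd trajectory container")
  if (!identical(payload$version, 1L))
    stop(sprintf("trajectory container version mismatch: %s", payload$version))
  structure(payload$traj, class = "herd_trajectory")
}

#' Export a trajectory as a tidy CSV
#'
#' One row per (frame, agent): t, agent, x, y, theta, action, r_shh,
#' r_prox, area.
#'
#' @param traj `herd_trajectory`.
#' @param path output CSV.
#' @export
export_trajectory_csv <- function(traj, path) {
  T_ <- dim(traj$positions)[1]
  N <- dim(traj$positions)[2]
  df <- data.frame(
    t = rep(seq_len(T_), each = N),
    agent = rep(seq_len(N), T_),
    x = as.numeric(t(traj$positions[, , 1])),
    y = as.numeric(t(traj$positions[, , 2])),
    theta = as.numeric(t(traj$headings)),
    action = ACTIONS[as.numeric(t(traj$actions))],
    r_shh = as.numeric(t(traj$r_shh)),
    r_prox = as.numeric(t(traj$r_prox)),
    area = as.numeric(t(traj$areas))
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a trajectory as an XYZ-style frame dump
#'
#' Plain-text multi-frame dump readable by standard particle viewers:
#' per frame, a count line, a comment line with the time index, then one
#' `A x y theta` line per agent.
#'
#' @param traj `herd_trajectory`.
#' @param path output file.
#' @export
export_trajectory_xyz <- function(traj, path) {
  T_ <- dim(traj$positions)[1]
  N <- dim(traj$positions)[2]
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(T_)) {
    writeLines(as.character(N), con)
    writeLines(sprintf("frame %d", t), con)
    writeLines(sprintf("A %.8f %.8f %.8f", traj$positions[t, , 1],
                       traj$positions[t, , 2], traj$headings[t, ]), con)
  }
  invisible(path)
}

#' Save / load a fitted policy
#'
#' RDS parameter container with the embedded configuration hash.
#'
#' @param object fitted `shh_policy` from [shh_train()] (or a bare
#'   `actor_model`).
#' @param path file path.
#' @export
write_policy <- function(object, path) {
  payload <- list(container = "selfherd_policy", version = 1L,
                  hash = if (inherits(object, "shh_policy"))
                    config_hash(object$config) else NA_character_,
                  object = object)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_policy
#' @export
read_policy <- function(path) {
  payload <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    stop(sprintf("truncated or unreadable policy file: %s", path)))
  if (!identical(payload$container, "selfherd_policy"))
    stop("not a selfherd policy container")
  payload$object
}
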