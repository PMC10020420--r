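#' Reward parameters
#'
#' The per-step reward of an agent is `r = r_SHH(A) + r_prox(d)`:
#' a selfish-herd term decreasing linearly from 1 to 0 as the domain of
#' danger A grows from the agent's own disk area `A_min = pi*(sigma/2)^2`
#' to the cutoff maximum `A_max = pi*delta^2`, plus a smooth proximity
#' penalty `-c * (1 - tanh((d - d0)/w))` on the nearest-neighbour distance
#' d, mimicking collision avoidance.
#'
#' @param c weight of the proximity penalty (default 0.375).
#' @param d0 proximity threshold in sigma (1.0 gives a strongly rotating
#'   group, 1.5 a weakly rotating group; default 1.0).
#' @param delta domain-of-danger cutoff radius, sigma (default 10).
#' @param w crossover width of the tanh penalty, sigma (default 2).
#' @param sigma body diameter (the length unit).
#' @return list of class `reward_params` with derived `a_min`, `a_max`.
#' @export
reward_params <- function(c = 0.375, d0 = 1.0, delta = 10, w = 2, sigma = 1) {
  stopifnot(c >= 0, d0 > 0, delta > d0, w > 0, sigma > 0)
  structure(list(c = c, d0 = d0, delta = delta, w = w, sigma = sigma,
                 a_min = pi * (sigma / 2)^2, a_max = pi * delta^2),
            class = "reward_params")
}

#' Selfish-herd reward of a domain-of-danger area
#'
#' `r_SHH(A) = (A_max - A) / (A_max - A_min)`, equal to 1 at the agent's
#' own disk area and 0 at the cutoff maximum. Areas transiently below
#' `A_min` (overlapping disks mid-resolution) are clipped to reward 1.
#'
#' @param area numeric vector of DOD areas, sigma^2.
#' @param params [reward_params()].
#' @return numeric vector in `[0, 1]`.
#' @export
reward_shh <- function(area, params = reward_params()) {
  if (any(area <= 0)) stop("invalid area: must be positive")
  if (any(area > params$a_max + 1e-9))
    stop("invalid area: exceeds the cutoff maximum pi*delta^2")
  pmin(1, pmax(0, (params$a_max - area) / (params$a_max - params$a_min)))
}

#' Proximity penalty of a nearest-neighbour distance
#'
#' `r_prox(d) = -c * (1 - tanh((d - d0)/w))`: a step-like penalty with a
#' smooth crossover at d0, equal to -c at d = d0 and vanishing for
#' d >> d0.
#'
#' @param d numeric vector of nearest-neighbour distances, sigma.
#' @param params [reward_params()].
#' @return numeric vector in `[-2c, 0]`.
#' @export
reward_prox <- function(d, params = reward_params()) {
  if (any(d <= 0)) stop("invalid distance: must be positive")
  -params$c * (1 - tanh((d - params$d0) / params$w))
}

#' Combined per-agent reward
#'
#' @param areas per-agent DOD areas, sigma^2.
#' @param nn_distances per-agent nearest-neighbour distances, sigma.
#' @param params [reward_params()].
#' @return data frame with columns `r_shh`, `r_prox`, `total` (one row per
#'   agent); attribute `"mean_total"` carries the ensemble mean reward.
#' @export
reward_total <- function(areas, nn_distances, params = reward_params()) {
  if (length(areas) != length(nn_distances))
    stop("`areas` and `nn_distances` must be aligned per agent")
  rs <- reward_shh(areas, params)
  rp <- reward_prox(nn_distances, params)
  out <- data.frame(r_shh = rs, r_prox = rp, total = rs + rp)
  attr(out, "mean_total") <- mean(out$total)
  out
}
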