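#' Vision-cone observable of one agent
#'
#' Each agent perceives a 180-degree forward cone divided into five equal
#' 36-degree sectors, ordered left (most counter-clockwise) to right. Every
#' visible neighbour j contributes `sigma / |r_ij|` -- inverse-distance
#' crowdedness -- to the sector containing the bearing of its centre.
#' Neighbours exactly on a sector boundary fall into the lower-index (more
#' counter-clockwise) sector; bearings of exactly +/-90 degrees are inside
#' the cone. With `occlusion = TRUE` a neighbour is invisible whenever the
#' sight line from the observer's centre to its centre passes within
#' sigma/2 of a nearer agent's centre (binary full-disk sight blocking).
#'
#' @param frame a [herd_frame()].
#' @param agent_index which agent observes (1-based).
#' @param occlusion logical; apply sight blocking (default TRUE).
#' @param half_angle half-opening of the cone in radians (default pi/2).
#' @param n_sectors number of sectors (default 5).
#' @param sigma body diameter.
#' @return numeric vector of length `n_sectors`, all entries >= 0.
#' @export
observe <- function(frame, agent_index, occlusion = TRUE,
                    half_angle = pi / 2, n_sectors = 5L, sigma = 1) {
  n <- nrow(frame$positions)
  if (agent_index < 1 || agent_index > n) stop("invalid agent index")
  observe_all(frame, occlusion, half_angle, n_sectors, sigma)[agent_index, ]
}

#' Vision-cone observables of all agents
#'
#' Vectorized form of [observe()]: one row per agent.
#'
#' @inheritParams observe
#' @return numeric matrix, N x `n_sectors`.
#' @export
observe_all <- function(frame, occlusion = TRUE, half_angle = pi / 2,
                        n_sectors = 5L, sigma = 1) {
  .observe_all_cpp(frame$positions, frame$headings, occlusion,
                   half_angle, as.integer(n_sectors), sigma)
}
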