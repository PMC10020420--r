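# Trajectory statistics of the non-equilibrium steady state: mean squared
# displacement, rotational order (global and spatially resolved), median
# and cumulative domain-of-danger areas, DOD autocorrelation, and
# neighbour persistence.

lag_series <- function(lags, ensemble, per_agent = NULL, kind = "lag_series") {
  structure(list(lags = lags, ensemble = ensemble, per_agent = per_agent,
                 kind = kind),
            class = "lag_series")
}

#' @export
print.lag_series <- function(x, ...) {
  cat(sprintf("<lag_series:%s> %d lags [%g .. %g]\n", x$kind, length(x$lags),
              min(x$lags), max(x$lags)))
  invisible(x)
}

#' @export
as.data.frame.lag_series <- function(x, ...) {
  out <- data.frame(lag = x$lags, value = x$ensemble, series = "ensemble")
  if (!is.null(x$per_agent)) {
    pa <- data.frame(lag = rep(x$lags, ncol(x$per_agent)),
                     value = as.numeric(x$per_agent),
                     series = rep(sprintf("agent_%d", seq_len(ncol(x$per_agent))),
                                  each = length(x$lags)))
    out <- rbind(out, pa)
  }
  out
}

default_lags <- function(T_, n_max = 120L) {
  lags <- unique(round(exp(seq(0, log(T_ - 1), length.out = n_max))))
  lags[lags >= 1 & lags <= T_ - 1]
}

#' Mean squared displacement
#'
#' `MSD_i(tau)` is the time average over start times t of
#' `|x_i(t + tau) - x_i(t)|^2`; the ensemble curve averages over agents.
#' With `subtract_com = TRUE` (default) the per-frame group centroid is
#' subtracted first, removing the slight drift of the centre of mass so
#' that the intra-group motion (orbital oscillations, saturation at the
#' group size) is visible.
#'
#' @param traj `herd_trajectory`.
#' @param subtract_com subtract the per-frame centroid.
#' @param lags integer lags to evaluate (default: log-spaced).
#' @return [lag_series] with per-agent matrix and ensemble mean.
#' @export
msd <- function(traj, subtract_com = TRUE, lags = NULL) {
  pos <- traj$positions
  T_ <- dim(pos)[1]
  if (T_ < 2) stop("need at least 2 frames for an MSD")
  if (is.null(lags)) lags <- default_lags(T_)
  lags <- lags[lags < T_]
  if (subtract_com) {
    cx <- rowMeans(pos[, , 1, drop = FALSE])
    cy <- rowMeans(pos[, , 2, drop = FALSE])
    pos[, , 1] <- pos[, , 1] - cx
    pos[, , 2] <- pos[, , 2] - cy
  }
  per <- matrix(NA_real_, length(lags), dim(pos)[2])
  for (k in seq_along(lags)) {
    tau <- lags[k]
    dx <- pos[(tau + 1):T_, , 1, drop = FALSE] - pos[1:(T_ - tau), , 1, drop = FALSE]
    dy <- pos[(tau + 1):T_, , 2, drop = FALSE] - pos[1:(T_ - tau), , 2, drop = FALSE]
    per[k, ] <- colMeans(matrix(dx^2 + dy^2, ncol = dim(pos)[2]))
  }
  lag_series(lags, rowMeans(per), per, "msd")
}

#' Rotational order parameter
#'
#' For each agent let `rhat_i` be the unit vector from the group centroid
#' to the agent and `uhat_i` its heading. The default (`form = "signed"`)
#' order parameter is `O_R = |sum_i (rhat_i x uhat_i)_z| / N`: 1 for a
#' perfect single mill, 0 for mixed handedness or disordered headings.
#' `form = "absolute"` instead averages `|rhat_i x uhat_i|` per agent; it
#' is chirality-insensitive and has baseline 2/pi for random headings, so
#' the signed form is the default for quantifying net group rotation.
#' Agents closer than 1e-9 to the centroid are excluded.
#'
#' @param frame a [herd_frame()], or a `herd_trajectory` (then a per-frame
#'   vector is returned).
#' @param form `"signed"` (default) or `"absolute"`.
#' @return scalar in `[0, 1]` (or a per-frame vector for trajectories).
#' @export
rotational_order <- function(frame, form = c("signed", "absolute")) {
  form <- match.arg(form)
  if (inherits(frame, "herd_trajectory")) {
    T_ <- dim(frame$positions)[1]
    return(vapply(seq_len(T_), function(t)
      rotational_order_xy(frame$positions[t, , ], frame$headings[t, ], form),
      numeric(1)))
  }
  rotational_order_xy(frame$positions, frame$headings, form)
}

rotational_order_xy <- function(pos, headings, form) {
  rel <- sweep(pos, 2, colMeans(pos))
  rn <- sqrt(rowSums(rel^2))
  keep <- rn > 1e-9
  if (!any(keep)) stop("rotational order undefined: all agents at the centroid")
  cr <- (rel[keep, 1] * sin(headings[keep]) -
           rel[keep, 2] * cos(headings[keep])) / rn[keep]
  if (form == "signed") abs(mean(cr)) else mean(abs(cr))
}

#' Spatially resolved rotational order map
#'
#' Grids the centroid-centred plane into square cells of side
#' `grid_spacing` and averages the signed cross product
#' `(rhat_i x uhat_i)_z` over all agent visits within the window, giving a
#' vorticity-like field: a single mill shows one same-sign core, two
#' counter-rotating vortices show opposite-sign lobes.
#'
#' @param traj `herd_trajectory`.
#' @param grid_spacing cell side, sigma.
#' @param window frames to use (integer count from the end of the
#'   trajectory; default all).
#' @param min_visits cells with fewer agent-visits are reported `NA`.
#' @return data frame of class `rotation_map`: cell centres `x`, `y`,
#'   mean signed cross product `value`, visit count `n`.
#' @export
spatial_rotation_map <- function(traj, grid_spacing = 1, window = NULL,
                                 min_visits = 5L) {
  T_ <- dim(traj$positions)[1]
  if (is.null(window)) window <- T_
  if (window < 1 || window > T_) stop("empty or invalid window")
  ts <- (T_ - window + 1):T_
  xs <- ys <- vs <- numeric(0)
  for (t in ts) {
    pos <- traj$positions[t, , ]
    rel <- sweep(pos, 2, colMeans(pos))
    rn <- sqrt(rowSums(rel^2))
    keep <- rn > 1e-9
    cr <- (rel[keep, 1] * sin(traj$headings[t, keep]) -
             rel[keep, 2] * cos(traj$headings[t, keep])) / rn[keep]
    xs <- c(xs, rel[keep, 1]); ys <- c(ys, rel[keep, 2]); vs <- c(vs, cr)
  }
  ix <- floor(xs / grid_spacing)
  iy <- floor(ys / grid_spacing)
  key <- paste(ix, iy)
  agg_n <- tapply(vs, key, length)
  agg_m <- tapply(vs, key, mean)
  ij <- do.call(rbind, strsplit(names(agg_n), " "))
  out <- data.frame(
    x = (as.numeric(ij[, 1]) + 0.5) * grid_spacing,
    y = (as.numeric(ij[, 2]) + 0.5) * grid_spacing,
    value = ifelse(agg_n >= min_visits, agg_m, NA_real_),
    n = as.integer(agg_n), row.names = NULL)
  class(out) <- c("rotation_map", "data.frame")
  out
}

#' Median domain-of-danger and mean-reward time series
#'
#' @param traj `herd_trajectory`.
#' @return data frame: `t`, `median_area`, `mean_reward`.
#' @export
median_dod <- function(traj) {
  data.frame(t = seq_len(nrow(traj$areas)),
             median_area = apply(traj$areas, 1, median),
             mean_reward = rowMeans(traj$reward))
}

#' Cumulative averaged domain of danger
#'
#' `Abar_i(tau) = (1/tau) * sum_(t<=tau) A_i(t)`: the running time average
#' of each agent's DOD. In the steady state the curves of all agents
#' converge to the ensemble mean -- the risk-sharing result.
#'
#' @param traj `herd_trajectory`.
#' @return [lag_series] (`lags` = tau in steps starting at 1, per-agent
#'   matrix, ensemble mean over agents).
#' @export
cumulative_dod <- function(traj) {
  A <- traj$areas
  per <- apply(A, 2, cumsum) / seq_len(nrow(A))
  lag_series(seq_len(nrow(A)), rowMeans(per), per, "cumdod")
}

#' Distribution of cumulative DOD across agents
#'
#' Histogram of `{Abar_i(tau)}` at each requested tau, normalized so the
#' probabilities over agents sum to one per tau.
#'
#' @param traj `herd_trajectory`.
#' @param taus averaging intervals (steps).
#' @param breaks number of area bins (shared across taus).
#' @return data frame: `tau`, bin centre `area`, probability `p`.
#' @export
cumulative_dod_distribution <- function(traj, taus, breaks = 30L) {
  cd <- cumulative_dod(traj)
  taus <- taus[taus %in% cd$lags]
  rng <- range(cd$per_agent[taus, ])
  bks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = breaks + 1L)
  mids <- (bks[-1] + bks[-length(bks)]) / 2
  out <- lapply(taus, function(tau) {
    h <- graphics::hist(cd$per_agent[tau, ], breaks = bks, plot = FALSE)
    data.frame(tau = tau, area = mids, p = h$counts / sum(h$counts))
  })
  do.call(rbind, out)
}

#' Ensemble-averaged autocorrelation of the domain of danger
#'
#' Per agent, the mean-removed, variance-normalized autocorrelation of
#' `A_i(t)` over the observation window; the ensemble curve averages the
#' per-agent functions, so `ACF(0) = 1`. Agents with zero variance are
#' excluded with a warning.
#'
#' @param traj `herd_trajectory`.
#' @param max_lag largest lag (default: half the window).
#' @return [lag_series] starting at lag 0.
#' @export
dod_acf <- function(traj, max_lag = NULL) {
  A <- traj$areas
  T_ <- nrow(A)
  if (is.null(max_lag)) max_lag <- floor(T_ / 2)
  max_lag <- min(max_lag, T_ - 1L)
  v <- apply(A, 2, stats::var)
  keep <- which(v > 1e-24)
  if (!length(keep)) stop("all agents have zero DOD variance")
  if (length(keep) < ncol(A))
    warning(sprintf("%d zero-variance agent(s) excluded from the ACF",
                    ncol(A) - length(keep)))
  per <- vapply(keep, function(i)
    as.numeric(stats::acf(A[, i], lag.max = max_lag, plot = FALSE,
                          demean = TRUE)$acf),
    numeric(max_lag + 1L))
  lag_series(0:max_lag, rowMeans(per), per, "acf")
}

#' Correlation time of a lag series
#'
#' The smallest lag at which the ensemble curve first drops below `1/e`.
#'
#' @param ls [lag_series] (typically from [dod_acf()]).
#' @return lag in steps; `Inf` when the curve never drops below `1/e`.
#' @export
correlation_time <- function(ls) {
  below <- which(ls$ensemble < exp(-1))
  if (!length(below)) return(Inf)
  ls$lags[below[1]]
}

#' Neighbour persistence probability
#'
#' `p_NN(tau)`: the probability, averaged over agents and reference times,
#' that a current within-cutoff Voronoi neighbour is still a neighbour
#' after lag tau -- the neighbour-mixing (ergodicity) measure of the
#' steady state. `p_NN(0) = 1` by construction. Agents with an empty
#' neighbour set at a reference time are excluded from that reference.
#'
#' @param traj `herd_trajectory`.
#' @param lags integer lags (default log-spaced).
#' @param n_ref number of reference times (evenly spaced; default up to
#'   40).
#' @return [lag_series].
#' @export
neighbor_persistence <- function(traj, lags = NULL, n_ref = 40L) {
  T_ <- dim(traj$positions)[1]
  if (is.null(lags)) lags <- c(0L, default_lags(T_))
  lags <- sort(unique(lags[lags >= 0 & lags < T_]))
  need <- sort(unique(as.vector(outer(
    round(seq(1, max(1, T_ - max(lags[lags > 0], 1)), length.out = n_ref)),
    lags, `+`))))
  need <- need[need >= 1 & need <= T_]
  adj <- new.env()
  get_adj <- function(t) {
    key <- as.character(t)
    if (is.null(adj[[key]]))
      adj[[key]] <- compute_dod(traj$positions[t, , ],
                                traj$config$delta)$adjacency
    adj[[key]]
  }
  refs <- round(seq(1, max(1, T_ - max(lags[lags > 0], 1)), length.out = n_ref))
  refs <- unique(refs)
  vals <- vapply(lags, function(tau) {
    fr <- 0; cnt <- 0
    for (t in refs) {
      if (t + tau > T_) next
      A0 <- get_adj(t)
      A1 <- get_adj(t + tau)
      deg <- rowSums(A0)
      keepi <- deg > 0
      if (!any(keepi)) next
      overlap <- rowSums(A0 & A1)[keepi] / deg[keepi]
      fr <- fr + sum(overlap)
      cnt <- cnt + sum(keepi)
    }
    if (cnt == 0) NA_real_ else fr / cnt
  }, numeric(1))
  lag_series(lags, vals, NULL, "pnn")
}

#' Convergence lag of the cumulative DOD
#'
#' The smallest tau beyond which every agent's cumulative average stays
#' within `tol` (relative) of the ensemble mean -- the time scale on which
#' predation risk equalizes across the herd.
#'
#' @param cd [lag_series] from [cumulative_dod()].
#' @param tol relative tolerance (default 0.10).
#' @return lag in steps (`Inf` if never reached).
#' @export
cumdod_convergence_lag <- function(cd, tol = 0.10) {
  dev <- abs(sweep(cd$per_agent, 1, cd$ensemble) /
               pmax(cd$ensemble, 1e-12))
  worst <- apply(dev, 1, max)
  ok <- rev(cummax(rev(worst))) <= tol
  if (!any(ok)) return(Inf)
  cd$lags[which(ok)[1]]
}

#' Relative spread of cumulative DOD across agents
#'
#' Interquartile range of `{Abar_i(tau)}` divided by the ensemble mean,
#' per tau.
#'
#' @param cd [lag_series] from [cumulative_dod()].
#' @return numeric vector aligned with `cd$lags`.
#' @export
risk_spread <- function(cd) {
  iqr <- apply(cd$per_agent, 1, function(x) diff(quantile(x, c(0.25, 0.75))))
  as.numeric(iqr / pmax(cd$ensemble, 1e-12))
}

#' Saturation onset of the MSD
#'
#' The plateau is the mean ensemble MSD over the last decade of lags; the
#' onset is the smallest lag reaching `frac` of it.
#'
#' @param ms [lag_series] from [msd()].
#' @param frac plateau fraction (default 0.95).
#' @return lag in steps (`Inf` if never reached).
#' @export
msd_saturation_lag <- function(ms, frac = 0.95) {
  lmax <- max(ms$lags)
  plateau <- mean(ms$ensemble[ms$lags > lmax / 10])
  hit <- which(ms$ensemble >= frac * plateau)
  if (!length(hit)) return(Inf)
  ms$lags[hit[1]]
}
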