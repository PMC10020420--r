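# scripted trajectory builders -------------------------------------------

# agents moving with constant per-step velocity rows of `vel`
ballistic_traj <- function(pos0, vel, n_steps, headings = NULL) {
  if (is.null(headings)) headings <- atan2(vel[, 2], vel[, 1])
  frames <- lapply(seq_len(n_steps), function(t)
    herd_frame(pos0 + (t - 1) * vel, headings, t - 1L))
  trajectory_from_frames(frames, shh_config(n_agents = max(2L, nrow(pos0))))
}

test_that("MSD reproduces closed forms", {
  still <- make_fixture("ring", n_agents = 8, n_frames = 30, omega = 0)
  ms <- msd(still, subtract_com = FALSE, lags = 1:20)
  expect_true(all(abs(ms$ensemble) < 1e-18))
  # ballistic pair moving apart at speed v each: with COM subtraction the
  # centre of mass is static and each agent keeps speed v
  v <- 0.25
  tr <- ballistic_traj(rbind(c(0, 0), c(5, 0)), rbind(c(-v, 0), c(v, 0)), 60)
  for (sub in c(TRUE, FALSE)) {
    ms <- msd(tr, subtract_com = sub, lags = c(1, 5, 10, 20))
    expect_equal(ms$ensemble, (v * c(1, 5, 10, 20))^2, tolerance = 1e-9)
  }
  # a rigid drift added to every agent is removed by COM subtraction
  tr2 <- ballistic_traj(rbind(c(0, 0), c(5, 0)),
                        rbind(c(-v, 0), c(v, 0)) + c(0.3, 0.3, -0.1, -0.1), 60)
  ms2 <- msd(tr2, subtract_com = TRUE, lags = c(1, 5, 10, 20))
  expect_equal(ms2$ensemble, (v * c(1, 5, 10, 20))^2, tolerance = 1e-9)
})

test_that("rotational order separates mills, mixed rings and random headings", {
  mill <- make_fixture("mill", n_agents = 24)
  expect_equal(rotational_order(mill), 1, tolerance = 1e-12)
  mixed <- make_fixture("ring", n_agents = 24, handedness = "mixed")
  expect_equal(rotational_order(mixed), 0, tolerance = 1e-12)
  set.seed(17)
  big <- herd_frame(10 * cbind(cos(runif(1e4, 0, 2 * pi)),
                               sin(runif(1e4, 0, 2 * pi))) +
                      matrix(runif(2e4, -1, 1), ncol = 2),
                    runif(1e4, 0, 2 * pi))
  expect_lt(rotational_order(big), 0.03)
  # chirality-blind: a mirror image has the same magnitude
  mirr <- herd_frame(cbind(mill$positions[, 1], -mill$positions[, 2]),
                     (-mill$headings) %% (2 * pi))
  expect_equal(rotational_order(mirr), rotational_order(mill),
               tolerance = 1e-12)
  # printed per-agent-absolute variant: baseline 2/pi for random headings
  expect_equal(rotational_order(big, form = "absolute"), 2 / pi,
               tolerance = 0.02)
  expect_error(rotational_order(herd_frame(matrix(0.0, 2, 2) + 1e-12,
                                           c(0, 0))), "centroid|coincident|degenerate")
})

test_that("the spatial rotation map resolves vortex structure", {
  mill <- make_fixture("mill", n_agents = 60, n_frames = 40, omega = 0.1,
                       spacing = 2)
  mp <- spatial_rotation_map(mill, grid_spacing = 2, min_visits = 3L)
  occ <- mp$value[!is.na(mp$value)]
  expect_true(all(occ > 0))        # one handedness everywhere
  rim <- mp[!is.na(mp$value) & sqrt(mp$x^2 + mp$y^2) > 6, ]
  expect_true(all(rim$value > 0.9))
  tv <- make_fixture("two_vortex", n_agents = 60, n_frames = 40,
                     omega = 0.1, spacing = 2)
  expect_lt(rotational_order(tv$init), 0.05)
  mp2 <- spatial_rotation_map(tv, grid_spacing = 3, min_visits = 3L)
  occ2 <- mp2$value[!is.na(mp2$value)]
  # opposite-sign lobes, mirror antisymmetric between the two cores
  expect_gt(mean(occ2 > 0.5), 0.25)
  expect_gt(mean(occ2 < -0.5), 0.25)
  left <- mp2$value[mp2$x < 0 & !is.na(mp2$value)]
  right <- mp2$value[mp2$x > 0 & !is.na(mp2$value)]
  expect_gt(mean(left), 0.2)
  expect_lt(mean(right), -0.2)
  # static gas: no systematic rotation anywhere
  gas <- make_fixture("gas", n_agents = 40, n_frames = 30, seed = 2)
  mp3 <- spatial_rotation_map(gas, grid_spacing = 4, min_visits = 5L)
  expect_lt(abs(mean(mp3$value, na.rm = TRUE)), 0.2)
})

test_that("median DOD and cumulative DOD match brute-force oracles", {
  gas <- make_fixture("gas", n_agents = 15, n_frames = 12, seed = 3)
  md <- median_dod(gas)
  expect_equal(md$median_area,
               apply(gas$areas, 1, function(x) sort(x)[8]))
  expect_equal(md$mean_reward, rowMeans(gas$reward))
  expect_equal(median(c(1, 2, 100)), 2)  # robustness convention used above
  cd <- cumulative_dod(gas)
  # prefix-sum oracle
  for (i in c(1, 7, 15))
    expect_equal(cd$per_agent[, i],
                 cumsum(gas$areas[, i]) / seq_len(12), tolerance = 1e-12)
  # constant and alternating closed forms
  cA <- matrix(5, 10, 2); cA[seq(2, 10, 2), 2] <- 7
  fake <- gas; fake$areas <- cbind(rep(3, 10), rep(c(5, 7), 5))
  cd2 <- cumulative_dod(fake)
  expect_true(all(abs(cd2$per_agent[, 1] - 3) < 1e-12))
  expect_equal(cd2$per_agent[seq(2, 10, 2), 2], rep(6, 5))
})

test_that("the DOD autocorrelation is normalized and matches closed forms", {
  gas <- make_fixture("gas", n_agents = 10, n_frames = 50, seed = 4)
  ac <- dod_acf(gas)
  expect_equal(ac$ensemble[1], 1)
  # sinusoidal areas: ACF(tau) ~ cos(2 pi tau / P)
  P <- 25; T_ <- 500
  fake <- gas
  fake$areas <- sapply(1:10, function(i)
    10 + sin(2 * pi * (1:T_) / P + i))
  fake$positions <- array(0, c(T_, 10, 2))  # unused by the ACF
  ac2 <- dod_acf(fake, max_lag = 50)
  expect_equal(ac2$ensemble, cos(2 * pi * (0:50) / P), tolerance = 0.06)
  # white noise: beyond lag 0 everything inside the 3/sqrt(T) band
  set.seed(6)
  fake$areas <- matrix(rnorm(T_ * 10, 100, 5), T_, 10)
  ac3 <- dod_acf(fake, max_lag = 40)
  expect_true(all(abs(ac3$ensemble[-1]) < 3 / sqrt(T_)))
  # zero-variance agents are excluded with a warning; all-constant errors
  fake2 <- gas
  fake2$areas[, 1] <- 42
  expect_warning(dod_acf(fake2), "zero-variance")
  fake3 <- gas
  fake3$areas[] <- 42
  expect_error(dod_acf(fake3), "zero")
})

test_that("neighbour persistence is 1 for frozen herds and chance-level for re-scattered ones", {
  frozen <- make_fixture("ring", n_agents = 15, n_frames = 25, omega = 0)
  pn <- neighbor_persistence(frozen, lags = c(0L, 5L, 20L))
  expect_equal(pn$ensemble, rep(1, 3))
  # independent re-scattering each frame: p_NN(tau>0) equals the mean
  # chance adjacency overlap, estimated by a permutation oracle
  gas <- make_fixture("gas", n_agents = 20, n_frames = 40, seed = 8)
  pn2 <- neighbor_persistence(gas, lags = c(0L, 3L, 11L), n_ref = 25L)
  expect_equal(pn2$ensemble[1], 1)
  perm <- replicate(300, {
    t1 <- sample(40, 2)
    a0 <- compute_dod(gas$positions[t1[1], , ], 10)$adjacency
    a1 <- compute_dod(gas$positions[t1[2], , ], 10)$adjacency
    deg <- rowSums(a0)
    mean((rowSums(a0 & a1) / deg)[deg > 0])
  })
  se <- sd(perm) / sqrt(length(perm)) + 0.02
  expect_lt(abs(pn2$ensemble[2] - mean(perm)), 3 * se)
  expect_lt(abs(pn2$ensemble[3] - mean(perm)), 3 * se)
})

test_that("lag statistics are invariant under global translation", {
  gas <- make_fixture("gas", n_agents = 12, n_frames = 30, seed = 9)
  shifted <- gas
  shifted$positions[, , 1] <- shifted$positions[, , 1] + 100
  shifted$positions[, , 2] <- shifted$positions[, , 2] - 40
  expect_equal(msd(shifted)$ensemble, msd(gas)$ensemble, tolerance = 1e-9)
  expect_equal(neighbor_persistence(shifted, lags = c(0L, 4L))$ensemble,
               neighbor_persistence(gas, lags = c(0L, 4L))$ensemble)
  expect_equal(rotational_order(herd_frame(gas$positions[1, , ] + 50,
                                           gas$headings[1, ])),
               rotational_order(herd_frame(gas$positions[1, , ],
                                           gas$headings[1, ])))
})

test_that("rigid rotation and neighbour shuffling are distinguishable regimes", {
  # rigidly rotating mill: the whole Voronoi diagram co-rotates, so every
  # neighbour is kept forever (and cell areas never change at all)
  mill <- make_fixture("mill", n_agents = 18, n_frames = 50, omega = 0.12)
  pn <- neighbor_persistence(mill, lags = c(0L, 10L, 40L))
  expect_equal(pn$ensemble, rep(1, 3))
  expect_lt(max(apply(mill$areas, 2, function(x) diff(range(x)))), 1e-9)
  # agents sliding around a fixed ellipse: areas oscillate with the
  # revolution period and revive instead of decaying (the biased ACF
  # estimator damps lag tau by (1 - tau/T))
  n <- 16; T_ <- 600; P <- 60
  base <- 2 * pi * (0:(n - 1)) / n
  frames <- lapply(seq_len(T_), function(t) {
    phi <- 2 * pi * (t - 1) / P
    herd_frame(cbind(8 * cos(base + phi), 5 * sin(base + phi)),
               base + phi + pi / 2, t - 1L)
  })
  periodic <- trajectory_from_frames(frames, shh_config(n_agents = n))
  ac <- dod_acf(periodic, max_lag = P)
  expect_gt(ac$ensemble[P + 1], (1 - P / T_) - 0.05)
  # neighbour-shuffling gas: persistence decays well below 1
  gas <- make_fixture("gas", n_agents = 16, n_frames = 60, seed = 10)
  pn2 <- neighbor_persistence(gas, lags = c(0L, 10L), n_ref = 20L)
  expect_lt(pn2$ensemble[2], 0.8)
})

test_that("risk spread of cumulative DOD is non-increasing on steady-state-like input", {
  # stationary exchangeable areas: spread shrinks as 1/sqrt(tau)
  set.seed(11)
  gas <- make_fixture("gas", n_agents = 10, n_frames = 5, seed = 11)
  T_ <- 400
  gas$areas <- matrix(50 + rnorm(T_ * 10, 0, 8), T_, 10)
  cd <- cumulative_dod(gas)
  sp <- risk_spread(cd)
  taus <- c(10, 50, 200, 400)
  expect_true(all(diff(sp[taus]) < 0))
  lag <- cumdod_convergence_lag(cd, tol = 0.10)
  expect_true(is.finite(lag))
  expect_true(all(abs(cd$per_agent[T_, ] / cd$ensemble[T_] - 1) <= 0.10))
})

test_that("MSD saturation lag identifies the plateau onset", {
  # Ornstein-Uhlenbeck-like confined walk: MSD saturates
  set.seed(12)
  T_ <- 600; n <- 6
  x <- matrix(0, T_, n); y <- matrix(0, T_, n)
  for (t in 2:T_) {
    x[t, ] <- 0.9 * x[t - 1, ] + rnorm(n, 0, 0.5)
    y[t, ] <- 0.9 * y[t - 1, ] + rnorm(n, 0, 0.5)
  }
  gas <- make_fixture("gas", n_agents = n, n_frames = 2, seed = 13)
  tr <- gas
  tr$positions <- array(c(x, y), c(T_, n, 2))
  tr$headings <- matrix(0, T_, n)
  ms <- msd(tr, subtract_com = FALSE)
  lag <- msd_saturation_lag(ms)
  expect_true(is.finite(lag))
  expect_lt(lag, 100)   # OU correlation time ~ 10 steps
})
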