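test_that("policy evaluation is a deterministic softmax over four actions", {
  set.seed(1)
  m <- actor_model()
  p <- policy_evaluate(m, rep(0, 5))
  expect_length(p, 4)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  o <- runif(5)
  expect_identical(policy_evaluate(m, o), policy_evaluate(m, o))
  # matrix input: one distribution per row
  P <- policy_evaluate(m, matrix(runif(20), 4, 5))
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-9)
  expect_error(policy_evaluate(m, c(NA, 1, 1, 1, 1)), "non-finite")
  expect_error(policy_evaluate(m, rep(0, 3)), "dimension")
})

test_that("a hand-built linear actor reproduces the closed-form softmax", {
  m <- actor_model(hidden = integer(0))  # no hidden layer: logits = oW + b
  W <- matrix(seq(-1, 1, length.out = 20), 5, 4)
  b <- c(0.1, -0.2, 0.3, 0)
  m$actor$W[[1]] <- W
  m$actor$b[[1]] <- b
  o <- c(0.5, 1, 0, 2, 0.25)
  z <- as.numeric(o %*% W + b)
  expect_equal(unname(policy_evaluate(m, o)), exp(z) / sum(exp(z)),
               tolerance = 1e-12)
})

test_that("action sampling matches the distribution and is seeded", {
  expect_true(all(sample_action(matrix(c(1, 0, 0, 0), 1e3, 4, byrow = TRUE)) == 1L))
  set.seed(8)
  a <- sample_action(matrix(0.25, 1e5, 4))
  fr <- tabulate(a, 4) / 1e5
  expect_true(all(abs(fr - 0.25) < 3 * sqrt(0.25 * 0.75 / 1e5)))
  set.seed(5); s1 <- sample_action(matrix(runif(40), 10, 4) |> (\(m) m / rowSums(m))())
  set.seed(5); s2 <- sample_action(matrix(runif(40), 10, 4) |> (\(m) m / rowSums(m))())
  expect_identical(s1, s2)
  expect_error(sample_action(c(0.5, 0.2, 0.2, 0.2)), "invalid policy")
})

test_that("discounted returns follow the geometric recursion", {
  expect_equal(discounted_returns(c(1, 0, 1), 0.5), c(1.25, 0.5, 1))
  r <- runif(10)
  expect_equal(discounted_returns(r, 0), r)
  g <- discounted_returns(rep(1, 4000), 0.99)
  expect_equal(g[1], 1 / (1 - 0.99), tolerance = 1e-3)
  # matrix form treats columns as agents
  M <- cbind(c(1, 0, 1), c(0, 0, 2))
  expect_equal(discounted_returns(M, 0.5), cbind(c(1.25, 0.5, 1), c(0.5, 1, 2)))
  expect_error(discounted_returns(r, 1), "gamma")
  expect_error(discounted_returns(r, -0.1), "gamma")
})

test_that("policy gradient solves a four-armed bandit within 500 updates", {
  set.seed(3)
  m <- actor_model(hidden = c(16L))
  obs <- matrix(0, 64, 5)
  for (k in 1:500) {
    p <- policy_evaluate(m, rep(0, 5))
    a <- sample_action(matrix(p, 64, 4, byrow = TRUE))
    r <- as.numeric(a == 2L)       # only arm 2 pays
    upd <- actor_update(m, obs, a, r - mean(r), lr = 0.05,
                        entropy_weight = 0.001)
    m <- upd$model
    if (policy_evaluate(m, rep(0, 5))[2] >= 0.99) break
  }
  expect_gte(policy_evaluate(m, rep(0, 5))[2], 0.99)
})

test_that("zero learning rate and zero discount leave the model untouched", {
  cfg <- tiny_config(lr = 0, gamma = 0, n_episodes = 1L,
                     steps_per_episode = 30L)
  set.seed(cfg$seed)
  m0 <- actor_model(cfg$n_sectors, 4L, cfg$hidden)
  fit <- shh_train(cfg)
  expect_equal(fit$model$actor$W, m0$actor$W, tolerance = 1e-12)
  expect_equal(fit$model$critic$W, m0$critic$W, tolerance = 1e-12)
})

test_that("all agents share one actor and training logs the schedule", {
  cfg <- tiny_config()
  fit <- shh_train(cfg)
  expect_s3_class(fit, "shh_policy")
  expect_equal(nrow(fit$log), cfg$n_episodes)
  expect_true(all(is.finite(fit$log$mean_reward)))
  # decentralized execution, centralized parameters: any two agents map
  # the same observable to the same distribution
  o <- runif(5)
  expect_identical(predict(fit, o), policy_evaluate(fit$model, o))
  expect_length(coef(fit), length(unlist(fit$model$actor)))
})

test_that("the fitted-policy object supports the standard model methods", {
  fit <- shh_train(tiny_config())
  expect_output(print(fit), "Selfish-herd policy")
  s <- summary(fit)
  expect_s3_class(s, "summary.shh_policy")
  expect_output(print(s), "trainable parameters")
  expect_type(coef(fit), "double")
  expect_equal(predict(fit, matrix(0, 2, 5)),
               policy_evaluate(fit$model, matrix(0, 2, 5)))
  expect_true(predict(fit, rep(0, 5), type = "action") %in% ACTIONS)
  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
  tr <- simulate(fit, nsim = 2, seed = 3, n_steps = 10)
  expect_length(tr, 2)
  expect_s3_class(tr[[1]], "herd_trajectory")
  expect_output(print(tr[[1]]), "herd_trajectory")
})

test_that("scripted and frozen rollouts behave as prescribed", {
  cfg <- tiny_config()
  still <- rollout("stand_still", n_steps = 20, config = cfg, seed = 4)
  expect_true(all(abs(sweep(still$positions[, , 1], 2,
                            still$positions[1, , 1])) < 1e-12))
  expect_true(all(still$actions == match("stand_still", ACTIONS)))
  # single ballistic agent: length 0.25 * n_steps
  cfg1 <- shh_config(n_agents = 2L, box_side = 60, noise_sd = 0,
                     steps_per_episode = 40L)
  init <- herd_frame(rbind(c(0, 0), c(50, 0)), c(0, pi / 2))
  fw <- rollout("forward", n_steps = 40, config = cfg1, init = init)
  expect_equal(fw$positions[40, 1, ], c(10, 0), tolerance = 1e-9)
  # seeded reproducibility of stochastic rollouts
  fit <- shh_train(tiny_config(n_episodes = 1L))
  t1 <- rollout(fit, n_steps = 25, seed = 11)
  t2 <- rollout(fit, n_steps = 25, seed = 11)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$actions, t2$actions)
})

test_that("training lifts the mean reward of a small herd above the random-policy baseline", {
  cfg <- shh_config(n_agents = 10L, box_side = 12, steps_per_episode = 800L,
                    n_episodes = 5L, minibatch = 1024L, lr = 2e-3,
                    epochs_per_episode = 2L, gamma = 0.95, seed = 202L)
  fit <- shh_train(cfg)
  n_eval <- 20
  set.seed(303)
  ev_tr <- vapply(seq_len(n_eval), function(i)
    mean(rollout(fit, n_steps = 400, config = cfg)$reward), numeric(1))
  ev_rn <- vapply(seq_len(n_eval), function(i)
    mean(rollout("random", n_steps = 400, config = cfg)$reward), numeric(1))
  se <- sqrt(var(ev_tr) / n_eval + var(ev_rn) / n_eval)
  expect_gt(mean(ev_tr) - mean(ev_rn), 5 * se)
  # the training log itself improves over episodes
  expect_gt(mean(tail(fit$log$mean_reward, 2)), fit$log$mean_reward[1])
})
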