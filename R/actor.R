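# Shared actor-critic networks: small multilayer perceptrons written in
# plain matrix algebra (forward pass, backprop, Adam), sized for the
# 5-input observable and 4-action policy of the herd task.

mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = 1 / sqrt(sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b)
}

# forward pass; tanh hidden layers, linear output. Returns the output and
# the per-layer activations needed for backprop.
mlp_forward <- function(net, X) {
  L <- length(net$W)
  hs <- vector("list", L + 1L)
  hs[[1]] <- X
  for (l in seq_len(L)) {
    Z <- hs[[l]] %*% net$W[[l]]
    Z <- sweep(Z, 2, net$b[[l]], "+")
    hs[[l + 1]] <- if (l < L) tanh(Z) else Z
  }
  list(out = hs[[L + 1]], hs = hs)
}

# backprop from the gradient w.r.t. the linear output
mlp_backward <- function(net, fwd, dout) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- dout
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fwd$hs[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1)
      delta <- (delta %*% t(net$W[[l]])) * (1 - fwd$hs[[l]]^2)
  }
  list(W = gW, b = gb)
}

softmax_rows <- function(Z) {
  Z <- Z - Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  E <- exp(Z)
  E / rowSums(E)
}

adam_init <- function(net) {
  zero <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero(net$W), vW = zero(net$W),
       mb = zero(net$b), vb = zero(net$b), t = 0L)
}

adam_step <- function(net, grad, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (l in seq_along(net$W)) {
    st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * grad$W[[l]]
    st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * grad$W[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (st$mW[[l]] / bc1) / (sqrt(st$vW[[l]] / bc2) + eps)
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * grad$b[[l]]
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * grad$b[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (st$mb[[l]] / bc1) / (sqrt(st$vb[[l]] / bc2) + eps)
  }
  list(net = net, state = st)
}

#' Initialize a shared actor-critic model
#'
#' The actor maps the 5-dimensional crowdedness observable to action
#' logits (softmax head over the four actions); the critic maps the same
#' observable to a scalar state-value baseline. Both are tanh multilayer
#' perceptrons. All agents share one set of parameters (centralized
#' training, decentralized execution).
#'
#' @param n_inputs observable dimension (default 5).
#' @param n_actions number of actions (default 4).
#' @param hidden integer vector of hidden-layer widths (default c(64, 64)).
#' @return object of class `actor_model`; evaluation is deterministic
#'   given parameters and input.
#' @export
actor_model <- function(n_inputs = 5L, n_actions = 4L, hidden = c(64L, 64L)) {
  structure(list(
    actor = mlp_init(c(n_inputs, hidden, n_actions)),
    critic = mlp_init(c(n_inputs, hidden, 1L)),
    n_inputs = n_inputs, n_actions = n_actions, hidden = hidden,
    adam_actor = NULL, adam_critic = NULL
  ), class = "actor_model")
}

#' Evaluate the policy on one or many observables
#'
#' @param model an `actor_model` (or the `model` element of a fitted
#'   [shh_train()] object).
#' @param obs numeric vector of length `n_inputs`, or a matrix with one
#'   observable per row.
#' @return probability vector over the four actions (rows summing to 1
#'   when `obs` is a matrix).
#' @export
policy_evaluate <- function(model, obs) {
  vec <- is.null(dim(obs))
  X <- if (vec) matrix(obs, 1) else as.matrix(obs)
  if (!all(is.finite(X))) stop("non-finite observable")
  if (ncol(X) != model$n_inputs) stop("observable has wrong dimension")
  P <- softmax_rows(mlp_forward(model$actor, X)$out)
  if (vec) setNames(P[1, ], ACTIONS) else P
}

#' Critic state-value estimate
#' @inheritParams policy_evaluate
#' @return numeric vector of state values.
#' @export
value_evaluate <- function(model, obs) {
  X <- if (is.null(dim(obs))) matrix(obs, 1) else as.matrix(obs)
  as.numeric(mlp_forward(model$critic, X)$out)
}

#' Sample an action from a policy distribution
#'
#' @param dist probability vector over the four actions (or a matrix of
#'   per-agent distributions, one per row).
#' @return integer action id(s), indexing [ACTIONS]; uses the current R
#'   RNG stream, so runs are reproducible from a seed.
#' @export
sample_action <- function(dist) {
  P <- if (is.null(dim(dist))) matrix(dist, 1) else as.matrix(dist)
  if (any(P < -1e-9) || any(abs(rowSums(P) - 1) > 1e-6))
    stop("invalid policy distribution")
  P[P < 0] <- 0
  u <- runif(nrow(P))
  cum <- t(apply(P, 1, cumsum))
  a <- rowSums(u > cum) + 1L
  pmin(a, ncol(P))
}

#' Discounted returns of a reward sequence
#'
#' `G_t = sum_k gamma^k r_(t+k)` over the remaining episode.
#'
#' @param rewards numeric vector (one agent) or T x N matrix (per-step
#'   rows, per-agent columns).
#' @param gamma discount factor in `[0, 1)`.
#' @return returns with the same shape as `rewards`.
#' @export
discounted_returns <- function(rewards, gamma) {
  if (gamma < 0 || gamma >= 1) stop("`gamma` must be in [0, 1)")
  vec <- is.null(dim(rewards))
  R <- if (vec) matrix(rewards, ncol = 1) else rewards
  G <- R
  T_ <- nrow(R)
  if (T_ > 1)
    for (t in (T_ - 1):1) G[t, ] <- R[t, ] + gamma * G[t + 1, ]
  if (vec) as.numeric(G) else G
}

#' One policy-gradient update of the shared actor
#'
#' Advantage-weighted REINFORCE step with an entropy bonus:
#' the loss is `-mean(log pi(a|o) * A) - beta * mean(H(pi(.|o)))`,
#' minimized by one Adam step on the pooled batch.
#'
#' @param model `actor_model`.
#' @param obs batch matrix of observables.
#' @param actions integer action ids.
#' @param advantages numeric advantages, same length as `actions`.
#' @param lr Adam learning rate.
#' @param entropy_weight entropy bonus weight beta.
#' @return list: updated `model`, scalar `loss`, scalar mean `entropy`.
#' @export
actor_update <- function(model, obs, actions, advantages,
                         lr = 3e-4, entropy_weight = 0.01) {
  X <- as.matrix(obs)
  n <- nrow(X)
  fwd <- mlp_forward(model$actor, X)
  P <- softmax_rows(fwd$out)
  logP <- log(pmax(P, 1e-12))
  Y <- matrix(0, n, model$n_actions)
  Y[cbind(seq_len(n), actions)] <- 1
  H <- -rowSums(P * logP)
  loss <- -mean(logP[cbind(seq_len(n), actions)] * advantages) -
    entropy_weight * mean(H)
  if (!is.finite(loss)) stop("training diverged: non-finite actor loss")
  dlogits <- ((P - Y) * advantages + entropy_weight * P * (logP + H)) / n
  grad <- mlp_backward(model$actor, fwd, dlogits)
  if (is.null(model$adam_actor)) model$adam_actor <- adam_init(model$actor)
  upd <- adam_step(model$actor, grad, model$adam_actor, lr)
  model$actor <- upd$net
  model$adam_actor <- upd$state
  list(model = model, loss = loss, entropy = mean(H))
}

#' One regression update of the critic baseline
#'
#' Mean-squared-error step of the state-value network toward the observed
#' discounted returns.
#'
#' @inheritParams actor_update
#' @param returns target discounted returns.
#' @return list: updated `model`, scalar `loss`.
#' @export
critic_update <- function(model, obs, returns, lr = 3e-4) {
  X <- as.matrix(obs)
  n <- nrow(X)
  fwd <- mlp_forward(model$critic, X)
  v <- as.numeric(fwd$out)
  loss <- mean((v - returns)^2)
  if (!is.finite(loss)) stop("training diverged: non-finite critic loss")
  dout <- matrix(2 * (v - returns) / n, ncol = 1)
  grad <- mlp_backward(model$critic, fwd, dout)
  if (is.null(model$adam_critic)) model$adam_critic <- adam_init(model$critic)
  upd <- adam_step(model$critic, grad, model$adam_critic, lr)
  model$critic <- upd$net
  model$adam_critic <- upd$state
  list(model = model, loss = loss)
}
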