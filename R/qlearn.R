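#' Exploration-probability annealing schedule
#'
#' `epsilon(e) = max(0.01, 0.08 - 0.01 * (e / 200))`: starts at 0.08,
#' decays linearly with training episode, floored at 0.01.
#'
#' @param episode Training episode index (0-based); vectorized.
#' @return Exploration probability in `[0.01, 0.08]`.
#' @export
epsilon_schedule <- function(episode) {
  stopifnot(all(episode >= 0))
  pmax(0.01, 0.08 - 0.01 * (episode / 200))
}

#' Experience replay buffer
#'
#' Fixed-capacity FIFO ring store of transitions
#' `(s_t, a_t, r_t, s_{t+1}, d_t)`; once full, the oldest entries are
#' evicted first.
#'
#' @param capacity Maximum number of stored transitions.
#' @return A list with functions `add(transition)`, `size()`,
#'   `get(i)`, and `sample_batch(n)` (indices without replacement).
#' @export
replay_buffer <- function(capacity = 50000) {
  stopifnot(capacity >= 1)
  store <- vector("list", capacity)
  n <- 0L       # filled slots
  pos <- 0L     # last written slot
  list(
    add = function(transition) {
      pos <<- (pos %% capacity) + 1L
      store[[pos]] <<- transition
      n <<- min(n + 1L, capacity)
      invisible(NULL)
    },
    size = function() n,
    get = function(i) store[[i]],
    sample_batch = function(size) {
      idx <- sample.int(n, size, replace = size > n)
      store[idx]
    }
  )
}

#' Streaming observation normalizer (Welford's algorithm)
#'
#' Numerically stable online mean/variance per observation entry, used to
#' normalize environment observations to mean 0 and s.d. 1 before they are
#' fed to the value network.
#'
#' @param dim Observation dimensionality.
#' @param norm A normalizer created by `welford_new()`.
#' @param obs Observation vector.
#' @param sd_floor Lower bound on the standard deviation, protecting
#'   constant entries (they normalize to 0).
#' @return `welford_new()`/`welford_update()`: a normalizer (list with
#'   `n`, `mean`, `m2`). `welford_apply()`: the normalized observation.
#'   `welford_stats()`: list with `mean` and `var` (population variance).
#' @export
welford_new <- function(dim) {
  list(n = 0L, mean = numeric(dim), m2 = numeric(dim))
}

#' @rdname welford_new
#' @export
welford_update <- function(norm, obs) {
  stopifnot(length(obs) == length(norm$mean))
  n <- norm$n + 1L
  delta <- obs - norm$mean
  mean <- norm$mean + delta / n
  m2 <- norm$m2 + delta * (obs - mean)
  list(n = n, mean = mean, m2 = m2)
}

#' @rdname welford_new
#' @export
welford_stats <- function(norm) {
  v <- if (norm$n > 0L) norm$m2 / norm$n else rep(0, length(norm$mean))
  list(mean = norm$mean, var = v)
}

#' @rdname welford_new
#' @export
welford_apply <- function(norm, obs, sd_floor = 1e-8) {
  s <- welford_stats(norm)
  sd <- pmax(sqrt(s$var), sd_floor)
  (obs - s$mean) / sd
}

#' Bootstrap target for one transition
#'
#' `R_hat = r_t` on terminal transitions, otherwise
#' `r_t + discount * max_a Q(s_{t+1}, a)` with Q read from the value
#' network's feedforward prediction on the normalized next observation.
#'
#' @param transition List with `s`, `a`, `r`, `s_next`, `d`.
#' @param net The value network.
#' @param norm A [welford_new()] normalizer (applied to `s_next`).
#' @param discount Discount factor.
#' @return The scalar regression target for action `a`.
#' @export
q_target <- function(transition, net, norm, discount = 0.98) {
  if (isTRUE(transition$d)) return(transition$r)
  q_next <- predict(net, welford_apply(norm, transition$s_next))
  transition$r + discount * max(q_next)
}

#' Masked value-network update
#'
#' One learning step in which only the output neuron of the taken action
#' receives a target. Under prospective configuration the remaining output
#' neurons are freed (they relax and may change through the shared hidden
#' layers); under backpropagation their error is masked out.
#'
#' @param net The value network.
#' @param rule `"pc"` or `"bp"`.
#' @param s_in Normalized observation (vector or column matrix).
#' @param action Action index (scalar, or one per batch column).
#' @param target_value Regression target(s) for the chosen action(s).
#' @param alpha Learning rate.
#' @param control Relaxation settings for `"pc"`.
#' @return The updated network.
#' @export
masked_q_learn <- function(net, rule = c("pc", "bp"), s_in, action,
                           target_value, alpha,
                           control = relax_control(gamma0 = 0.05,
                                                   max_steps = 32,
                                                   adaptive = FALSE)) {
  rule <- match.arg(rule)
  n_out <- net$layer_sizes[length(net$layer_sizes)]
  X <- .as_columns(s_in, net$layer_sizes[1L])
  B <- ncol(X)
  stopifnot(length(action) == B, length(target_value) == B,
            all(action >= 1), all(action <= n_out))
  mask <- matrix(FALSE, n_out, B)
  mask[cbind(action, seq_len(B))] <- TRUE
  tgt <- matrix(0, n_out, B)
  tgt[mask] <- target_value
  learn_step(net, rule, X, tgt, alpha, control = control,
             output_mask = mask)
}

#' Q-learning configuration
#'
#' Defaults follow the reference protocol: 10000 episodes, discount 0.98,
#' replay capacity 50000 with training starting once more than 2000
#' transitions are stored, 10 replay epochs of minibatch 60 per episode,
#' a value network with two hidden layers of 64 sigmoid neurons, and for
#' the `"pc"` rule a fixed (non-adaptive) relaxation of 32 sweeps at
#' integration step 0.05. The smaller fixed relaxation reflects value
#' learning being less stable and more expensive than supervised
#' training. All knobs are exposed so tests can run desk-scale versions.
#'
#' @param episodes,discount,minibatch,replay_epochs,capacity,train_threshold
#'   Loop parameters; see above.
#' @param hidden Hidden layer sizes of the value network.
#' @param activation Activation of the value network.
#' @param epsilon_fn Exploration schedule, a function of the 0-based
#'   episode index.
#' @param pc_control [relax_control()] used by the `"pc"` rule.
#' @return A list of class `q_config`.
#' @export
q_config <- function(episodes = 10000, discount = 0.98, minibatch = 60,
                     replay_epochs = 10, capacity = 50000,
                     train_threshold = 2000, hidden = c(64, 64),
                     activation = "sigmoid",
                     epsilon_fn = epsilon_schedule,
                     pc_control = relax_control(gamma0 = 0.05,
                                                max_steps = 32,
                                                adaptive = FALSE)) {
  structure(list(episodes = as.integer(episodes), discount = discount,
                 minibatch = as.integer(minibatch),
                 replay_epochs = as.integer(replay_epochs),
                 capacity = as.integer(capacity),
                 train_threshold = as.integer(train_threshold),
                 hidden = hidden, activation = activation,
                 epsilon_fn = epsilon_fn, pc_control = pc_control),
            class = "q_config")
}

#' Built-in deterministic two-state chain environment
#'
#' A minimal MDP for validating the learning loop without external
#' simulators. From the start state, action 1 advances to the second
#' state (reward 0) and action 2 ends the episode with a small immediate
#' reward 0.1; from the second state, action 1 ends with reward 1 and
#' action 2 with reward 0. With discount 0.98 the optimal greedy policy
#' is action 1 in both states (value 0.98 > 0.1 at the start).
#' Observations are one-hot state encodings.
#'
#' Any environment implementing the same contract -- `reset()` returning
#' an observation and `step(action)` returning
#' `list(obs, reward, terminal)`, plus `obs_dim` and `n_actions` -- can be
#' plugged into [q_learning_loop()].
#'
#' @return An environment list.
#' @export
toy_chain_env <- function() {
  state <- 1L
  obs_of <- function(s) as.numeric(seq_len(2) == s)
  list(
    obs_dim = 2L,
    n_actions = 2L,
    reset = function() {
      state <<- 1L
      obs_of(state)
    },
    step = function(action) {
      stopifnot(action %in% c(1L, 2L))
      if (state == 1L) {
        if (action == 1L) {
          state <<- 2L
          list(obs = obs_of(2L), reward = 0, terminal = FALSE)
        } else {
          list(obs = obs_of(1L), reward = 0.1, terminal = TRUE)
        }
      } else {
        r <- if (action == 1L) 1 else 0
        list(obs = obs_of(2L), reward = r, terminal = TRUE)
      }
    }
  )
}

#' Q-learning with experience replay
#'
#' Trains a value network on a pluggable environment with epsilon-greedy
#' exploration (argmax ties broken by lowest action index), a FIFO replay
#' buffer, and -- once the buffer holds more than `train_threshold`
#' transitions -- `replay_epochs` minibatch updates per episode with
#' bootstrap targets from [q_target()] applied through [masked_q_learn()].
#' Observation statistics are updated with Welford's algorithm on every
#' state as it is observed; transitions store raw observations and are
#' normalized with the current statistics at replay time.
#'
#' @param env Environment implementing the [toy_chain_env()] contract.
#' @param rule `"pc"` or `"bp"`.
#' @param config A [q_config()].
#' @param alpha Learning rate.
#' @param seed Optional integer seed (exploration, minibatch sampling and
#'   network initialization).
#' @param net Optional pre-built value network; by default a
#'   Xavier-initialized network `obs_dim - hidden... - n_actions` is
#'   created from `config`.
#' @return A list with `rewards` (sum of rewards per episode), `net`,
#'   `normalizer` and `config`.
#' @export
q_learning_loop <- function(env, rule = c("pc", "bp"), config = q_config(),
                            alpha = 0.01, seed = NULL, net = NULL) {
  rule <- match.arg(rule)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(net)) {
    net <- pcn_network(c(env$obs_dim, config$hidden, env$n_actions),
                       activation = config$activation)
  }
  buffer <- replay_buffer(config$capacity)
  norm <- welford_new(env$obs_dim)
  rewards <- numeric(config$episodes)

  for (ep in seq_len(config$episodes)) {
    eps <- config$epsilon_fn(ep - 1L)
    obs <- env$reset()
    norm <- welford_update(norm, obs)
    done <- FALSE
    sum_reward <- 0
    while (!done) {
      a <- if (stats::runif(1) < eps) {
        sample.int(env$n_actions, 1)
      } else {
        which.max(predict(net, welford_apply(norm, obs)))
      }
      res <- env$step(a)
      if (!all(c("obs", "reward", "terminal") %in% names(res))) {
        stop("environment step() must return obs, reward and terminal",
             call. = FALSE)
      }
      sum_reward <- sum_reward + res$reward
      buffer$add(list(s = obs, a = a, r = res$reward,
                      s_next = res$obs, d = res$terminal))
      norm <- welford_update(norm, res$obs)
      obs <- res$obs
      done <- isTRUE(res$terminal)
    }
    rewards[ep] <- sum_reward

    if (buffer$size() > config$train_threshold) {
      for (epoch in seq_len(config$replay_epochs)) {
        batch <- buffer$sample_batch(config$minibatch)
        S <- vapply(batch, function(t) welford_apply(norm, t$s),
                    numeric(env$obs_dim))
        S_next <- vapply(batch, function(t) welford_apply(norm, t$s_next),
                         numeric(env$obs_dim))
        S <- matrix(S, nrow = env$obs_dim)
        S_next <- matrix(S_next, nrow = env$obs_dim)
        r <- vapply(batch, `[[`, numeric(1), "r")
        d <- vapply(batch, function(t) isTRUE(t$d), logical(1))
        a <- vapply(batch, `[[`, numeric(1), "a")
        q_next <- predict(net, S_next)
        targets <- r + config$discount * apply(q_next, 2, max) * !d
        net <- masked_q_learn(net, rule, S, a, targets, alpha,
                              control = config$pc_control)
      }
    }
  }
  list(rewards = rewards, net = net, normalizer = norm, config = config)
}

#' Sliding-window mean of a reward trace
#'
#' @param x Numeric trace (e.g. sum of rewards per episode).
#' @param window Window length.
#' @return Trailing moving average, `NA` where the window is incomplete.
#' @export
sliding_mean <- function(x, window = 200) {
  stats::filter(x, rep(1 / window, window), sides = 1)
}
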