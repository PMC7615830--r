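test_that("Hebbian update matches the numeric energy gradient at fixed activity", {
  net <- pcn_network(c(3, 4, 3, 2), activation = "sigmoid", seed = 42)
  xs <- random_state(net, seed = 31)
  st <- pcn_errors(net, xs)
  alpha <- 0.3
  upd <- pcn_update_weights(net, st, alpha)
  for (l in 1:3) {
    fW <- function(v) {
      n2 <- net
      n2$weights[[l]] <- matrix(v, nrow(net$weights[[l]]))
      energy_by_hand(n2, lapply(xs, as.matrix))
    }
    g <- num_grad(fW, as.numeric(net$weights[[l]]))
    expect_equal(as.numeric(upd$weights[[l]] - net$weights[[l]]),
                 -alpha * g, tolerance = 1e-5)
  }
})

test_that("zero errors produce zero weight change", {
  net <- pcn_network(c(3, 4, 2), activation = "sigmoid", seed = 2)
  xs <- pcnlearn:::.forward_activations(net, matrix(c(1, 0, -1), 3, 1))
  st <- pcn_errors(net, xs)
  upd <- pcn_update_weights(net, st, alpha = 0.5)
  expect_equal(upd$weights, net$weights)
})

test_that("one Hebbian update strictly decreases the energy at fixed activities", {
  for (seed in 1:4) {
    net <- pcn_network(c(3, 5, 2), activation = "leaky_relu", seed = seed)
    pat <- random_pattern_pair(3, 2, seed = seed + 70)
    r <- pcn_relax(net, pat$s_in, target = pat$s_target)
    e0 <- pcn_energy(net, r)$total
    upd <- pcn_update_weights(net, r, alpha = 1e-4)
    e1 <- energy_by_hand(upd, r$activities)
    expect_lt(e1, e0)
  }
})

test_that("learning the current prediction is a fixed point", {
  net <- pcn_network(c(3, 4, 2), activation = "sigmoid", seed = 9)
  s_in <- c(0.5, -0.5, 1)
  tgt <- predict(net, s_in)
  # long relaxation so residual errors reach machine precision
  upd <- pcn_learn(net, s_in, tgt, alpha = 0.1,
                   control = relax_control(max_steps = 2048))
  expect_lt(max(mapply(function(a, b) max(abs(a - b)),
                       upd$weights, net$weights)), 1e-10)
})

test_that("repeated prospective-configuration learning drives the loss to zero", {
  net <- pcn_network(c(8, 8, 8), activation = "linear", seed = 11)
  pat <- random_pattern_pair(8, 8, seed = 12)
  for (i in 1:200) net <- pcn_learn(net, pat$s_in, pat$s_target, alpha = 0.05)
  expect_lt(mlp_loss(net, pat$s_in, pat$s_target), 1e-6)
})

test_that("single-weight-layer networks give identical pc and bp updates", {
  for (act in c("linear", "sigmoid")) {
    net <- pcn_network(c(4, 3), activation = act, seed = 5)
    pat <- random_pattern_pair(4, 3, seed = 6)
    a <- pcn_learn(net, pat$s_in, pat$s_target, alpha = 0.1)
    b <- bp_learn(net, pat$s_in, pat$s_target, alpha = 0.1)
    expect_equal(a$weights, b$weights)
    # and both equal the explicit delta rule
    f <- if (act == "linear") identity else function(x) 1 / (1 + exp(-x))
    eps <- pat$s_target - drop(net$weights[[1]] %*% f(pat$s_in))
    expect_equal(a$weights[[1]],
                 net$weights[[1]] + 0.1 * outer(eps, f(pat$s_in)))
  }
})

test_that("bear fixture: pc strengthens the correct output on the first update", {
  fx <- bear_fixture()
  pc <- pcn_learn(fx$net, fx$pattern$s_in, fx$pattern$s_target, fx$alpha)
  bp <- bp_learn(fx$net, fx$pattern$s_in, fx$pattern$s_target, fx$alpha)
  # hidden -> correct-output weight is row 2 of layer 2
  expect_gt(pc$weights[[2]][2, 1], 1)
  expect_equal(bp$weights[[2]][2, 1], 1)
  # exact prospective hidden state: 2/3 for unit weights
  r <- pcn_relax(fx$net, 1, target = c(0, 1))
  expect_equal(drop(r$activities[[2]]), 2 / 3, tolerance = 1e-6)
  expect_equal(drop(r$errors[[3]]), c(-2 / 3, 1 / 3), tolerance = 1e-6)
})

test_that("per-layer learning rates scale each layer's update independently", {
  net <- pcn_network(c(2, 3, 2), activation = "linear", seed = 8)
  pat <- random_pattern_pair(2, 2, seed = 9)
  base <- pcn_learn(net, pat$s_in, pat$s_target, alpha = 0.1)
  mixed <- pcn_learn(net, pat$s_in, pat$s_target, alpha = NA,
                     alpha_per_layer = c(0.1, 0.2))
  d_base <- weight_delta(net, base)
  d_mixed <- weight_delta(net, mixed)
  expect_equal(d_mixed[[1]], d_base[[1]])
  expect_equal(d_mixed[[2]], 2 * d_base[[2]])
})

test_that("partial output clamping frees the unclamped neurons during relaxation", {
  net <- pcn_network(c(2, 3, 3), activation = "sigmoid", seed = 13)
  s_in <- c(1, -1)
  mask <- c(TRUE, FALSE, FALSE)
  r <- pcn_relax(net, s_in, target = 0.7, output_mask = mask)
  expect_equal(drop(r$activities[[3]])[1], 0.7)   # clamped entry fixed
  # free outputs settled to near-zero error; clamped one carries the error
  expect_lt(max(abs(drop(r$errors[[3]])[2:3])), 1e-3)
  # free outputs at equilibrium differ from the plain forward pass:
  # the hidden activity shifted to accommodate the clamp
  expect_gt(max(abs(drop(r$activities[[3]])[2:3] -
                    predict(net, s_in)[2:3])), 1e-4)
})
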