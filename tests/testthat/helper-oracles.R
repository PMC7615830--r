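# Independent numerical oracles used across tests.

# central-difference gradient of a scalar function
num_grad <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x
    xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# total energy recomputed directly from the defining formula,
# independent of pcn_errors()/pcn_energy()
energy_by_hand <- function(net, activities) {
  f <- switch(net$activation,
              linear = identity,
              sigmoid = function(x) 1 / (1 + exp(-x)),
              leaky_relu = function(x) ifelse(x > 0, x, 0.01 * x))
  tot <- 0
  for (l in seq_along(net$weights)) {
    eps <- activities[[l + 1]] - net$weights[[l]] %*% f(as.matrix(activities[[l]]))
    tot <- tot + 0.5 * sum(eps^2)
  }
  tot
}

# random small network + consistent random state
random_state <- function(net, seed) {
  set.seed(seed)
  lapply(net$layer_sizes, function(n) rnorm(n))
}

# weight-matrix change between two networks
weight_delta <- function(before, after) {
  Map(function(a, b) b - a, before$weights, after$weights)
}
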