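#' Construct a layered network shared by both learning rules
#'
#' Builds a bias-free multilayer network with `L` weight matrices connecting
#' `L + 1` layers of neurons. The same object is trained either as a
#' predictive coding network (prospective configuration, [pcn_learn()]) or as
#' a multilayer perceptron (backpropagation, [bp_learn()]); with identical
#' weights the two produce identical predictions, so comparisons isolate the
#' learning rule itself.
#'
#' Weight matrix `l` has `layer_sizes[l + 1]` rows and `layer_sizes[l]`
#' columns, and the input to layer `l + 1` is `w^l f(x^l)` (the activation is
#' applied presynaptically; there are no bias terms).
#'
#' @param layer_sizes Integer vector of neuron counts per layer,
#'   input first, output last. At least two layers.
#' @param activation Name of the elementwise activation: `"linear"`,
#'   `"sigmoid"` or `"leaky_relu"`.
#' @param init_sd Optional fixed standard deviation for Normal(0, sd) weight
#'   initialization (used by the behavioral simulations). When `NULL`
#'   (default), Xavier initialization is used: per layer,
#'   `sd = sqrt(2 / (n_l + n_{l+1}))`.
#' @param init `"xavier_normal"` (default) or `"xavier_uniform"`; ignored
#'   when `init_sd` is supplied. The uniform variant draws from
#'   `U(-b, b)` with `b = sqrt(6 / (n_l + n_{l+1}))` (same variance).
#' @param seed Optional integer seed for reproducible initialization.
#' @param update_mask Optional list of 0/1 matrices (one per weight layer)
#'   multiplying every weight update, for structurally constrained
#'   connectivity (e.g. the one-to-one input wiring of the motor network).
#'   Masked-out weights stay at their initial value forever.
#'
#' @return An object of class `pcn_network`: a list with elements
#'   `layer_sizes`, `weights` (list of matrices), `activation`, and
#'   optionally `update_mask`.
#' @examples
#' net <- pcn_network(c(2, 4, 2), activation = "sigmoid", seed = 1)
#' predict(net, c(1, 0))
#' @export
pcn_network <- function(layer_sizes, activation = "linear", init_sd = NULL,
                        init = c("xavier_normal", "xavier_uniform"),
                        seed = NULL, update_mask = NULL) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2) {
    stop("a network needs at least an input and an output layer", call. = FALSE)
  }
  if (any(layer_sizes <= 0) || anyNA(layer_sizes)) {
    stop("all layer sizes must be positive integers", call. = FALSE)
  }
  init <- match.arg(init)
  .get_activation(activation)  # validate name early
  if (!is.null(seed)) set.seed(seed)

  L <- length(layer_sizes) - 1L
  weights <- vector("list", L)
  for (l in seq_len(L)) {
    n_in <- layer_sizes[l]
    n_out <- layer_sizes[l + 1L]
    if (!is.null(init_sd)) {
      stopifnot(init_sd >= 0)
      w <- stats::rnorm(n_out * n_in, mean = 0, sd = init_sd)
    } else if (init == "xavier_normal") {
      w <- stats::rnorm(n_out * n_in, mean = 0, sd = sqrt(2 / (n_in + n_out)))
    } else {
      b <- sqrt(6 / (n_in + n_out))
      w <- stats::runif(n_out * n_in, min = -b, max = b)
    }
    weights[[l]] <- matrix(w, nrow = n_out, ncol = n_in)
  }

  if (!is.null(update_mask)) {
    stopifnot(length(update_mask) == L)
    for (l in seq_len(L)) {
      stopifnot(all(dim(update_mask[[l]]) == dim(weights[[l]])))
      weights[[l]] <- weights[[l]] * update_mask[[l]]
    }
  }

  structure(
    list(layer_sizes = layer_sizes, weights = weights,
         activation = activation, update_mask = update_mask),
    class = "pcn_network"
  )
}

#' @export
print.pcn_network <- function(x, ...) {
  cat("Layered network (", paste(x$layer_sizes, collapse = "-"), "), ",
      length(x$weights), " weight layer(s), activation: ", x$activation,
      "\n", sep = "")
  invisible(x)
}

#' @export
coef.pcn_network <- function(object, ...) object$weights

# Coerce an input pattern to an n x B matrix of column patterns.
.as_columns <- function(x, n, what = "input") {
  if (is.matrix(x)) {
    if (nrow(x) != n) {
      stop(what, " has ", nrow(x), " rows; expected ", n, call. = FALSE)
    }
    x
  } else {
    if (length(x) != n) {
      stop(what, " has length ", length(x), "; expected ", n, call. = FALSE)
    }
    matrix(as.numeric(x), nrow = n, ncol = 1)
  }
}

# Feedforward pass returning all layer activities (list of n_l x B matrices).
.forward_activations <- function(net, X) {
  act <- .get_activation(net$activation)
  L <- length(net$weights)
  xs <- vector("list", L + 1L)
  xs[[1L]] <- X
  for (l in seq_len(L)) {
    xs[[l + 1L]] <- net$weights[[l]] %*% act$f(xs[[l]])
  }
  xs
}

#' Feedforward prediction
#'
#' Propagates an input pattern through the network:
#' `x^1 = s_in`, `x^{l+1} = w^l f(x^l)`. For a predictive coding network this
#' is the exact energy minimum when only the input is clamped (all prediction
#' errors zero), so it coincides with free-output relaxation; see
#' [pcn_relax()].
#'
#' @param object A [pcn_network()].
#' @param s_in Input pattern: numeric vector of length `n^1`, or a matrix
#'   with one column per pattern.
#' @param ... Unused.
#' @return Output activities, same shape convention as the input (vector in,
#'   vector out).
#' @export
predict.pcn_network <- function(object, s_in, ...) {
  X <- .as_columns(s_in, object$layer_sizes[1L])
  out <- .forward_activations(object, X)[[length(object$weights) + 1L]]
  if (!is.matrix(s_in)) drop(out) else out
}
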