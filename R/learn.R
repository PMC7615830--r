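#' Hebbian weight consolidation
#'
#' Applies the weight dynamics at a converged relaxation state:
#' `dw^l = alpha_l * eps^{l+1} f(x^l)^T` (an outer product of post-synaptic
#' error and pre-synaptic rate, i.e. simple Hebbian plasticity), which is
#' gradient descent on the energy with respect to the weights at fixed
#' activities. When the state holds a batch of columns the per-example
#' updates are averaged before application.
#'
#' @param net A [pcn_network()].
#' @param state A converged `pcn_state`/`pcn_relaxation` with fresh errors.
#' @param alpha Learning rate applied to every layer.
#' @param alpha_per_layer Optional numeric vector of length `L` overriding
#'   `alpha` layer by layer (the motor simulation fits independent rates
#'   for its two layers).
#' @return The updated network.
#' @export
pcn_update_weights <- function(net, state, alpha, alpha_per_layer = NULL) {
  act <- .get_activation(net$activation)
  L <- length(net$weights)
  rates <- if (is.null(alpha_per_layer)) rep(alpha, L) else {
    stopifnot(length(alpha_per_layer) == L)
    alpha_per_layer
  }
  B <- ncol(state$activities[[1L]])
  for (l in seq_len(L)) {
    dw <- rates[l] * tcrossprod(state$errors[[l + 1L]],
                                act$f(state$activities[[l]])) / B
    if (!is.null(net$update_mask)) dw <- dw * net$update_mask[[l]]
    net$weights[[l]] <- net$weights[[l]] + dw
  }
  net
}

#' Learn one pattern by prospective configuration
#'
#' The complete learning step of the predictive coding network: clamp the
#' input (and the masked output neurons to their targets), relax the
#' remaining activities to the prospective configuration with [pcn_relax()],
#' then consolidate with [pcn_update_weights()]. Free output neurons (mask
#' `FALSE`) participate in relaxation and generate their own errors, which
#' is what lets learning about one output reveal and correct prospective
#' errors on others.
#'
#' @inheritParams pcn_relax
#' @inheritParams pcn_update_weights
#' @param alpha Learning rate.
#' @return The updated network.
#' @examples
#' net <- pcn_network(c(1, 1, 2), seed = 1)
#' net2 <- pcn_learn(net, 1, target = c(0, 1), alpha = 0.2)
#' @export
pcn_learn <- function(net, s_in, target, alpha, control = relax_control(),
                      output_mask = NULL, alpha_per_layer = NULL) {
  r <- pcn_relax(net, s_in, target = target, output_mask = output_mask,
                 control = control)
  pcn_update_weights(net, r, alpha, alpha_per_layer)
}

#' Squared-error loss of the feedforward prediction
#'
#' `L = 1/2 ||s_target - x^{L+1}||^2` over unmasked outputs. With the output
#' clamped to the target and all other layers at their feedforward values,
#' this equals the top-layer local energy of the predictive coding network.
#'
#' @inheritParams bp_learn
#' @return Numeric: the loss (one value per batch column).
#' @export
mlp_loss <- function(net, s_in, target, output_mask = NULL) {
  X <- .as_columns(s_in, net$layer_sizes[1L])
  pred <- .forward_activations(net, X)[[length(net$weights) + 1L]]
  tm <- .expand_target(target, output_mask, nrow(pred), ncol(pred))
  err <- tm$target - pred
  if (!is.null(tm$mask)) err[!tm$mask] <- 0
  drop(0.5 * colSums(err^2))
}

# normalize target/mask into full-width matrices
.expand_target <- function(target, output_mask, n_out, B) {
  mask <- NULL
  if (!is.null(output_mask)) {
    mask <- if (is.matrix(output_mask)) output_mask else
      matrix(as.logical(output_mask), n_out, B)
  }
  if (is.matrix(target)) {
    stopifnot(nrow(target) == n_out)
    Tm <- target
  } else if (length(target) == n_out) {
    Tm <- matrix(target, n_out, B)
  } else if (!is.null(mask) && length(target) == sum(mask[, 1L]) && B == 1L) {
    Tm <- matrix(0, n_out, B)
    Tm[mask] <- target
  } else {
    stop("target shape does not match the network output", call. = FALSE)
  }
  list(target = Tm, mask = mask)
}

#' Backpropagation baseline
#'
#' Trains the same [pcn_network()] as a multilayer perceptron: a forward
#' pass, then one plain gradient-descent step on the squared-error loss,
#' with the error backpropagated layer by layer through the chain rule.
#' Masked-out output neurons (mask `FALSE`) contribute zero error. Batch
#' columns are averaged, mirroring the prospective-configuration
#' convention.
#'
#' @param net A [pcn_network()].
#' @param s_in Input pattern (vector or column matrix).
#' @param target Target pattern; full output width, or values for the
#'   masked-true entries only.
#' @param alpha Learning rate.
#' @param output_mask Optional logical vector/matrix; `FALSE` entries are
#'   excluded from the loss.
#' @param alpha_per_layer Optional per-layer learning rates.
#' @return The updated network.
#' @export
bp_learn <- function(net, s_in, target, alpha, output_mask = NULL,
                     alpha_per_layer = NULL) {
  act <- .get_activation(net$activation)
  L <- length(net$weights)
  rates <- if (is.null(alpha_per_layer)) rep(alpha, L) else {
    stopifnot(length(alpha_per_layer) == L)
    alpha_per_layer
  }
  X <- .as_columns(s_in, net$layer_sizes[1L])
  B <- ncol(X)
  xs <- .forward_activations(net, X)
  tm <- .expand_target(target, output_mask, net$layer_sizes[L + 1L], B)

  delta <- xs[[L + 1L]] - tm$target         # dL/dx^{L+1}
  if (!is.null(tm$mask)) delta[!tm$mask] <- 0
  new_w <- net$weights
  for (l in L:1) {
    grad_w <- tcrossprod(delta, act$f(xs[[l]])) / B   # dL/dw^l (batch mean)
    if (!is.null(net$update_mask)) grad_w <- grad_w * net$update_mask[[l]]
    if (l > 1L) {
      delta <- act$fprime(xs[[l]]) * crossprod(net$weights[[l]], delta)
    }
    new_w[[l]] <- new_w[[l]] - rates[l] * grad_w
  }
  net$weights <- new_w
  net
}

#' One weight update by either learning rule
#'
#' Convenience dispatcher used throughout the experiment harnesses: applies
#' a single learning step with prospective configuration (`rule = "pc"`,
#' [pcn_learn()]) or backpropagation (`rule = "bp"`, [bp_learn()]).
#'
#' @inheritParams pcn_learn
#' @param rule `"pc"` or `"bp"`.
#' @return The updated network.
#' @export
learn_step <- function(net, rule = c("pc", "bp"), s_in, target, alpha,
                       control = relax_control(), output_mask = NULL,
                       alpha_per_layer = NULL) {
  rule <- match.arg(rule)
  if (rule == "pc") {
    pcn_learn(net, s_in, target, alpha, control = control,
              output_mask = output_mask, alpha_per_layer = alpha_per_layer)
  } else {
    bp_learn(net, s_in, target, alpha, output_mask = output_mask,
             alpha_per_layer = alpha_per_layer)
  }
}
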