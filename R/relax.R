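#' Relaxation schedule settings
#'
#' Controls the numerical integration of the neural dynamics during
#' relaxation. By default the integration step starts at `gamma0 = 0.1` and
#' relaxation runs for at most 128 sweeps; in adaptive mode, after any sweep
#' in which the total energy did not decrease the step is halved, and
#' relaxation terminates early on the second halving (i.e. when the step
#' reaches 0.025 for the default `gamma0`). The reinforcement learning
#' configuration instead uses a fixed step (`adaptive = FALSE`,
#' `gamma0 = 0.05`, `max_steps = 32`).
#'
#' @param gamma0 Initial integration step, positive.
#' @param max_steps Maximum number of relaxation sweeps.
#' @param halving_factor Multiplier applied to the step when energy fails to
#'   decrease (adaptive mode).
#' @param max_halvings Number of halvings after which relaxation terminates
#'   early; no sweep is taken at the post-termination step size.
#' @param adaptive Logical; use the energy-monitored halving schedule.
#' @return A list of class `relax_control`.
#' @export
relax_control <- function(gamma0 = 0.1, max_steps = 128L,
                          halving_factor = 0.5, max_halvings = 2L,
                          adaptive = TRUE) {
  stopifnot(gamma0 > 0, max_steps >= 1, halving_factor > 0,
            halving_factor < 1, max_halvings >= 0)
  structure(list(gamma0 = gamma0, max_steps = as.integer(max_steps),
                 halving_factor = halving_factor,
                 max_halvings = as.integer(max_halvings),
                 adaptive = isTRUE(adaptive)),
            class = "relax_control")
}

# column-wise scaling: multiply column j of M by g[j]
.scale_cols <- function(M, g) {
  if (length(g) == 1L) return(g * M)
  M * rep(g, each = nrow(M))
}

#' Prediction errors of a network state
#'
#' Sets the error units `eps^l = x^l - w^{l-1} f(x^{l-1})` for every layer
#' `l >= 2`, given the current activities.
#'
#' @param net A [pcn_network()].
#' @param activities List of `L + 1` activity arrays (vectors or column
#'   matrices), or a state list carrying an `activities` element.
#' @return A list of class `pcn_state` with `activities` and `errors`
#'   (element 1 of `errors` is `NULL`: the input layer has no error units).
#' @export
pcn_errors <- function(net, activities) {
  if (is.list(activities) && !is.null(activities$activities)) {
    activities <- activities$activities
  }
  act <- .get_activation(net$activation)
  L <- length(net$weights)
  stopifnot(length(activities) == L + 1L)
  xs <- lapply(seq_along(activities), function(l) {
    .as_columns(activities[[l]], net$layer_sizes[l], paste0("layer ", l))
  })
  errors <- vector("list", L + 1L)
  for (l in seq_len(L)) {
    errors[[l + 1L]] <- xs[[l + 1L]] - net$weights[[l]] %*% act$f(xs[[l]])
  }
  structure(list(activities = xs, errors = errors), class = "pcn_state")
}

# per-column total energy from an error list
.energy_cols <- function(errors) {
  tot <- 0
  for (l in seq_along(errors)) {
    if (!is.null(errors[[l]])) tot <- tot + 0.5 * colSums(errors[[l]]^2)
  }
  tot
}

#' Energy of a network state
#'
#' The energy decomposes into local per-layer terms
#' `E^l = 1/2 ||x^l - w^{l-1} f(x^{l-1})||^2` (one half the squared norm of
#' the prediction error), summed over layers `2..L+1`. Both the neural
#' dynamics (relaxation) and the weight dynamics (Hebbian consolidation)
#' descend this energy.
#'
#' @param net A [pcn_network()].
#' @param state A `pcn_state` (from [pcn_errors()] or [pcn_relax()]) or a
#'   list of activities.
#' @return List of class `pcn_energy` with `per_layer` (named numeric,
#'   layers `2..L+1`, summed over any batch columns) and `total`.
#' @export
pcn_energy <- function(net, state) {
  if (is.null(state$errors)) state <- pcn_errors(net, state)
  errs <- state$errors
  per_layer <- vapply(seq_along(errs), function(l) {
    if (is.null(errs[[l]])) NA_real_ else 0.5 * sum(errs[[l]]^2)
  }, numeric(1))
  per_layer <- per_layer[-1L]
  names(per_layer) <- paste0("E", seq_along(per_layer) + 1L)
  structure(list(per_layer = per_layer, total = sum(per_layer)),
            class = "pcn_energy")
}

#' @export
print.pcn_energy <- function(x, ...) {
  cat("Total energy:", format(x$total), "\n")
  print(x$per_layer)
  invisible(x)
}

#' One sweep of the neural dynamics
#'
#' Updates every unclamped activity down the energy gradient:
#' `dx^l = gamma * (-eps^l + f'(x^l) o (w^l)^T eps^{l+1})` for hidden layers,
#' and `dx^{L+1} = -gamma * eps^{L+1}` for free output neurons (no layer
#' above). Input neurons and clamped output neurons are left unchanged.
#' Errors in the returned state are stale; recompute with [pcn_errors()].
#'
#' Exposed mainly so the dynamics can be checked against numerical gradients
#' of [pcn_energy()]; normal use goes through [pcn_relax()].
#'
#' @param net A [pcn_network()].
#' @param state A `pcn_state` whose errors were computed for its activities.
#' @param gamma Integration step (scalar, or one value per batch column).
#' @param output_clamp `NULL` (all outputs free), or a logical vector/matrix
#'   marking which output entries are clamped.
#' @return The updated `pcn_state`.
#' @export
pcn_relax_step <- function(net, state, gamma, output_clamp = NULL) {
  act <- .get_activation(net$activation)
  L <- length(net$weights)
  xs <- state$activities
  errs <- state$errors
  if (L >= 2L) {
    for (l in 2:L) {
      delta <- -errs[[l]] +
        act$fprime(xs[[l]]) * crossprod(net$weights[[l]], errs[[l + 1L]])
      xs[[l]] <- xs[[l]] + .scale_cols(delta, gamma)
    }
  }
  top <- L + 1L
  delta_top <- .scale_cols(-errs[[top]], gamma)
  if (!is.null(output_clamp)) {
    if (!is.matrix(output_clamp)) {
      output_clamp <- matrix(output_clamp, nrow = nrow(xs[[top]]),
                             ncol = ncol(xs[[top]]))
    }
    delta_top[output_clamp] <- 0
  }
  xs[[top]] <- xs[[top]] + delta_top
  structure(list(activities = xs, errors = errs), class = "pcn_state")
}

#' Relax a predictive coding network to its prospective state
#'
#' Implements inference in the energy-based network: the input layer is
#' clamped to `s_in`, clamped output neurons are fixed at their target
#' values, all remaining activities start at zero and then descend the
#' energy by iterated sweeps of the neural dynamics. At convergence the
#' hidden activities form the prospective configuration: the pattern of
#' activity the network should exhibit once learning has corrected the
#' output error. [pcn_update_weights()] then consolidates it.
#'
#' With no output clamped, relaxation converges to the feedforward
#' prediction exactly (all errors vanish); [predict.pcn_network()] computes
#' that fixed point directly.
#'
#' @param net A [pcn_network()].
#' @param s_in Input pattern (vector, or matrix with one column per
#'   pattern; each column is relaxed independently).
#' @param target Target values for clamped output neurons: vector/matrix of
#'   full output width, or of length `sum(output_mask)` when a partial mask
#'   is given. Required iff any output is clamped.
#' @param output_mask Logical vector (length `n^{L+1}`) or matrix marking
#'   clamped output neurons. `NULL` with a target clamps all outputs;
#'   `NULL` without a target leaves all outputs free.
#' @param control A [relax_control()].
#' @return An object of class `pcn_relaxation`: a `pcn_state` (activities
#'   and freshly computed errors) plus `energy_trace` (matrix, one row per
#'   recorded state including the initial one), `gamma` (final per-column
#'   integration step), `halvings`, `steps` (sweeps executed) and
#'   `terminated_early`.
#' @examples
#' net <- pcn_network(c(2, 3, 2), seed = 1)
#' r <- pcn_relax(net, c(1, 0), target = c(0, 1))
#' pcn_energy(net, r)$total
#' @export
pcn_relax <- function(net, s_in, target = NULL, output_mask = NULL,
                      control = relax_control()) {
  act <- .get_activation(net$activation)
  L <- length(net$weights)
  sizes <- net$layer_sizes
  X <- .as_columns(s_in, sizes[1L])
  B <- ncol(X)
  n_out <- sizes[L + 1L]

  # resolve clamping
  if (is.null(output_mask)) {
    clamp <- if (is.null(target)) NULL else matrix(TRUE, n_out, B)
  } else {
    if (!is.matrix(output_mask)) {
      stopifnot(length(output_mask) == n_out)
      clamp <- matrix(as.logical(output_mask), n_out, B)
    } else clamp <- output_mask
    if (any(clamp) && is.null(target)) {
      stop("target required when output neurons are clamped", call. = FALSE)
    }
    if (!any(clamp)) clamp <- NULL
  }

  # initial state: hidden layers and free outputs at 0, clamped at target
  xs <- vector("list", L + 1L)
  xs[[1L]] <- X
  for (l in 2:(L + 1L)) xs[[l]] <- matrix(0, sizes[l], B)
  if (!is.null(clamp)) {
    Tm <- matrix(0, n_out, B)
    if (is.matrix(target)) {
      stopifnot(nrow(target) == n_out, ncol(target) == B)
      Tm <- target
    } else if (length(target) == n_out) {
      Tm <- matrix(target, n_out, B)
    } else if (length(target) == sum(clamp[, 1L]) && B == 1L) {
      Tm[clamp] <- target
    } else {
      stop("target length does not match the clamped outputs", call. = FALSE)
    }
    xs[[L + 1L]][clamp] <- Tm[clamp]
  }

  # inner loop kept free of per-sweep object wrapping for speed
  W <- net$weights
  f <- act$f
  fprime <- act$fprime
  top <- L + 1L
  fx1 <- f(xs[[1L]])
  errs <- vector("list", top)
  compute_errors <- function() {
    errs[[2L]] <<- xs[[2L]] - W[[1L]] %*% fx1
    if (L >= 2L) {
      for (l in 2:L) errs[[l + 1L]] <<- xs[[l + 1L]] - W[[l]] %*% f(xs[[l]])
    }
  }
  energy_now <- function() {
    tot <- 0
    for (l in 2:top) tot <- tot + 0.5 * colSums(errs[[l]]^2)
    tot
  }

  compute_errors()
  E <- energy_now()
  trace <- list(E)
  gamma <- rep(control$gamma0, B)
  halvings <- integer(B)
  active <- rep(TRUE, B)
  steps <- 0L
  single <- B == 1L

  while (steps < control$max_steps && any(active)) {
    g <- if (single) gamma else gamma * active
    if (L >= 2L) {
      for (l in 2:L) {
        delta <- -errs[[l]] + fprime(xs[[l]]) * crossprod(W[[l]], errs[[l + 1L]])
        xs[[l]] <- xs[[l]] + .scale_cols(delta, g)
      }
    }
    if (is.null(clamp)) {
      xs[[top]] <- xs[[top]] - .scale_cols(errs[[top]], g)
    } else if (!all(clamp)) {
      delta_top <- .scale_cols(-errs[[top]], g)
      delta_top[clamp] <- 0
      xs[[top]] <- xs[[top]] + delta_top
    }
    steps <- steps + 1L
    for (l in 2:top) {
      if (any(!is.finite(xs[[l]]))) {
        stop("relaxation diverged at step ", steps,
             " (non-finite activity in layer ", l, ")", call. = FALSE)
      }
    }
    compute_errors()
    E_new <- energy_now()
    trace[[steps + 1L]] <- E_new
    if (control$adaptive) {
      stalled <- active & (E_new >= E)
      if (any(stalled)) {
        gamma[stalled] <- gamma[stalled] * control$halving_factor
        halvings[stalled] <- halvings[stalled] + 1L
        active[halvings >= control$max_halvings] <- FALSE
      }
    }
    E <- E_new
  }

  out <- structure(list(activities = xs, errors = errs),
                   class = "pcn_state")
  out$energy_trace <- do.call(rbind, trace)
  out$gamma <- gamma
  out$halvings <- halvings
  out$steps <- steps
  out$terminated_early <- !any(active) && steps < control$max_steps
  out$output_clamp <- clamp
  class(out) <- c("pcn_relaxation", "pcn_state")
  out
}

#' @export
print.pcn_relaxation <- function(x, ...) {
  cat("Relaxation: ", x$steps, " sweep(s), final energy ",
      format(sum(x$energy_trace[nrow(x$energy_trace), ])),
      if (x$terminated_early) ", terminated early" else "", "\n", sep = "")
  invisible(x)
}
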