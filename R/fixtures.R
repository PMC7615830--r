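#' The 1-1-2 "bear" fixture
#'
#' The minimal interference example: one input neuron (seeing the river)
#' drives one hidden neuron, which predicts two outputs (hearing the water,
#' smelling the salmon). All weights start at 1, the input is `[1]` and the
#' target is `[0, 1]`: the first prediction must be unlearned while the
#' second is already correct. Trained with backpropagation the correct
#' output is dragged down before recovering; prospective configuration
#' first infers the lower prospective hidden activity, reveals a positive
#' error on the correct output, and increases its weight on the very first
#' iteration.
#'
#' @return A list with `net` (linear 1-1-2 network, unit weights),
#'   `pattern` (a `PatternPair`: `s_in`, `s_target`), the learning rate
#'   `alpha = 0.2` and `iterations = 24` used in the reference protocol.
#' @examples
#' fx <- bear_fixture()
#' predict(fx$net, fx$pattern$s_in)  # c(1, 1)
#' @export
bear_fixture <- function() {
  net <- pcn_network(c(1, 1, 2), activation = "linear", init_sd = 0)
  net$weights[[1]][] <- 1
  net$weights[[2]][] <- 1
  list(net = net,
       pattern = list(s_in = 1, s_target = c(0, 1)),
       alpha = 0.2,
       iterations = 24L)
}

#' Random input/target pattern pair
#'
#' Entries i.i.d. Normal(0, 1), reproducible by seed.
#'
#' @param in_size,out_size Pattern lengths.
#' @param seed Optional integer seed.
#' @return List with `s_in` and `s_target`.
#' @export
random_pattern_pair <- function(in_size, out_size, seed = NULL) {
  stopifnot(in_size >= 1, out_size >= 1)
  if (!is.null(seed)) set.seed(seed)
  list(s_in = stats::rnorm(in_size), s_target = stats::rnorm(out_size))
}

#' Random deep linear network
#'
#' `depth` weight layers between equal-width layers of linear neurons,
#' Xavier-initialized; the building block of the alignment depth sweep.
#'
#' @param depth Number of weight layers (>= 1).
#' @param seed Optional integer seed.
#' @param width Neurons per layer.
#' @param init Passed to [pcn_network()].
#' @return A [pcn_network()].
#' @export
deep_linear_fixture <- function(depth, seed = NULL, width = 64,
                                init = "xavier_normal") {
  stopifnot(depth >= 1)
  pcn_network(rep(width, depth + 1L), activation = "linear",
              init = init, seed = seed)
}

#' Synthetic Gaussian-blob classification data
#'
#' Balanced multi-class data for exercising the batched training loop:
#' each class is an isotropic Gaussian blob whose center is drawn on a
#' sphere of radius `separation`, targets are one-hot. A desk-scale
#' stand-in for image benchmarks; it makes no claim to reproduce any
#' benchmark numbers.
#'
#' @param n_per_class Training examples per class.
#' @param n_test_per_class Test examples per class.
#' @param classes Number of classes.
#' @param dim Input dimensionality.
#' @param separation Distance of class centers from the origin.
#' @param noise_sd Within-class standard deviation.
#' @param seed Optional integer seed.
#' @return A list of class `synthetic_dataset` with `train` and `test`,
#'   each holding `x` (`dim x n` matrix), `y` (`classes x n` one-hot
#'   matrix) and `labels` (integer class per example), plus `class_count`.
#' @export
synthetic_blobs <- function(n_per_class = 20, n_test_per_class = 10,
                            classes = 2, dim = 4, separation = 3,
                            noise_sd = 1, seed = NULL) {
  stopifnot(classes >= 2, n_per_class >= 1, dim >= 1)
  if (!is.null(seed)) set.seed(seed)
  centers <- matrix(stats::rnorm(dim * classes), dim, classes)
  centers <- apply(centers, 2, function(v) separation * v / sqrt(sum(v^2)))
  make_split <- function(n_each) {
    labels <- rep(seq_len(classes), each = n_each)
    x <- centers[, labels, drop = FALSE] +
      matrix(stats::rnorm(dim * length(labels), sd = noise_sd),
             dim, length(labels))
    y <- matrix(0, classes, length(labels))
    y[cbind(labels, seq_along(labels))] <- 1
    ord <- sample(length(labels))
    list(x = x[, ord, drop = FALSE], y = y[, ord, drop = FALSE],
         labels = labels[ord])
  }
  structure(list(train = make_split(n_per_class),
                 test = make_split(n_test_per_class),
                 class_count = classes),
            class = "synthetic_dataset")
}

#' Minibatch training loop
#'
#' Generic supervised training shared by both rules: per iteration, one
#' weight update from a minibatch (per-example updates averaged); per
#' epoch, a pass over the shuffled training set followed by evaluation of
#' the classification test error (fraction of argmax-mismatched examples).
#' `batch_size = 1` gives the online-learning regime where every experience
#' triggers a weight update.
#'
#' @param net A [pcn_network()] whose input/output widths match the data.
#' @param rule `"pc"` or `"bp"`.
#' @param dataset A [synthetic_blobs()]-style dataset.
#' @param alpha Learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Number of epochs.
#' @param seed Optional seed controlling the shuffling.
#' @param control Relaxation settings for `"pc"`.
#' @return A list with `test_error` (per-epoch trace), `mean_test_error`,
#'   `min_test_error` and the trained `net`.
#' @export
train_loop <- function(net, rule = c("pc", "bp"), dataset, alpha,
                       batch_size = 32, epochs = 10, seed = NULL,
                       control = relax_control()) {
  rule <- match.arg(rule)
  if (!is.null(seed)) set.seed(seed)
  x <- dataset$train$x
  y <- dataset$train$y
  n <- ncol(x)
  stopifnot(n >= 1)
  test_error <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    starts <- seq(1, n, by = batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1, n)]
      net <- learn_step(net, rule, x[, idx, drop = FALSE],
                        y[, idx, drop = FALSE], alpha, control = control)
    }
    pred <- predict(net, dataset$test$x)
    guess <- apply(pred, 2, which.max)
    truth <- apply(dataset$test$y, 2, which.max)
    test_error[ep] <- mean(guess != truth)
  }
  list(test_error = test_error,
       mean_test_error = mean(test_error),
       min_test_error = min(test_error),
       net = net)
}
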