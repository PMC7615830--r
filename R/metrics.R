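#' Target alignment
#'
#' Interference metric: the cosine of the angle between the direction from
#' the current output toward the target (`target - y_before`) and the
#' direction the output actually moved after one learning step
#' (`y_after - y_before`), both measured as free predictions. A value of 1
#' means learning moved the output straight at the target (no
#' interference); lower values mean weight updates for some outputs
#' degraded others.
#'
#' @param y_before Free prediction before the weight update.
#' @param y_after Free prediction after the weight update.
#' @param target Target pattern.
#' @return Cosine in `[-1, 1]`, or `NA` when either direction vector has
#'   zero norm (alignment undefined; deliberately not reported as 0).
#' @examples
#' target_alignment(c(1, 1), c(0.5, 1), c(0, 1))
#' @export
target_alignment <- function(y_before, y_after, target) {
  u <- as.numeric(target) - as.numeric(y_before)
  v <- as.numeric(y_after) - as.numeric(y_before)
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  sum(u * v) / (nu * nv)
}

#' Measure one learning step of either rule
#'
#' The measurement harness behind the interference comparisons: record the
#' free (unclamped) prediction, apply a single weight update with the chosen
#' rule, record the free prediction again, and compute the target alignment
#' between the two predictions and the target. The input network is not
#' modified; a copy is trained.
#'
#' @inheritParams learn_step
#' @return A list with `y_before`, `y_after`, `alignment`, `loss_before`,
#'   `loss_after`, and the trained network copy (`net_after`).
#' @export
measure_learning_step <- function(net, rule = c("pc", "bp"), s_in, target,
                                  alpha, control = relax_control()) {
  rule <- match.arg(rule)
  y_before <- predict(net, s_in)
  trained <- learn_step(net, rule, s_in, target, alpha, control = control)
  y_after <- predict(trained, s_in)
  list(
    y_before = y_before,
    y_after = y_after,
    alignment = target_alignment(y_before, y_after, target),
    loss_before = mlp_loss(net, s_in, target),
    loss_after = mlp_loss(trained, s_in, target),
    net_after = trained
  )
}

#' Target-alignment depth sweep
#'
#' Repeats the single-step interference measurement on randomly generated
#' linear networks of increasing depth: width-64 layers, Xavier-initialized
#' weights, a single random input/target pattern pair with Normal(0, 1)
#' entries, one weight update at `alpha = 0.001`, free predictions before
#' and after. Backpropagation's alignment degrades with depth because
#' updates in different layers interfere; prospective configuration stays
#' close to 1.
#'
#' @param depths Integer vector of weight-layer counts to test.
#' @param n_reps Repetitions (fresh network and pattern) per depth.
#' @param alpha Learning rate for the single update.
#' @param width Neurons per layer (all layers, input and output included).
#' @param rules Character vector of rules to run.
#' @param seed Base seed; repetition `r` at any depth uses `seed + r` so
#'   both rules see identical networks and patterns.
#' @param control Relaxation settings for the `pc` rule.
#' @return A data frame with columns `depth`, `rep`, `rule`, `alignment`.
#' @export
alignment_depth_sweep <- function(depths = 1:25, n_reps = 27, alpha = 0.001,
                                  width = 64, rules = c("pc", "bp"),
                                  seed = 1, control = relax_control()) {
  rows <- vector("list", length(depths) * n_reps * length(rules))
  k <- 0L
  for (d in depths) {
    for (r in seq_len(n_reps)) {
      net <- deep_linear_fixture(depth = d, seed = seed + r, width = width)
      pat <- random_pattern_pair(width, width, seed = seed + 1000L + r)
      for (rule in rules) {
        m <- measure_learning_step(net, rule, pat$s_in, pat$s_target,
                                   alpha = alpha, control = control)
        k <- k + 1L
        rows[[k]] <- data.frame(depth = d, rep = r, rule = rule,
                                alignment = m$alignment)
      }
    }
  }
  do.call(rbind, rows[seq_len(k)])
}
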