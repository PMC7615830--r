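#' Trial schedule for the contextual sensorimotor learning simulation
#'
#' Builds the full per-participant trial sequence of the two-context motor
#' adaptation experiment. Backgrounds B and R signal contexts paired during
#' training with opposite perturbations (B+ and R-). The training stage has
#' 24 blocks, each following a fixed recipe: a B0/R0 pair (order
#' counterbalanced across consecutive blocks), 32 perturbation trials with
#' equal numbers of B+ and R- within every consecutive 8 in pseudorandom
#' order, another B0/R0 pair, `n <- {14, 16, 18}` washout trials, a triplet
#' whose exposure trial is B+ or R- (counterbalanced across consecutive
#' blocks), `n <- {6, 8, 10}` further washout trials, and a second triplet
#' with whichever exposure the first did not use. `n <- {a, b, c}` denotes
#' sampling without replacement, replenishing the set when it empties.
#' The testing stage has 8 repetitions of 4 blocks (one per test
#' combination B+, R+, B-, R-; block order shuffled per repetition), each
#' block being `n <- {2, 4, 6}` washout trials followed by a triplet whose
#' exposure is the block's combination. A triplet is B0 / exposure / B0;
#' the two B0 probes measure single-trial learning.
#'
#' Washout trials contain equal numbers of B0 and R0 in pseudorandom order.
#'
#' @param seed Integer seed for the schedule's randomness.
#' @param participant Participant index; its parity sets the starting arm
#'   of the counterbalanced orderings.
#' @return A data frame with one row per trial: `trial`, `session`
#'   (`"training"`/`"testing"`), `block`, `background` (`"B"`/`"R"`),
#'   `perturbation` (`"+"`, `"-"`, `"0"`), `role` (`"pair"`, `"standard"`,
#'   `"washout"`, `"triplet_pre"`, `"triplet_exposure"`, `"triplet_post"`),
#'   `combination` (testing blocks only, else `NA`).
#' @export
motor_schedule <- function(seed = 1, participant = 1) {
  set.seed(seed)
  pools <- list(w1 = integer(0), w2 = integer(0), wt = integer(0))
  draw_pool <- function(which, full) {
    if (length(pools[[which]]) == 0L) pools[[which]] <<- sample(full)
    n <- pools[[which]][1L]
    pools[[which]] <<- pools[[which]][-1L]
    n
  }
  rows <- list()
  push <- function(session, block, background, perturbation, role,
                   combination = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      session = session, block = block, background = background,
      perturbation = perturbation, role = role, combination = combination)
  }
  washout <- function(session, block, n) {
    bgs <- sample(rep(c("B", "R"), n / 2))
    for (bg in bgs) push(session, block, bg, "0", "washout")
  }
  triplet <- function(session, block, exposure, combination = NA_character_) {
    bg <- substr(exposure, 1, 1)
    pert <- substr(exposure, 2, 2)
    push(session, block, "B", "0", "triplet_pre", combination)
    push(session, block, bg, pert, "triplet_exposure", combination)
    push(session, block, "B", "0", "triplet_post", combination)
  }

  # training stage: 24 blocks
  for (b in seq_len(24L)) {
    pair <- if ((b + participant) %% 2 == 0) c("B", "R") else c("R", "B")
    arm1 <- if ((b + participant) %% 2 == 0) "B+" else "R-"
    arm2 <- setdiff(c("B+", "R-"), arm1)
    for (bg in pair) push("training", b, bg, "0", "pair")
    for (g in 1:4) {                     # 32 perturbation trials, 4 x 8
      eight <- sample(rep(c("B+", "R-"), 4))
      for (tt in eight) {
        push("training", b, substr(tt, 1, 1), substr(tt, 2, 2), "standard")
      }
    }
    for (bg in pair) push("training", b, bg, "0", "pair")
    washout("training", b, draw_pool("w1", c(14L, 16L, 18L)))
    triplet("training", b, arm1)
    washout("training", b, draw_pool("w2", c(6L, 8L, 10L)))
    triplet("training", b, arm2)
  }

  # testing stage: 8 repetitions x 4 combinations
  combos <- c("B+", "R+", "B-", "R-")
  blk <- 24L
  for (rep_i in seq_len(8L)) {
    for (cmb in sample(combos)) {
      blk <- blk + 1L
      washout("testing", blk, draw_pool("wt", c(2L, 4L, 6L)))
      triplet("testing", blk, cmb, combination = cmb)
    }
  }

  out <- do.call(rbind, rows)
  out$trial <- seq_len(nrow(out))
  out[, c("trial", "session", "block", "background", "perturbation",
          "role", "combination")]
}

#' Minimal network for the motor learning simulation
#'
#' A 2-2-2 linear network: two input neurons encode the background colors
#' (B, R), two hidden neurons the belief of being in the corresponding
#' context, and two output neurons the predicted perturbation in the two
#' directions. The input-to-hidden wiring is one-to-one (the off-diagonal
#' weights are structurally zero and never updated); hidden-to-output is
#' fully connected. Weights start at Normal(0, `init_sd`), modelling
#' participants with no prior associations.
#'
#' @param seed Optional integer seed.
#' @param init_sd Standard deviation of the initial weights.
#' @return A [pcn_network()] with a diagonal update mask on layer 1.
#' @export
motor_network <- function(seed = NULL, init_sd = 0.01) {
  pcn_network(c(2, 2, 2), activation = "linear", init_sd = init_sd,
              seed = seed,
              update_mask = list(diag(2), matrix(1, 2, 2)))
}

.motor_input <- function(background) {
  if (background == "B") c(1, 0) else c(0, 1)
}

.motor_target <- function(perturbation) {
  switch(perturbation, "+" = c(1, 0), "-" = c(0, 1), "0" = c(0, 0))
}

#' Run the contextual motor learning experiment
#'
#' Simulates `n_participants` runs through the full [motor_schedule()],
#' training a fresh [motor_network()] on every trial with the chosen rule
#' (inputs: B = `[1,0]`, R = `[0,1]`; targets: `+` = `[1,0]`, `-` =
#' `[0,1]`, no perturbation = `[0,0]`). On the two B0 probe trials of each
#' testing triplet, the free-prediction perturbation (the difference
#' between the two output activities) is recorded before the trial's
#' learning step; the adaptation change of the triplet is the absolute
#' difference of the two probes. Changes are averaged over the 8
#' repetitions of each test combination and over participants.
#'
#' @param rule `"pc"` or `"bp"`.
#' @param init_sd Initial weight standard deviation. The defaults here and
#'   for the learning rates are the best-fit grid values from the package's
#'   exhaustive search against the shipped approximate comparison data.
#' @param lr_input,lr_output Learning rates for the input-to-hidden and
#'   hidden-to-output layers (fitted independently; the perception-to-belief
#'   and belief-to-prediction pathways need not be equally plastic).
#' @param n_participants Number of simulated participants.
#' @param seed Base seed; participant `p` derives its own schedule and
#'   network seeds from it.
#' @param control Relaxation settings for `"pc"`.
#' @return A list with `mean_change` (named numeric over the four test
#'   combinations), `per_participant` (participants x combinations
#'   matrix), and the call parameters.
#' @export
run_motor_experiment <- function(rule = c("pc", "bp"), init_sd = 0.05,
                                 lr_input = 5e-4, lr_output = 0.01,
                                 n_participants = 24, seed = 1,
                                 control = relax_control()) {
  rule <- match.arg(rule)
  combos <- c("B+", "R+", "B-", "R-")
  per_part <- matrix(NA_real_, n_participants, length(combos),
                     dimnames = list(NULL, combos))
  alphas <- c(lr_input, lr_output)
  for (p in seq_len(n_participants)) {
    sched <- motor_schedule(seed = seed + 2L * p, participant = p)
    net <- motor_network(seed = seed + 2L * p + 1L, init_sd = init_sd)
    probes <- list()          # per testing triplet: pre/post predictions
    pre_val <- NA_real_
    for (i in seq_len(nrow(sched))) {
      tr <- sched[i, ]
      s_in <- .motor_input(tr$background)
      tgt <- .motor_target(tr$perturbation)
      if (tr$session == "testing" &&
          tr$role %in% c("triplet_pre", "triplet_post")) {
        out <- predict(net, s_in)
        pred <- out[1] - out[2]
        if (tr$role == "triplet_pre") {
          pre_val <- pred
        } else {
          probes[[length(probes) + 1L]] <-
            list(combination = tr$combination, change = abs(pred - pre_val))
        }
      }
      net <- learn_step(net, rule, s_in, tgt, alpha = 1,
                        control = control, alpha_per_layer = alphas)
    }
    ch <- vapply(probes, function(x) x$change, numeric(1))
    cb <- vapply(probes, function(x) x$combination, character(1))
    per_part[p, ] <- vapply(combos, function(cc) mean(ch[cb == cc]),
                            numeric(1))
  }
  list(mean_change = colMeans(per_part),
       per_participant = per_part,
       rule = rule, init_sd = init_sd,
       lr_input = lr_input, lr_output = lr_output, seed = seed)
}

#' Analytic scale (and bias) fit of model values to behavioral data
#'
#' The model's per-condition values `x` live on a different scale than the
#' behavioral/neural data `d`, so the fit objective is
#' `sum((a * x + b - d)^2)` with the scale `a` restricted to be
#' non-negative and the bias `b` used only where the data have an
#' arbitrary baseline (the reversal task's fMRI signal). Both are resolved
#' analytically: without bias `a = max(0, sum(x d) / sum(x^2))`; with bias,
#' ordinary least squares, with `a` clipped at zero and `b` refit as
#' `mean(d)` in that case.
#'
#' @param x Per-condition model values.
#' @param d Per-condition data values (same length).
#' @param with_bias Include the intercept `b`.
#' @return A list with `a`, `b` (`NULL` when `with_bias = FALSE`) and
#'   `objective` (the residual sum of squares).
#' @export
fit_scale <- function(x, d, with_bias = FALSE) {
  stopifnot(length(x) == length(d))
  if (all(x == 0)) {
    stop("degenerate fit: model values are all zero", call. = FALSE)
  }
  if (!with_bias) {
    a <- max(0, sum(x * d) / sum(x^2))
    list(a = a, b = NULL, objective = sum((a * x - d)^2))
  } else {
    xc <- x - mean(x)
    a <- if (sum(xc^2) == 0) 0 else sum(xc * (d - mean(d))) / sum(xc^2)
    if (a < 0) a <- 0
    b <- mean(d) - a * mean(x)
    list(a = a, b = b, objective = sum((a * x + b - d)^2))
  }
}

#' Exhaustive grid-search fit of a learning rule to behavioral data
#'
#' Runs the chosen simulation at every combination of the parameter grids,
#' fits the analytic scale (and bias, for the reversal task) against the
#' supplied per-condition data, and returns the grid point minimizing the
#' residual objective. Deterministic given `seed`: every grid point uses
#' the same participant seeds.
#'
#' @param rule `"pc"` or `"bp"`.
#' @param task `"motor"` or `"reversal"`.
#' @param data Named numeric of per-condition data values `d_c`; names must
#'   match the conditions produced by the simulation (motor: `B+`, `R+`,
#'   `B-`, `R-`; reversal: `punish_stay`, `stay`, `punish_switch`,
#'   `switch`).
#' @param grids Named list of parameter vectors. Motor: `init_sd`,
#'   `lr_input`, `lr_output`. Reversal: `init_sd`, `alpha`.
#' @param n_participants Participants per evaluation.
#' @param seed Base seed shared by all grid points.
#' @param control Relaxation settings for `"pc"`.
#' @param ... Further arguments passed to the experiment runner.
#' @return A list with `best` (list: `params`, `fit`, `model_values`) and
#'   `results` (data frame of every grid point and its objective).
#' @export
grid_search_fit <- function(rule = c("pc", "bp"),
                            task = c("motor", "reversal"),
                            data, grids, n_participants = NULL, seed = 1,
                            control = relax_control(), ...) {
  rule <- match.arg(rule)
  task <- match.arg(task)
  stopifnot(length(grids) >= 1, all(lengths(grids) >= 1))
  if (is.null(n_participants)) {
    n_participants <- if (task == "motor") 24L else 16L
  }
  grid <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  results <- grid
  results$objective <- NA_real_
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    g <- as.list(grid[i, , drop = FALSE])
    if (task == "motor") {
      run <- run_motor_experiment(rule, init_sd = g$init_sd,
                                  lr_input = g$lr_input,
                                  lr_output = g$lr_output,
                                  n_participants = n_participants,
                                  seed = seed, control = control, ...)
      x <- run$mean_change
      fit <- fit_scale(x[names(data)], data, with_bias = FALSE)
    } else {
      run <- run_reversal_experiment(rule, init_sd = g$init_sd,
                                     alpha = g$alpha,
                                     n_participants = n_participants,
                                     seed = seed, control = control, ...)
      x <- run$mean_signal
      fit <- fit_scale(x[names(data)], data, with_bias = TRUE)
    }
    results$objective[i] <- fit$objective
    if (is.null(best) || fit$objective < best$fit$objective) {
      best <- list(params = g, fit = fit, model_values = x)
    }
  }
  list(best = best, results = results)
}
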