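#' Probabilistic reversal learning environment
#'
#' A stateful two-option reward sampler. On every trial the chosen option
#' pays +1 (reward) with its current probability and -1 (punishment)
#' otherwise. The two probabilities are anti-correlated: every
#' `reversal_period` trials they swap, so when one increases the other
#' decreases by the same amount and their sum is conserved at
#' `p_high + p_low` throughout. The task's latent structure (which option
#' is currently superior) is what the hidden neuron of the minimal network
#' can come to encode.
#'
#' @param p_high,p_low Reward probabilities of the better and worse
#'   option (`0 <= p_low < p_high <= 1`).
#' @param reversal_period Trials between probability swaps.
#' @return A list with functions `outcome(choice)` (advances one trial and
#'   returns +1/-1), `probs()` (current per-option reward probabilities)
#'   and `trial()` (trials elapsed).
#' @export
reversal_environment <- function(p_high = 0.8, p_low = 0.2,
                                 reversal_period = 20) {
  stopifnot(p_low >= 0, p_high <= 1, p_low < p_high, reversal_period >= 1)
  trial <- 0L
  current_probs <- function(t) {
    if (((t - 1L) %/% reversal_period) %% 2L == 0L) c(p_high, p_low)
    else c(p_low, p_high)
  }
  list(
    outcome = function(choice) {
      stopifnot(choice %in% c(1L, 2L))
      trial <<- trial + 1L
      p <- current_probs(trial)[choice]
      if (stats::runif(1) < p) 1 else -1
    },
    probs = function() current_probs(trial + 1L),
    trial = function() trial
  )
}

#' Softmax choice probabilities and sampling
#'
#' `P(i) = exp(v_i / T) / sum_j exp(v_j / T)`.
#'
#' @param values Numeric vector of option values.
#' @param temperature Softmax temperature (the simulations use 1).
#' @return `softmax_probs()`: the probability vector. `softmax_choice()`:
#'   one sampled option index.
#' @export
softmax_probs <- function(values, temperature = 1) {
  stopifnot(all(is.finite(values)), temperature > 0)
  z <- values / temperature
  e <- exp(z - max(z))
  e / sum(e)
}

#' @rdname softmax_probs
#' @export
softmax_choice <- function(values, temperature = 1) {
  sample.int(length(values), 1, prob = softmax_probs(values, temperature))
}

#' Run the reversal reinforcement learning experiment
#'
#' Each simulated participant gets a fresh 1-1-2 linear network (one input
#' neuron fixed at 1 encoding "being in the task", one hidden neuron for
#' the latent state, two output neurons for the option values). On every
#' trial the model predicts both option values (free prediction), chooses
#' by softmax (temperature 1), receives +1/-1 from the
#' [reversal_environment()], and takes one learning step with the chosen
#' option's output clamped to the outcome; under `"pc"` the other output
#' is left free so relaxation can update it through the shared hidden
#' neuron, while under `"bp"` its error is masked out. The chosen option's
#' predicted value (recorded before learning) is the model's counterpart
#' of the value signal.
#'
#' Afterwards, every consecutive pair of trials whose first member was
#' punished is classified by whether the same option was chosen next
#' (`stay`) or the other one (`switch`), yielding four averaged signals:
#' the punished trial and its successor for each case, pooled over all
#' trials and participants.
#'
#' @param rule `"pc"` or `"bp"`.
#' @param init_sd Initial weight standard deviation. The default is the
#'   best-fit value from the package's grid search against the shipped
#'   approximate comparison data.
#' @param alpha Learning rate (default likewise the fitted value).
#' @param n_participants Simulated participants.
#' @param n_trials Trials per participant.
#' @param p_high,p_low,reversal_period Passed to [reversal_environment()].
#' @param seed Base seed; participant `p` uses `seed + p`.
#' @param control Relaxation settings for `"pc"`.
#' @return A list with `mean_signal` (named numeric: `punish_stay`,
#'   `stay`, `punish_switch`, `switch`), `n_per_type`, and `trials` (data
#'   frame of participant, trial, choice, outcome, signal).
#' @export
run_reversal_experiment <- function(rule = c("pc", "bp"), init_sd = 0.1,
                                    alpha = 0.05, n_participants = 16,
                                    n_trials = 128, p_high = 0.8,
                                    p_low = 0.2, reversal_period = 20,
                                    seed = 1, control = relax_control()) {
  rule <- match.arg(rule)
  recs <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    set.seed(seed + p)
    net <- pcn_network(c(1, 1, 2), activation = "linear", init_sd = init_sd)
    env <- reversal_environment(p_high, p_low, reversal_period)
    choice <- integer(n_trials)
    outcome <- numeric(n_trials)
    signal <- numeric(n_trials)
    for (t in seq_len(n_trials)) {
      values <- predict(net, 1)
      choice[t] <- softmax_choice(values)
      outcome[t] <- env$outcome(choice[t])
      signal[t] <- values[choice[t]]
      mask <- seq_len(2) == choice[t]
      target <- ifelse(mask, outcome[t], 0)
      net <- learn_step(net, rule, 1, target, alpha,
                        control = control, output_mask = mask)
    }
    recs[[p]] <- data.frame(participant = p, trial = seq_len(n_trials),
                            choice = choice, outcome = outcome,
                            signal = signal)
  }
  trials <- do.call(rbind, recs)

  sig <- list(punish_stay = numeric(0), stay = numeric(0),
              punish_switch = numeric(0), switch = numeric(0))
  for (p in seq_len(n_participants)) {
    d <- trials[trials$participant == p, ]
    for (t in seq_len(nrow(d) - 1L)) {
      if (d$outcome[t] == -1) {
        if (d$choice[t + 1L] == d$choice[t]) {
          sig$punish_stay <- c(sig$punish_stay, d$signal[t])
          sig$stay <- c(sig$stay, d$signal[t + 1L])
        } else {
          sig$punish_switch <- c(sig$punish_switch, d$signal[t])
          sig$switch <- c(sig$switch, d$signal[t + 1L])
        }
      }
    }
  }
  list(mean_signal = vapply(sig, mean, numeric(1)),
       n_per_type = vapply(sig, length, integer(1)),
       trials = trials,
       rule = rule, init_sd = init_sd, alpha = alpha, seed = seed)
}
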