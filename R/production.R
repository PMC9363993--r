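#' Experience-weighted value update
#'
#' One step of the reinforcement-learning value function: the expected value
#' of a behaviour moves towards the reward just received,
#' `rho * reward + (1 - rho) * e_prev`. Behaviours in the repertoire that
#' were not produced receive reward 0, so unused behaviours lose value over
#' time. Starting from 0 and producing every step with unit reward, the value
#' after n productions is `1 - (1 - rho)^n`; the true reward is a fixed point
#' and an upper bound.
#'
#' @param e_prev previous expected value(s).
#' @param reward reward(s) received at the last timestep (0 if the behaviour
#'   was not produced).
#' @param rho recent experience bias in (0, 1).
#' @return Updated expected value(s), same length as `e_prev`.
#' @export
update_expected_value <- function(e_prev, reward, rho) {
  if (rho <= 0 || rho >= 1) stop("rho must lie strictly in (0, 1)")
  rho * reward + (1 - rho) * e_prev
}

#' Individual choice probabilities (softmax)
#'
#' Converts the expected values of the behaviours in an agent's repertoire
#' into choice probabilities with a softmax at temperature `alpha`:
#' `I_k = exp(E_k / alpha) / sum_k exp(E_k / alpha)`. Probabilities are
#' strictly positive, so a behaviour with zero expected value can still be
#' produced.
#'
#' @param expected named numeric vector of expected values, one entry per
#'   behaviour in the repertoire.
#' @param alpha risk-appetite (softmax temperature), positive.
#' @return Named probability vector summing to 1.
#' @export
individual_probabilities <- function(expected, alpha = 1) {
  if (length(expected) == 0) stop("repertoire is empty")
  if (alpha <= 0) stop("alpha must be positive")
  w <- exp(expected / alpha)
  w / sum(w)
}

#' Frequency-dependent social observation weights
#'
#' Counts productions of each behaviour in the agent's own repertoire by its
#' network neighbours within the memory window, raises the counts to the
#' power `f` and normalizes. Behaviours outside the repertoire are invisible
#' to the agent. `0^f` is taken as 0, so a behaviour never observed in the
#' window gets weight 0 whenever any other count is positive; if every count
#' is zero the weights fall back to the uniform distribution over the
#' repertoire (no social signal).
#'
#' @param agent observing agent index.
#' @param net a [social_network()].
#' @param history a production history matrix (timestep x agent) of
#'   behaviour labels, as recorded by [run_simulation()].
#' @param t current timestep; the window covers the last `m` completed
#'   timesteps `t - m, ..., t - 1` (see `window_mode`).
#' @param m memory window length.
#' @param f frequency-dependent production bias exponent.
#' @param repertoire character vector of behaviours the agent knows.
#' @param window_mode `"m"` (default) uses the last `m` completed timesteps;
#'   `"m_plus_1"` uses the last `m + 1` completed timesteps (the literal
#'   m+1-index reading of the window sum).
#' @return Named weight vector over `repertoire` summing to 1.
#' @export
social_frequencies <- function(agent, net, history, t, m, f,
                               repertoire = c("a", "b"),
                               window_mode = c("m", "m_plus_1")) {
  window_mode <- match.arg(window_mode)
  span <- if (window_mode == "m") m else m + 1
  rows <- seq.int(max(1, t - span), min(t - 1, nrow(history)))
  nb <- agent_neighbors(net, agent)
  counts <- if (t <= 1 || length(rows) == 0 || rows[1] > rows[length(rows)]) {
    stats::setNames(rep(0, length(repertoire)), repertoire)
  } else {
    obs <- history[rows, nb, drop = FALSE]
    vapply(repertoire, function(k) sum(obs == k), numeric(1))
  }
  social_weights_from_counts(counts, f)
}

#' @param counts named vector of in-repertoire neighbour production counts.
#' @rdname social_frequencies
#' @export
social_weights_from_counts <- function(counts, f) {
  if (all(counts == 0)) {
    return(stats::setNames(
      rep(1 / length(counts), length(counts)),
      names(counts)
    ))
  }
  w <- counts^f
  w / sum(w)
}

#' Mix individual and social information into production probabilities
#'
#' `P_k = (1 - sigma) * I_k + sigma * S_k` over the agent's repertoire. With
#' `sigma = 0` social information is ignored; with `sigma = 1` personal
#' experience is ignored.
#'
#' @param individual named probability vector from
#'   [individual_probabilities()].
#' @param social named weight vector from [social_frequencies()].
#' @param sigma social information bias in \[0, 1\].
#' @return Named probability vector summing to 1.
#' @export
production_probabilities <- function(individual, social, sigma) {
  if (!identical(sort(names(individual)), sort(names(social)))) {
    stop("individual and social probabilities cover different behaviours")
  }
  (1 - sigma) * individual + sigma * social[names(individual)]
}

#' Draw one behaviour to produce
#'
#' A single categorical draw from a production probability vector.
#'
#' @param probabilities named probability vector summing to 1.
#' @return One behaviour label.
#' @export
choose_behaviour <- function(probabilities) {
  if (length(probabilities) == 1) return(names(probabilities))
  sample(names(probabilities), 1, prob = probabilities)
}
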