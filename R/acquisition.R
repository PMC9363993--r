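#' Transmission weight of an agent
#'
#' The proportion of the memory window in which an agent produced the novel
#' behaviour: (productions of "b" in the window) / m. Naive agents, having
#' never produced "b", always have weight 0.
#'
#' @param agent producing agent index.
#' @param history production history matrix (timestep x agent).
#' @param t current timestep.
#' @param m memory window length; the divisor is always `m`.
#' @param window_mode see [social_frequencies()].
#' @return Weight in \[0, 1\] (up to `(m + 1) / m` under `"m_plus_1"`).
#' @export
transmission_weight <- function(agent, history, t, m,
                                window_mode = c("m", "m_plus_1")) {
  window_mode <- match.arg(window_mode)
  span <- if (window_mode == "m") m else m + 1
  rows <- seq.int(max(1, t - span), min(t - 1, nrow(history)))
  if (t <= 1 || length(rows) == 0) return(0)
  sum(history[rows, agent] == "b") / m
}

#' Transmission function
#'
#' Social exposure of one agent: `T_i = s * sum_j a_ij * w_j`, the
#' transmission-rate-scaled sum of the transmission weights of the agent's
#' network neighbours.
#'
#' @param agent focal (naive) agent index.
#' @param net a [social_network()].
#' @param weights per-agent transmission weights (length `n_agents`).
#' @param s social transmission rate, non-negative.
#' @export
transmission_function <- function(agent, net, weights, s) {
  if (s < 0) stop("s must be non-negative")
  s * sum(net$adjacency[agent, ] * weights)
}

#' Per-timestep acquisition probability
#'
#' `P(acquire) = 1 - exp(-lambda_b * (T + A))`: a discrete-time hazard that
#' is zero when there is neither social exposure nor asocial innovation, and
#' strictly increasing in the exposure `T`.
#'
#' @param T_i social exposure from [transmission_function()].
#' @param lambda_b baseline learning rate.
#' @param asocial asocial innovation flag A (0 or 1).
#' @export
acquisition_probability <- function(T_i, lambda_b, asocial = 0) {
  if (any(T_i < 0)) stop("transmission function must be non-negative")
  1 - exp(-lambda_b * (T_i + asocial))
}

#' One acquisition sweep over the population
#'
#' Draws one independent Bernoulli acquisition event per naive agent, using
#' the production history up to timestep `t - 1`. Acquiring agents add the
#' novel behaviour to their repertoire with expected value 0 (its value must
#' be learned through the agent's own productions).
#'
#' @param knows_b logical vector: which agents already know "b".
#' @param net a [social_network()].
#' @param history production history matrix up to row `t - 1`.
#' @param t current timestep.
#' @param params a [constellation()].
#' @param window_mode see [social_frequencies()].
#' @return List with `knows_b` (updated) and `acquired` (indices of agents
#'   acquiring at this timestep).
#' @export
acquisition_step <- function(knows_b, net, history, t, params,
                             window_mode = c("m", "m_plus_1")) {
  window_mode <- match.arg(window_mode)
  naive <- which(!knows_b)
  if (length(naive) == 0) {
    return(list(knows_b = knows_b, acquired = integer(0)))
  }
  w <- vapply(
    seq_along(knows_b),
    function(j) transmission_weight(j, history, t, params$m, window_mode),
    numeric(1)
  )
  exposure <- as.numeric(net$adjacency[naive, , drop = FALSE] %*% w) * params$s
  p <- acquisition_probability(exposure, params$lambda_b, params$A)
  acquired <- naive[stats::runif(length(naive)) < p]
  knows_b[acquired] <- TRUE
  list(knows_b = knows_b, acquired = acquired)
}
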