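#' Run one linked acquisition + production simulation
#'
#' Drives the full generative model: every timestep, each naive agent may
#' acquire the novel behaviour "b" through social transmission from
#' neighbours that recently produced it (and/or asocial innovation), and
#' every agent then produces one behaviour from its repertoire according to
#' the reinforcement-learning production rules. The two sub-models are linked
#' through the production history: observed productions drive both the
#' transmission weights and the social term of the production mixture.
#'
#' Timesteps are 1-based. All agents start with repertoire \{"a"\} and
#' expected value 1 for "a"; under the default seeding one uniformly random
#' agent additionally knows "b" from the start (time of acquisition 0, so it
#' is always first in the acquisition order) with expected value 0. Within a
#' timestep, productions are drawn first and the acquisition sweep (which
#' uses productions up to `t - 1`) follows, so a newly knowledgeable agent
#' first produces "b" no earlier than the next timestep; see `acquire_first`
#' for the alternative ordering.
#'
#' @param params a [constellation()].
#' @param net a [social_network()]; by default a fresh connected random
#'   regular network with the constellation's `N` and `k` is drawn.
#' @param rng_seed optional integer seed for the whole run (network included
#'   when `net` is NULL).
#' @param stop stopping rule: `"completion"` (default) stops once every agent
#'   has both acquired and produced "b" at least once; `"fixed"` runs exactly
#'   `horizon` timesteps; `"twice_ttd"` runs until twice the time-to-diffusion
#'   (used for recording production series for inference).
#' @param horizon number of timesteps for `stop = "fixed"`.
#' @param max_steps hard cap; a run that has not met its stopping rule by
#'   then is returned with `converged = FALSE` rather than an error.
#' @param seed_agent `"random"` seeds one knowledgeable agent; `"none"`
#'   starts with every agent naive (asocial-innovation scenarios).
#' @param initial_repertoire `"seeded"` (default) or `"full"`, in which case
#'   every agent knows both behaviours from the start (no acquisition
#'   dynamics) with initial expected values `e_init`.
#' @param e_init named vector of initial expected values used for
#'   `initial_repertoire = "full"`.
#' @param window_mode memory window convention, see [social_frequencies()].
#' @param acquire_first if `TRUE`, the acquisition sweep at `t` runs before
#'   production, so a newly knowledgeable agent may produce "b" in the same
#'   timestep. The default (`FALSE`) draws productions first: an agent
#'   acquiring at `t` can first produce "b" at `t + 1`.
#' @param ideal_weights if `TRUE`, transmission weights are replaced by the
#'   knowledge indicator (1 for every knowledgeable neighbour), removing the
#'   influence of production on transmission (pure diffusion dynamics).
#' @param record_probs if `TRUE`, the per-timestep probability of producing
#'   "b" for every agent is kept in the record (for likelihood replay
#'   checks).
#' @return An object of class `diffusion_record`: a list with per-agent
#'   times `t_a`, `t_p`, ranks `o_a`, `o_p`, the `history` matrix
#'   (timestep x agent, labels "a"/"b"), `seed_agent`, `ttd`, `ttfp`,
#'   `converged`, `n_steps`, the constellation and the network.
#' @export
run_simulation <- function(params, net = NULL, rng_seed = NULL,
                           stop = c("completion", "fixed", "twice_ttd"),
                           horizon = NULL, max_steps = 10000,
                           seed_agent = c("random", "none"),
                           initial_repertoire = c("seeded", "full"),
                           e_init = c(a = 1, b = 1),
                           window_mode = c("m", "m_plus_1"),
                           acquire_first = FALSE,
                           ideal_weights = FALSE,
                           record_probs = FALSE) {
  stop <- match.arg(stop)
  seed_agent <- match.arg(seed_agent)
  initial_repertoire <- match.arg(initial_repertoire)
  window_mode <- match.arg(window_mode)
  if (stop == "fixed" && is.null(horizon)) stop("fixed stop needs a horizon")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.null(net)) net <- generate_random_regular(params$N, params$k)
  N <- net$n_agents
  adj <- net$adjacency
  m <- params$m
  span <- if (window_mode == "m") m else m + 1

  knows_b <- rep(FALSE, N)
  t_a <- rep(NA_real_, N)
  t_p <- rep(NA_real_, N)
  E_a <- rep(1, N)
  E_b <- rep(0, N)
  seed <- NA_integer_
  if (initial_repertoire == "full") {
    knows_b[] <- TRUE
    t_a[] <- 0
    E_a[] <- e_init[["a"]]
    E_b[] <- e_init[["b"]]
  } else if (seed_agent == "random") {
    seed <- sample.int(N, 1)
    knows_b[seed] <- TRUE
    t_a[seed] <- 0
  }

  cap <- 512L
  hist <- matrix(0L, cap, N) # 1 = "a", 2 = "b"
  prob_b_log <- if (record_probs) matrix(NA_real_, cap, N) else NULL
  cnt_a <- rep(0, N) # per-agent productions in the sliding window
  cnt_b <- rep(0, N)
  ttd <- NA_real_
  track_acquisition <- initial_repertoire == "seeded"
  converged <- FALSE
  t <- 0L

  repeat {
    t <- t + 1L
    if (t > cap) {
      cap2 <- cap * 2L
      h2 <- matrix(0L, cap2, N)
      h2[seq_len(cap), ] <- hist
      hist <- h2
      if (record_probs) {
        p2 <- matrix(NA_real_, cap2, N)
        p2[seq_len(cap), ] <- prob_b_log
        prob_b_log <- p2
      }
      cap <- cap2
    }
    # slide the observation window: add t-1, drop t-span-1
    if (t >= 2) {
      prev <- hist[t - 1L, ]
      cnt_a <- cnt_a + (prev == 1L)
      cnt_b <- cnt_b + (prev == 2L)
    }
    if (t - span - 1L >= 1L) {
      old <- hist[t - span - 1L, ]
      cnt_a <- cnt_a - (old == 1L)
      cnt_b <- cnt_b - (old == 2L)
    }

    do_acquisition <- function() {
      naive <- which(!knows_b)
      if (length(naive) == 0) return()
      w <- if (ideal_weights) as.numeric(knows_b) else cnt_b / m
      exposure <- params$s * as.numeric(adj[naive, , drop = FALSE] %*% w)
      p <- 1 - exp(-params$lambda_b * (exposure + params$A))
      hit <- naive[stats::runif(length(naive)) < p]
      if (length(hit)) {
        knows_b[hit] <<- TRUE
        t_a[hit] <<- t
        E_b[hit] <<- 0
      }
    }
    if (track_acquisition && acquire_first) do_acquisition()

    # value update from t-1 rewards, then softmax / social mixture
    if (t >= 2) {
      prev <- hist[t - 1L, ]
      E_a <- params$rho * params$r_a * (prev == 1L) + (1 - params$rho) * E_a
      E_b <- params$rho * params$r_b * (prev == 2L) + (1 - params$rho) * E_b
    }
    ew_a <- exp(E_a / params$alpha)
    ew_b <- exp(E_b / params$alpha)
    I_b <- ifelse(knows_b, ew_b / (ew_a + ew_b), 0)
    obs_a <- as.numeric(adj %*% cnt_a)
    obs_b <- as.numeric(adj %*% cnt_b)
    wa <- obs_a^params$f
    wb <- obs_b^params$f
    tot <- wa + wb
    S_b <- ifelse(knows_b, ifelse(tot > 0, wb / tot, 0.5), 0)
    P_b <- ifelse(
      knows_b,
      (1 - params$sigma) * I_b + params$sigma * S_b,
      0
    )
    produced_b <- stats::runif(N) < P_b
    hist[t, ] <- ifelse(produced_b, 2L, 1L)
    if (record_probs) prob_b_log[t, ] <- P_b
    t_p[produced_b & is.na(t_p)] <- t

    if (track_acquisition && !acquire_first) do_acquisition()

    if (track_acquisition && is.na(ttd) && all(knows_b)) ttd <- max(t_a)
    done <- switch(stop,
      completion = all(knows_b) && !anyNA(t_p),
      fixed = t >= horizon,
      twice_ttd = !is.na(ttd) && t >= 2 * ttd
    )
    if (done) {
      converged <- TRUE
      break
    }
    if (t >= max_steps) break
  }

  history <- matrix(c("a", "b")[hist[seq_len(t), , drop = FALSE]], t, N)
  o_a <- if (!anyNA(t_a)) rank_events(t_a) else rep(NA_integer_, N)
  o_p <- if (!anyNA(t_p)) rank_events(t_p) else rep(NA_integer_, N)
  structure(
    list(
      t_a = t_a, t_p = t_p, o_a = o_a, o_p = o_p,
      history = history,
      prob_b = if (record_probs) prob_b_log[seq_len(t), , drop = FALSE],
      seed_agent = seed,
      ttd = if (track_acquisition) ttd else NA_real_,
      ttfp = if (!anyNA(t_p)) max(t_p) else NA_real_,
      converged = converged,
      n_steps = t,
      params = params,
      net = net,
      rng_seed = rng_seed
    ),
    class = "diffusion_record"
  )
}

#' @export
print.diffusion_record <- function(x, ...) {
  cat(sprintf(
    "<diffusion_record> %d agents, %d timesteps, TTD %s, TTFP %s%s\n",
    length(x$t_a), x$n_steps, format(x$ttd), format(x$ttfp),
    if (x$converged) "" else " [did not converge]"
  ))
  invisible(x)
}

#' Rank event times with random tie-breaking
#'
#' Converts per-agent event times into ranks 1..N. Agents with identical
#' times receive distinct consecutive ranks, assigned uniformly at random
#' among the tied set (reproducible under the session RNG state).
#'
#' @param times numeric vector of event times (all finite).
#' @return Integer vector of ranks, a permutation of `1:length(times)`.
#' @export
rank_events <- function(times) {
  if (anyNA(times)) stop("all event times must be finite")
  as.integer(rank(times, ties.method = "random"))
}

#' Export a production history as long-format CSV
#'
#' Columns `timestep`, `agent` (1-based), `behaviour`.
#'
#' @param record a `diffusion_record`.
#' @param path file path.
#' @export
write_history <- function(record, path) {
  h <- record$history
  df <- data.frame(
    timestep = rep(seq_len(nrow(h)), ncol(h)),
    agent = rep(seq_len(ncol(h)), each = nrow(h)),
    behaviour = as.vector(h)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export acquisition and first-production events as CSV
#'
#' Columns `agent`, `time_of_acquisition`, `time_of_first_production`.
#'
#' @inheritParams write_history
#' @export
write_events <- function(record, path) {
  df <- data.frame(
    agent = seq_along(record$t_a),
    time_of_acquisition = record$t_a,
    time_of_first_production = record$t_p
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
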