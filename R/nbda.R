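#' Diffusion event data for time-of-acquisition analysis
#'
#' Bundles the inputs of a continuous time-of-acquisition diffusion analysis
#' (TADAc): per-agent continuous event times, the association network,
#' the set of demonstrators (agents treated as knowledgeable from time 0,
#' contributing to hazards but providing no event), and per-agent
#' transmission weights (1 for ideal data; the static production rate of the
#' novel behaviour for realistic data).
#'
#' @param event_times numeric vector, one entry per agent; `NA` for
#'   demonstrators.
#' @param net a [social_network()].
#' @param demonstrators integer indices of demonstrator agents.
#' @param weights per-agent transmission weights in \[0, 1\].
#' @return An object of class `nbda_data`.
#' @export
nbda_data <- function(event_times, net, demonstrators = integer(0),
                      weights = rep(1, length(event_times))) {
  stopifnot(length(event_times) == net$n_agents)
  if (any(!is.na(event_times[demonstrators]))) {
    stop("demonstrators must not have event times")
  }
  learners <- setdiff(seq_along(event_times), demonstrators)
  if (anyNA(event_times[learners])) stop("learners must have event times")
  if (any(event_times[learners] <= 0)) stop("event times must be positive")
  structure(
    list(
      event_times = event_times, net = net,
      demonstrators = as.integer(demonstrators), weights = weights
    ),
    class = "nbda_data"
  )
}

# Continuous event times from discrete acquisition timesteps: events in
# timestep t get times in (t-1, t), jittered uniformly, with the
# within-timestep order matching the random-tie-break ranks.
jitter_event_times <- function(discrete_t, ranks = rank_events(discrete_t)) {
  out <- numeric(length(discrete_t))
  for (t in unique(discrete_t)) {
    idx <- which(discrete_t == t)
    u <- sort(stats::runif(length(idx)))
    out[idx[order(ranks[idx])]] <- t - 1 + u
  }
  out
}

#' Generate ideal time-of-acquisition data
#'
#' Runs the acquisition sub-model in isolation with asocial innovation
#' enabled (A = 1). Under `mechanism = "social"` the transmission weight of
#' every knowledgeable agent is fixed at 1 (removing the influence of
#' production on transmission) and one random seed agent is knowledgeable
#' from the start, acting as a demonstrator. Under `"asocial"` the social
#' rate is 0 and every agent is naive at the start, so all acquisitions are
#' innovations with a constant per-timestep hazard.
#'
#' @param mechanism `"social"` or `"asocial"`.
#' @param params a [constellation()]; `lambda_b` and (for social) `s` are
#'   used.
#' @param net a [social_network()]; defaults to a fresh random regular
#'   network.
#' @param rng_seed optional integer seed.
#' @return An [nbda_data()] with jittered continuous event times.
#' @export
generate_ideal_data <- function(mechanism = c("social", "asocial"),
                                params = reference_constellation(),
                                net = NULL, rng_seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.null(net)) net <- generate_random_regular(params$N, params$k)
  N <- net$n_agents
  s <- if (mechanism == "social") params$s else 0
  knows <- rep(FALSE, N)
  demonstrators <- integer(0)
  if (mechanism == "social") {
    demonstrators <- sample.int(N, 1)
    knows[demonstrators] <- TRUE
  }
  t_acq <- rep(NA_real_, N)
  t <- 0L
  while (any(!knows) && t < 1e5) {
    t <- t + 1L
    naive <- which(!knows)
    exposure <- s * as.numeric(
      net$adjacency[naive, , drop = FALSE] %*% as.numeric(knows)
    )
    p <- 1 - exp(-params$lambda_b * (exposure + 1))
    hit <- naive[stats::runif(length(naive)) < p]
    knows[hit] <- TRUE
    t_acq[hit] <- t
  }
  learners <- setdiff(seq_len(N), demonstrators)
  times <- rep(NA_real_, N)
  times[learners] <- jitter_event_times(t_acq[learners])
  nbda_data(times, net, demonstrators, weights = rep(1, N))
}

#' Generate realistic time-of-first-production data
#'
#' Runs the full linked model with asocial innovation enabled (A = 1) and
#' records each agent's time of first production of the novel behaviour as
#' its observed event time. Under `mechanism = "social"` transmission
#' operates at the constellation's rate `s` with production-rate weights and
#' a random seed agent (included as a demonstrator); under `"asocial"` the
#' social rate is 0 and all acquisitions are innovations. The per-agent
#' static weight supplied to the inferential model is the agent's total
#' number of productions of "b" divided by the number of timesteps it was
#' knowledgeable.
#'
#' @inheritParams generate_ideal_data
#' @return An [nbda_data()] with jittered continuous first-production times
#'   and production-rate weights; the underlying `diffusion_record` is
#'   attached as attribute `"record"`.
#' @export
generate_realistic_data <- function(mechanism = c("social", "asocial"),
                                    params = reference_constellation(),
                                    net = NULL, rng_seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.null(net)) net <- generate_random_regular(params$N, params$k)
  run_params <- params
  run_params$A <- 1
  if (mechanism == "asocial") run_params$s <- 0
  rec <- run_simulation(
    run_params, net,
    seed_agent = if (mechanism == "social") "random" else "none"
  )
  if (!rec$converged) {
    stop("simulation hit the step cap before completing the diffusion")
  }
  N <- net$n_agents
  n_b <- colSums(rec$history == "b")
  steps_known <- rec$n_steps - rec$t_a
  weights <- ifelse(steps_known > 0, n_b / steps_known, 0)
  demonstrators <- if (mechanism == "social") rec$seed_agent else integer(0)
  learners <- setdiff(seq_len(N), demonstrators)
  times <- rep(NA_real_, N)
  times[learners] <- jitter_event_times(
    rec$t_p[learners],
    rank_events(rec$t_p)[learners]
  )
  out <- nbda_data(times, net, demonstrators, weights)
  attr(out, "record") <- rec
  out
}

# Per-(naive agent, timestep) exposures for the step-likelihood: the social
# sum SS evaluated at the start of each timestep, with knowledge states
# updating at step boundaries (sources become active the step after their
# event step; demonstrators from the start). Returns the flattened exposure
# vector, an event indicator aligned with it, and n.
ctada_step_stats <- function(data) {
  net <- data$net
  N <- net$n_agents
  times <- data$event_times
  steps <- ceiling(times) # event's timestep
  learners <- which(!is.na(times))
  t_max <- max(steps[learners])
  z <- rep(0, N)
  z[data$demonstrators] <- 1
  naive <- rep(TRUE, N)
  naive[data$demonstrators] <- FALSE
  SS_all <- vector("list", t_max)
  event_all <- vector("list", t_max)
  for (t in seq_len(t_max)) {
    idx <- which(naive)
    SS <- as.numeric(
      net$adjacency[idx, , drop = FALSE] %*% (data$weights * z)
    )
    ev <- !is.na(steps[idx]) & steps[idx] == t
    SS_all[[t]] <- SS
    event_all[[t]] <- ev
    hit <- idx[ev]
    naive[hit] <- FALSE
    z[hit] <- 1
  }
  list(
    SS = unlist(SS_all), event = unlist(event_all), n = length(learners)
  )
}

ctada_step_loglik <- function(st, lambda0, s) {
  h <- lambda0 * (s * st$SS + 1)
  sum(log1p(-exp(-h[st$event]))) - sum(h[!st$event])
}

# Sufficient statistics of the piecewise-constant-hazard likelihood.
# Between events the hazard of naive agent i is
#   lambda_i = lambda0 * (s * SS_i + 1),  SS_i = sum_j a_ij w_j z_j,
# with z_j the knowledge indicator (demonstrators from time 0, learners from
# their event time). Returns n (events), C0 = total naive exposure time,
# C1 = weighted naive exposure time, h = SS of each acquiring agent at its
# event.
ctada_stats <- function(data) {
  net <- data$net
  N <- net$n_agents
  times <- data$event_times
  learners <- which(!is.na(times))
  ord <- learners[order(times[learners])]
  tau <- times[ord]
  z <- rep(0, N)
  z[data$demonstrators] <- 1
  wz <- data$weights * z
  SS <- as.numeric(net$adjacency %*% wz)
  naive <- !logical(N)
  naive[data$demonstrators] <- FALSE
  C0 <- 0
  C1 <- 0
  h <- numeric(length(ord))
  t_prev <- 0
  for (e in seq_along(ord)) {
    dt <- tau[e] - t_prev
    C0 <- C0 + sum(naive) * dt
    C1 <- C1 + sum(SS[naive]) * dt
    h[e] <- SS[ord[e]]
    j <- ord[e]
    naive[j] <- FALSE
    SS <- SS + net$adjacency[, j] * data$weights[j]
    t_prev <- tau[e]
  }
  list(n = length(ord), C0 = C0, C1 = C1, h = h)
}

#' Log-likelihood of the continuous time-of-acquisition model
#'
#' Piecewise-constant-hazard event likelihood: between events, naive agent i
#' has hazard `lambda0 * (s * SS_i + 1)` where `SS_i` is the weighted number
#' of knowledgeable neighbours; the likelihood is the product over
#' inter-event intervals of the survival terms times the hazard of each
#' acquiring agent at its event. The asocial model fixes `s = 0`, so every
#' naive agent has constant hazard `lambda0`.
#'
#' Under `form = "step"` the same hazard is instead integrated over unit
#' timesteps, with knowledge states updating at step boundaries and the
#' event term `log(1 - exp(-hazard))` — the exact likelihood of a
#' discrete-timestep diffusion with tied event times. Simultaneously
#' acquired agents then share identical exposures, as in the generative
#' process.
#'
#' @param data an [nbda_data()].
#' @param lambda0 baseline rate, positive.
#' @param s social transmission rate, non-negative (ignored for
#'   `model = "asocial"`).
#' @param model `"social"` or `"asocial"`.
#' @param form `"event"` for the continuous event-time likelihood, `"step"`
#'   for the tie-grouped per-timestep likelihood.
#' @return Log-likelihood value.
#' @export
ctada_loglik <- function(data, lambda0, s = 0,
                         model = c("social", "asocial"),
                         form = c("event", "step")) {
  model <- match.arg(model)
  form <- match.arg(form)
  if (lambda0 < 0 || s < 0) stop("rates must be non-negative")
  if (model == "asocial") s <- 0
  if (lambda0 == 0) return(-Inf)
  if (form == "step") {
    return(ctada_step_loglik(ctada_step_stats(data), lambda0, s))
  }
  st <- ctada_stats(data)
  st$n * log(lambda0) + sum(log(s * st$h + 1)) -
    lambda0 * (s * st$C1 + st$C0)
}

#' Maximum-likelihood TADAc fit
#'
#' Fits the social (`lambda0`, `s`) or asocial (`lambda0`) time-of-
#' acquisition model by maximum likelihood, under either form of
#' [ctada_loglik()]. AICc is `-2 logL + 2K + 2K(K+1)/(n - K - 1)` with `n`
#' the number of acquisition events among initially naive agents.
#'
#' Under `form = "step"` (the default, matching tie-grouped discrete event
#' times) the asocial model has a closed-form MLE and the social model is
#' maximized by bounded quasi-Newton on the log scale from several starts;
#' the asocial solution is always included as an `s = 0` candidate, so the
#' nested social fit never falls below the asocial one. Under
#' `form = "event"`, `lambda0` is profiled out analytically
#' (`lambda0_hat(s) = n / (s * C1 + C0)`), leaving a bounded
#' one-dimensional search over `log10(s)` plus the `s = 0` boundary.
#'
#' @param data an [nbda_data()] with at least 2 events.
#' @param model `"social"` or `"asocial"`.
#' @param form likelihood form, see [ctada_loglik()].
#' @param s_range log10 search bounds for the social transmission rate.
#' @return An object of class `nbda_fit` with `lambda0_hat`, `s_hat`
#'   (social only), `log_likelihood`, `k_params`, `aicc`, `n_events`.
#' @export
fit_tadac <- function(data, model = c("social", "asocial"),
                      form = c("step", "event"), s_range = c(-4, 5)) {
  model <- match.arg(model)
  form <- match.arg(form)
  k <- if (model == "social") 2L else 1L
  if (form == "event") {
    st <- ctada_stats(data)
    n <- st$n
    if (n - k - 1 <= 0) stop("too few events for an AICc-corrected fit")
    profile_ll <- function(s) {
      lam <- n / (s * st$C1 + st$C0)
      n * log(lam) + sum(log(s * st$h + 1)) - n
    }
    if (model == "asocial") {
      s_hat <- NA_real_
      ll <- profile_ll(0)
    } else {
      opt <- stats::optimize(
        function(u) profile_ll(10^u),
        interval = s_range, maximum = TRUE, tol = 1e-8
      )
      cand_s <- c(0, 10^opt$maximum)
      cand_ll <- c(profile_ll(0), opt$objective)
      best <- which.max(cand_ll)
      s_hat <- cand_s[best]
      ll <- cand_ll[best]
    }
    lambda0_hat <- n / (ifelse(is.na(s_hat), 0, s_hat) * st$C1 + st$C0)
  } else {
    st <- ctada_step_stats(data)
    n <- st$n
    if (n - k - 1 <= 0) stop("too few events for an AICc-corrected fit")
    # closed-form asocial MLE: constant per-step acquisition probability
    p_hat <- n / length(st$SS)
    lam_aso <- -log(1 - p_hat)
    ll_aso <- ctada_step_loglik(st, lam_aso, 0)
    if (model == "asocial") {
      s_hat <- NA_real_
      lambda0_hat <- lam_aso
      ll <- ll_aso
    } else {
      nll <- function(par) {
        -ctada_step_loglik(st, exp(par[1]), exp(par[2]))
      }
      starts <- list(
        c(log(0.05), log(5)), c(log(lam_aso), log(1)),
        c(log(0.01), log(50))
      )
      fits <- lapply(starts, function(p0) {
        tryCatch(
          stats::optim(p0, nll, method = "L-BFGS-B",
                       lower = c(-14, s_range[1] * log(10)),
                       upper = c(3, s_range[2] * log(10))),
          error = function(e) NULL
        )
      })
      fits <- fits[!vapply(fits, is.null, logical(1))]
      vals <- vapply(fits, `[[`, numeric(1), "value")
      best <- fits[[which.min(vals)]]
      if (-best$value >= ll_aso) {
        lambda0_hat <- exp(best$par[1])
        s_hat <- exp(best$par[2])
        ll <- -best$value
      } else { # boundary: social model collapses to the asocial optimum
        lambda0_hat <- lam_aso
        s_hat <- 0
        ll <- ll_aso
      }
    }
  }
  aicc <- -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  structure(
    list(
      model = model, lambda0_hat = lambda0_hat, s_hat = s_hat,
      log_likelihood = ll, k_params = k, aicc = aicc, n_events = n,
      form = form
    ),
    class = "nbda_fit"
  )
}

#' @export
print.nbda_fit <- function(x, ...) {
  cat(sprintf(
    "<nbda_fit> %s model: lambda0 = %.5g%s, logL = %.3f, AICc = %.3f (n = %d)\n",
    x$model, x$lambda0_hat,
    if (x$model == "social") sprintf(", s = %.5g", x$s_hat) else "",
    x$log_likelihood, x$aicc, x$n_events
  ))
  invisible(x)
}

#' AICc model comparison
#'
#' `delta = AICc_asocial - AICc_social`; positive values support social
#' transmission, ties and negative values support asocial innovation.
#'
#' @param social,asocial `nbda_fit`s of both models on the same data.
#' @return List with `delta_aicc` and `support` ("social" or "asocial").
#' @export
delta_aicc <- function(social, asocial) {
  stopifnot(social$model == "social", asocial$model == "asocial")
  d <- asocial$aicc - social$aicc
  list(delta_aicc = d, support = if (d > 0) "social" else "asocial")
}
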