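test_that("the HPDI is the narrowest interval with the requested mass", {
  set.seed(15)
  u <- runif(20000)
  h <- hpdi(u, 0.92)
  expect_equal(h[2] - h[1], 0.92, tolerance = 0.02)
  expect_gte(h[1], min(u))
  expect_lte(h[2], max(u))
  expect_equal(hpdi(rep(0.4, 100)), c(0.4, 0.4))
  # a skewed sample's HPDI hugs the mode, unlike the central interval
  x <- rbeta(20000, 1, 8)
  hx <- hpdi(x, 0.92)
  ci <- quantile(x, c(0.04, 0.96))
  expect_lt(hx[2] - hx[1], ci[[2]] - ci[[1]])
  expect_lt(hx[1], ci[[1]])
  expect_error(hpdi(runif(10)), "50")
})

test_that("likelihood replay reproduces the engine's probabilities exactly", {
  params <- reference_constellation()
  rec <- run_simulation(params, rng_seed = 5, record_probs = TRUE)
  P <- ewa_replay_probs(
    rec$history, rec$net, rec$t_a, params$rho, params$sigma,
    f = params$f, alpha = params$alpha, m = params$m, repertoire = "realized"
  )
  expect_lt(max(abs(P - rec$prob_b)), 1e-12)
  # and for the homogeneous-repertoire dynamic
  rec2 <- run_simulation(
    params,
    rng_seed = 6, stop = "fixed", horizon = 120, seed_agent = "none",
    initial_repertoire = "full", e_init = c(a = 1, b = 1),
    record_probs = TRUE
  )
  P2 <- ewa_replay_probs(
    rec2$history, rec2$net, rec2$t_a, params$rho, params$sigma,
    repertoire = "full", e_init = c(a = 1, b = 1)
  )
  expect_lt(max(abs(P2 - rec2$prob_b)), 1e-12)
})

test_that("trivial repertoires contribute zero log-likelihood", {
  net <- cycle_net(4)
  hist <- matrix("a", 30, 4)
  # nobody ever knows b: every choice has probability 1
  ll <- ewa_choice_loglik(
    hist, net, knowledge = rep(Inf, 4), rho = 0.3, sigma = 0.7
  )
  expect_equal(ll, 0)
  expect_error(
    ewa_choice_loglik(
      matrix("b", 5, 4), net, knowledge = rep(Inf, 4), rho = 0.3, sigma = 0.5
    ),
    "repertoire"
  )
})

test_that("the generating parameters beat distant ones on average", {
  params <- reference_constellation()
  params$rho <- 0.5
  params$sigma <- 0.5
  diffs <- vapply(1:20, function(i) {
    rec <- run_simulation(
      params,
      rng_seed = 400 + i, stop = "fixed", horizon = 60,
      seed_agent = "none", initial_repertoire = "full",
      e_init = c(a = 1, b = 1)
    )
    at_truth <- ewa_choice_loglik(
      rec$history, rec$net, rec$t_a, 0.5, 0.5,
      repertoire = "full", e_init = c(a = 1, b = 1)
    )
    far <- ewa_choice_loglik(
      rec$history, rec$net, rec$t_a, 0.95, 0.05,
      repertoire = "full", e_init = c(a = 1, b = 1)
    )
    at_truth - far
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("the posterior equals the prior when the data are uninformative", {
  net <- cycle_net(4)
  hist <- matrix("a", 5, 4)
  fit <- fit_ewa(
    hist, net, knowledge = rep(Inf, 4),
    chains = 2, iter = 12000, warmup = 2000, rng_seed = 77
  )
  # thin to near-independent draws before the distributional check
  for (par in c("rho", "sigma")) {
    draws <- fit$draws[seq(1, nrow(fit$draws), by = 5), par]
    ks <- suppressWarnings(stats::ks.test(draws, "punif"))
    expect_lt(unname(ks$statistic), 0.05)
  }
})

test_that("posteriors contract as the recording lengthens", {
  params <- reference_constellation()
  params$rho <- 0.5
  params$sigma <- 0.5
  width <- function(horizon, seed) {
    rec <- run_simulation(
      params,
      rng_seed = seed, stop = "fixed", horizon = horizon,
      seed_agent = "none", initial_repertoire = "full",
      e_init = c(a = 1, b = 1)
    )
    fit <- fit_ewa(
      rec$history, rec$net, rec$t_a,
      repertoire = "full", e_init = c(a = 1, b = 1),
      chains = 2, iter = 900, warmup = 300, rng_seed = seed
    )
    mean(c(
      fit$hpdi_92$rho[2] - fit$hpdi_92$rho[1],
      fit$hpdi_92$sigma[2] - fit$hpdi_92$sigma[1]
    ))
  }
  short <- vapply(1:10, function(i) width(50, 500 + i), numeric(1))
  long <- vapply(1:10, function(i) width(200, 600 + i), numeric(1))
  expect_lt(mean(long), mean(short))
})

test_that("sampler diagnostics are reported and flag convergence", {
  params <- reference_constellation()
  rec <- run_simulation(
    params,
    rng_seed = 9, stop = "fixed", horizon = 150, seed_agent = "none",
    initial_repertoire = "full", e_init = c(a = 1, b = 1)
  )
  fit <- fit_ewa(
    rec$history, rec$net, rec$t_a,
    repertoire = "full", e_init = c(a = 1, b = 1),
    chains = 3, iter = 1500, warmup = 500, rng_seed = 3
  )
  expect_named(fit$rhat, c("rho", "sigma"))
  expect_true(all(fit$rhat < 1.1))
  expect_true(all(fit$n_effective > 100))
  expect_true(all(fit$draws > 0 & fit$draws < 1))
  expect_true(all(fit$hpdi_92$sigma >= 0 & fit$hpdi_92$sigma <= 1))
  # same seed, same posterior
  fit2 <- fit_ewa(
    rec$history, rec$net, rec$t_a,
    repertoire = "full", e_init = c(a = 1, b = 1),
    chains = 3, iter = 1500, warmup = 500, rng_seed = 3
  )
  expect_identical(fit$draws, fit2$draws)
  # cross-check the HPDI against coda on the same draws
  ci <- coda::HPDinterval(coda::mcmc(fit$draws[, "sigma"]), prob = 0.92)
  expect_equal(unname(fit$hpdi_92$sigma), unname(ci[1, ]), tolerance = 0.01)
})

test_that("posterior conclusions are insensitive to a Beta(2,2) prior", {
  params <- reference_constellation()
  params$rho <- 0.5
  params$sigma <- 0.5
  rec <- run_simulation(
    params,
    rng_seed = 11, stop = "fixed", horizon = 150, seed_agent = "none",
    initial_repertoire = "full", e_init = c(a = 1, b = 1)
  )
  f_unif <- fit_ewa(
    rec$history, rec$net, rec$t_a, repertoire = "full",
    e_init = c(a = 1, b = 1), chains = 2, iter = 1000, warmup = 300,
    rng_seed = 4
  )
  f_beta <- fit_ewa(
    rec$history, rec$net, rec$t_a, repertoire = "full",
    e_init = c(a = 1, b = 1), chains = 2, iter = 1000, warmup = 300,
    prior = "beta22", rng_seed = 4
  )
  expect_lt(max(abs(f_unif$mean - f_beta$mean)), 0.05)
})
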