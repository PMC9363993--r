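test_that("event-time likelihood matches a brute-force hazard product", {
  # path network 1-2-3, demonstrator 1, events: agent 2 at 0.7, agent 3 at 1.5
  adj <- matrix(0, 3, 3)
  adj[1, 2] <- adj[2, 1] <- 1
  adj[2, 3] <- adj[3, 2] <- 1
  net <- social_network(adj)
  w <- c(1, 0.5, 1)
  dat <- nbda_data(c(NA, 0.7, 1.5), net, demonstrators = 1, weights = w)
  brute <- function(lambda0, s) {
    # interval (0, 0.7): naive 2 and 3
    l2 <- lambda0 * (s * 1 + 1) # sees demonstrator with weight 1
    l3 <- lambda0 # neighbour 2 still naive
    ll <- -(l2 + l3) * 0.7 + log(l2)
    # interval (0.7, 1.5): naive 3, now exposed to agent 2 at weight 0.5
    l3b <- lambda0 * (s * 0.5 + 1)
    ll - l3b * 0.8 + log(l3b)
  }
  for (par in list(c(0.1, 2), c(0.05, 5), c(1, 0), c(0.3, 17))) {
    expect_equal(
      ctada_loglik(dat, par[1], par[2], "social", form = "event"),
      brute(par[1], par[2]),
      tolerance = 1e-10
    )
  }
  expect_equal(
    ctada_loglik(dat, 0.2, model = "asocial", form = "event"), brute(0.2, 0)
  )
})

test_that("the social model nests the asocial model at s = 0", {
  set.seed(10)
  dat <- generate_ideal_data("social", rng_seed = 10)
  for (form in c("event", "step")) {
    expect_equal(
      ctada_loglik(dat, 0.07, 0, "social", form = form),
      ctada_loglik(dat, 0.07, model = "asocial", form = form)
    )
  }
  # s * w invariance: doubling weights and halving s leaves logL unchanged
  dat2 <- dat
  dat2$weights <- dat$weights * 2
  expect_equal(
    ctada_loglik(dat2, 0.07, 2.5, "social", form = "event"),
    ctada_loglik(dat, 0.07, 5, "social", form = "event")
  )
})

test_that("asocial maximum-likelihood estimates have their closed forms", {
  set.seed(6)
  dat <- generate_ideal_data("asocial", rng_seed = 6)
  # event form: exponential waiting-time MLE, n / total exposure
  fit <- fit_tadac(dat, "asocial", form = "event")
  grid <- seq(0.5, 2, by = 0.01) * fit$lambda0_hat
  ll <- vapply(
    grid, function(l) ctada_loglik(dat, l, model = "asocial", form = "event"),
    numeric(1)
  )
  expect_equal(grid[which.max(ll)], fit$lambda0_hat, tolerance = 0.011)
  expect_equal(max(ll), fit$log_likelihood, tolerance = 1e-6)
  # step form: per-step Bernoulli MLE, checked against a profile grid
  fit_s <- fit_tadac(dat, "asocial", form = "step")
  ll_s <- vapply(
    grid, function(l) ctada_loglik(dat, l, model = "asocial", form = "step"),
    numeric(1)
  )
  expect_lte(max(ll_s), fit_s$log_likelihood + 1e-8)
})

test_that("AICc applies the small-sample correction", {
  set.seed(2)
  dat <- generate_ideal_data("social", rng_seed = 2)
  fit <- fit_tadac(dat, "asocial")
  # K = 1, n = 23 events (seed is a demonstrator)
  expect_equal(fit$n_events, 23)
  expect_equal(
    fit$aicc, -2 * fit$log_likelihood + 2 + 4 / 21
  )
  # formula spot check: K = 1, n = 23, logL = -50 gives ~102.190
  expect_equal(100 + 2 + 2 * 1 * 2 / 21, 102.190, tolerance = 1e-4)
  fit2 <- fit_tadac(dat, "social")
  expect_equal(
    fit2$aicc, -2 * fit2$log_likelihood + 4 + 12 / 20
  )
  # the social fit never has lower likelihood than the nested asocial fit
  expect_gte(fit2$log_likelihood, fit$log_likelihood)
})

test_that("AICc comparison labels support and treats ties as asocial", {
  f_soc <- structure(list(model = "social", aicc = 100), class = "nbda_fit")
  f_aso <- structure(list(model = "asocial", aicc = 110), class = "nbda_fit")
  cmp <- delta_aicc(f_soc, f_aso)
  expect_equal(cmp$delta_aicc, 10)
  expect_equal(cmp$support, "social")
  f_aso$aicc <- 100
  expect_equal(delta_aicc(f_soc, f_aso)$support, "asocial")
})

test_that("ideal data generators honour their mechanisms", {
  set.seed(41)
  # asocial: every agent is an event, uniform hazard 1 - exp(-lambda_b)
  dat <- generate_ideal_data("asocial", rng_seed = 41)
  expect_length(dat$demonstrators, 0)
  expect_equal(sum(!is.na(dat$event_times)), 24)
  steps <- unlist(lapply(1:10, function(i) {
    ceiling(generate_ideal_data("asocial", rng_seed = 41 + i)$event_times)
  }))
  expect_equal(
    mean(steps), mean(stats::rgeom(40000, 1 - exp(-0.05)) + 1),
    tolerance = 0.2
  )
  # social: agents with more knowledgeable neighbours acquire sooner
  cors <- replicate(40, {
    d <- generate_ideal_data("social")
    net <- d$net
    early_known <- rep(0, net$n_agents)
    early_known[d$demonstrators] <- 1
    exposure <- as.numeric(net$adjacency %*% early_known)
    suppressWarnings(cor(exposure, d$event_times, use = "complete.obs"))
  })
  expect_lt(mean(cors, na.rm = TRUE), 0)
})

test_that("realistic data carry production-rate weights and ordered times", {
  dat <- generate_realistic_data("social", rng_seed = 8)
  rec <- attr(dat, "record")
  expect_true(all(rec$t_p >= rec$t_a))
  expect_true(all(dat$weights >= 0 & dat$weights <= 1))
  # weight definition: productions of b over timesteps knowledgeable
  j <- which.max(rec$t_a)
  expect_equal(
    dat$weights[j],
    sum(rec$history[, j] == "b") / (rec$n_steps - rec$t_a[j])
  )
  expect_equal(dat$demonstrators, rec$seed_agent)
  expect_true(is.na(dat$event_times[rec$seed_agent]))
})

test_that("fits recover social transmission from ideal social batches", {
  set.seed(19)
  s_hats <- replicate(25, {
    dat <- generate_ideal_data("social")
    fit_tadac(dat, "social")$s_hat
  })
  # median estimate within a factor ~2 of the generating s = 5
  expect_gt(median(s_hats), 2.5)
  expect_lt(median(s_hats), 10)
})

test_that("degenerate event data are rejected", {
  net <- complete_net(4)
  expect_error(
    nbda_data(c(1, NA, 2, 3), net, demonstrators = integer(0)), "learners"
  )
  expect_error(nbda_data(c(1, 2, 3, 4), net, demonstrators = 1), "event")
  dat <- nbda_data(c(NA, NA, 0.5, 1.2), net, demonstrators = 1:2)
  expect_error(fit_tadac(dat, "social"), "too few events")
})
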