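test_that("simulations are bit-identical under the same seeds", {
  params <- reference_constellation()
  net <- generate_random_regular(24, 6, rng_seed = 4)
  r1 <- run_simulation(params, net, rng_seed = 77)
  r2 <- run_simulation(params, net, rng_seed = 77)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$t_a, r2$t_a)
  expect_identical(r1$o_p, r2$o_p)
})

test_that("completed records satisfy the structural invariants", {
  for (seed in c(3, 14, 159)) {
    rec <- run_simulation(reference_constellation(), rng_seed = seed)
    N <- length(rec$t_a)
    expect_true(rec$converged)
    # one production per agent per timestep
    expect_equal(dim(rec$history), c(rec$n_steps, N))
    expect_true(all(rec$history %in% c("a", "b")))
    # per-agent production follows acquisition
    expect_true(all(rec$t_p >= rec$t_a))
    # order vectors are permutations; the seed acquires first
    expect_setequal(rec$o_a, 1:N)
    expect_setequal(rec$o_p, 1:N)
    expect_equal(rec$o_a[rec$seed_agent], 1L)
    expect_equal(rec$t_a[rec$seed_agent], 0)
    expect_equal(rec$ttd, max(rec$t_a))
    expect_equal(rec$ttfp, max(rec$t_p))
    # no agent produces b before knowing it
    first_b <- apply(rec$history == "b", 2, function(col) {
      w <- which(col)
      if (length(w)) w[1] else Inf
    })
    expect_true(all(first_b > rec$t_a))
  }
})

test_that("acquisition follows network edges strictly when A = 0", {
  params <- reference_constellation()
  rec <- run_simulation(params, rng_seed = 21)
  m <- params$m
  for (i in seq_along(rec$t_a)) {
    t <- rec$t_a[i]
    if (t == 0) next # seed
    nb <- agent_neighbors(rec$net, i)
    window <- rec$history[seq(max(1, t - m), t - 1), nb, drop = FALSE]
    expect_true(any(window == "b"))
  }
})

test_that("a pure-social model without producing neighbours still stalls
           gracefully at the cap", {
  params <- constellation(s = 0, A = 0)
  rec <- run_simulation(params, rng_seed = 2, max_steps = 100)
  expect_false(rec$converged)
  expect_equal(rec$n_steps, 100)
})

test_that("stopping rules control the recorded horizon", {
  params <- reference_constellation()
  fixed <- run_simulation(params, rng_seed = 31, stop = "fixed", horizon = 40)
  expect_equal(fixed$n_steps, 40)
  twice <- run_simulation(params, rng_seed = 31, stop = "twice_ttd")
  expect_equal(twice$n_steps, 2 * twice$ttd)
  expect_true(all(twice$t_a <= twice$ttd))
})

test_that("rank_events ranks times with symmetric random tie-breaking", {
  expect_equal(rank_events(c(3, 1, 2)), c(3L, 1L, 2L))
  expect_equal(rank_events(c(10, 20, 30, 40)), 1:4)
  expect_error(rank_events(c(1, NA)), "finite")
  set.seed(88)
  ranks <- replicate(4000, rank_events(c(1, 2, 2, 5))[2])
  expect_equal(mean(ranks == 2), 0.5, tolerance = 0.05)
  expect_true(all(ranks %in% 2:3))
})

test_that("the vectorized engine agrees with the single-step operations", {
  params <- constellation(N = 12, k = 4, sigma = 0.4, f = 2, rho = 0.3)
  rec <- run_simulation(
    params,
    rng_seed = 63, stop = "fixed", horizon = 30, record_probs = TRUE
  )
  net <- rec$net
  N <- params$N
  # rebuild each agent's expected values and production probabilities from
  # the recorded history using the scalar operations
  E <- matrix(0, 2, N) # rows: a, b
  E[1, ] <- 1
  for (t in seq_len(rec$n_steps)) {
    if (t >= 2) {
      prev <- rec$history[t - 1, ]
      E[1, ] <- update_expected_value(E[1, ], as.numeric(prev == "a"),
                                      params$rho)
      E[2, ] <- update_expected_value(E[2, ], as.numeric(prev == "b"),
                                      params$rho)
    }
    for (i in seq_len(N)) {
      knows <- !is.na(rec$t_a[i]) && rec$t_a[i] < t
      if (!knows) {
        expect_equal(rec$prob_b[t, i], 0)
        next
      }
      ind <- individual_probabilities(
        c(a = E[1, i], b = E[2, i]), params$alpha
      )
      soc <- social_frequencies(
        i, net, rec$history, t, params$m, params$f
      )
      p <- production_probabilities(ind, soc, params$sigma)
      expect_equal(rec$prob_b[t, i], unname(p["b"]), tolerance = 1e-12)
      expect_equal(sum(p), 1, tolerance = 1e-12)
    }
  }
})

test_that("histories and events export as tidy CSV", {
  rec <- run_simulation(reference_constellation(), rng_seed = 12)
  hp <- withr::local_tempfile(fileext = ".csv")
  ep <- withr::local_tempfile(fileext = ".csv")
  write_history(rec, hp)
  write_events(rec, ep)
  h <- read.csv(hp)
  expect_equal(nrow(h), rec$n_steps * 24)
  expect_named(h, c("timestep", "agent", "behaviour"))
  e <- read.csv(ep)
  expect_equal(e$time_of_acquisition, rec$t_a)
  expect_equal(e$time_of_first_production, rec$t_p)
})
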