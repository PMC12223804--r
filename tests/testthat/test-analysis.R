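# minimal hand-built run record
fake_rec <- function(n_walkers, iters, coords_fun, tau = 1,
                     weights_fun = function(t) rep(1 / n_walkers, n_walkers)) {
  structure(list(
    config = list(), seed = 0L, tau = tau, coordinate_names = "x",
    states = list(),
    iterations = lapply(seq_len(iters), function(t) {
      list(ids = seq_len(n_walkers), parents = seq_len(n_walkers),
           weights = weights_fun(t),
           coords = matrix(coords_fun(t), ncol = 1),
           scores = rep(0, n_walkers),
           events = list(splits = list(), merges = list()))
    }),
    flux = numeric(iters), spec_updates = list()), class = "we_run")
}

test_that("exact markov oracle agrees with explicit matrix powers", {
  Tm <- fixture_T3()
  pi0 <- markov_stationary(Tm)
  expect_equal(exact_markov(Tm, pi0, 17), pi0, tolerance = 1e-12)
  p0 <- c(1, 0, 0)
  byhand <- p0 %*% Tm %*% Tm %*% Tm %*% Tm %*% Tm
  expect_equal(exact_markov(Tm, p0, 5), as.numeric(byhand),
               tolerance = 1e-12)
  expect_error(
    exact_markov(matrix(c(0.5, 0.4, 0.2, 0.8), 2, byrow = TRUE), c(1, 0), 1),
    "stochastic")
})

test_that("mean first-passage time matches the 2-state closed form", {
  for (a in c(0.1, 0.25, 0.5)) {
    Tm <- matrix(c(1 - a, a, a, 1 - a), 2, byrow = TRUE)
    expect_equal(markov_mfpt(Tm, 1, 2), 1 / a, tolerance = 1e-12)
  }
  expect_equal(markov_mfpt(fixture_T3(), 3, 3), 0)
})

test_that("weighted histogram conserves probability mass", {
  # single walker of weight 1: a delta in one bin
  rec1 <- fake_rec(1, 3, function(t) 2.5,
                   weights_fun = function(t) 1)
  h1 <- weighted_histogram(rec1, "x", breaks = 0:5)
  expect_equal(as.numeric(h1), c(0, 0, 1, 0, 0))
  # real run: total mass 1 within 1e-9 at any binning
  rec <- run_simulation(markov3_cfg(iterations = 20L, seed = 9L))
  h <- weighted_histogram(rec, "state", breaks = c(0.5, 1.5, 2.5, 3.5))
  expect_lt(abs(sum(h) - 1), 1e-9)
  # log-probability output floors empty bins instead of -Inf
  hl <- weighted_histogram(rec, "state", breaks = c(0.5, 1.5, 2.5, 3.5),
                           log_prob = TRUE)
  expect_true(all(is.finite(hl)))
  expect_error(weighted_histogram(rec, "zeta", breaks = 0:3), "unknown")
})

test_that("2-D weighted histogram sums to the same conserved mass", {
  cfg <- list(system = list(kind = "surrogate_unbinding_2d"),
              resampler = list(type = "mabl", n_split_merge = 5L),
              walker_count = 40L, tau = 1, iterations = 15L, seed = 4L)
  rec <- run_simulation(cfg)
  h2 <- weighted_histogram(rec, c("eint", "dist"),
                           breaks = list(seq(-250, 400, by = 50),
                                         seq(-2, 12, by = 1)))
  expect_lt(abs(sum(h2) - 1), 1e-9)
})

test_that("repulsive energies carry probability mass just before unbinding", {
  # on the surrogate system the energy-like coordinate rises above zero in
  # the exit channel; a completed unbinding run must therefore show mass
  # at eint > 0 at large separations
  cfg <- list(system = list(kind = "surrogate_unbinding_2d"),
              resampler = list(type = "mabl", n_split_merge = 5L),
              walker_count = 40L, tau = 1, iterations = 600L, seed = 1L,
              stop_state = "unbound")
  rec <- run_simulation(cfg)
  h2 <- weighted_histogram(rec, c("eint", "dist"),
                           breaks = list(c(-250, 0, 400), c(6, 8.5, 12)))
  expect_gt(h2[2, 1], 0)  # eint > 0 at dist in [6, 8.5): the exit approach
})

test_that("the first unbinding walker traces a continuous bound-to-unbound path", {
  cfg <- list(system = list(kind = "surrogate_unbinding_2d"),
              resampler = list(type = "mabl", n_split_merge = 5L),
              walker_count = 40L, tau = 1, iterations = 600L, seed = 2L,
              stop_state = "unbound")
  rec <- run_simulation(cfg)
  k <- length(rec$iterations)
  it <- rec$iterations[[k]]
  hit <- it$ids[which(it$coords[, 3] >= 8.5)[1]]
  tl <- trace_lineage(rec, hit, k)
  expect_equal(tl$iteration, seq_len(k))        # unbroken chain
  expect_lt(tl$dist[1], 2)                      # starts near the bound pose
  expect_gte(tl$dist[k], 8.5)                   # ends unbound
  # pointwise continuity: one iteration of overdamped dynamics cannot
  # teleport; successive separations differ by a bounded amount
  expect_lt(max(abs(diff(tl$dist))), 3)
})

test_that("first-event aggregate time accumulates walkers x tau", {
  # 40 walkers, tau 1, event at iteration 50 -> 2000 walker-time units
  rec <- fake_rec(40, 60, function(t) if (t >= 50) c(9, rep(0, 39))
                  else rep(0, 40))
  tgt <- state_def("hit", list(x = c(8.5, Inf)))
  expect_equal(first_event_aggregate_time(rec, tgt), 2000)
  # event already at iteration 1 with 5 walkers
  rec2 <- fake_rec(5, 3, function(t) c(9, 0, 0, 0, 0))
  expect_equal(first_event_aggregate_time(rec2, tgt), 5)
  # no event
  rec3 <- fake_rec(5, 3, function(t) rep(0, 5))
  expect_true(is.na(first_event_aggregate_time(rec3, tgt)))
})

test_that("first-event time grows with the iteration of the event", {
  tgt <- state_def("hit", list(x = c(8.5, Inf)))
  times <- vapply(c(2, 5, 9), function(k) {
    rec <- fake_rec(7, 10, function(t) if (t >= k) c(9, rep(0, 6))
                    else rep(0, 7))
    first_event_aggregate_time(rec, tgt)
  }, numeric(1))
  expect_true(all(diff(times) > 0))
})

test_that("flux rate estimator handles constant and empty series", {
  est <- flux_rate_estimate(rep(0.02, 50), tau = 1, burn_in = 10)
  expect_equal(est$rate, 0.02, tolerance = 1e-12)
  est0 <- flux_rate_estimate(rep(0, 30))
  expect_equal(est0$rate, 0)
  expect_equal(est0$se, 0)
  expect_error(flux_rate_estimate(numeric(0)), "burn_in")
})

test_that("recycled flux recovers 1/MFPT on the 3-state chain", {
  Tm <- fixture_T3()
  mfpt <- markov_mfpt(Tm, 1, 3)
  cfg <- markov3_cfg(walkers = 20L, iterations = 800L, seed = 12L,
                     recycling = list(target = "target"))
  rec <- run_simulation(cfg)
  est <- flux_rate_estimate(rec$flux, tau = rec$tau, burn_in = 100)
  expect_lt(abs(est$rate - 1 / mfpt) / (1 / mfpt), 0.10)
})

test_that("flux on the 2-state symmetric chain matches the closed form", {
  a <- 0.2
  Tm <- matrix(c(1 - a, a, a, 1 - a), 2, byrow = TRUE)
  cfg <- list(system = list(kind = "markov_chain",
                            parameters = list(transition = Tm)),
              resampler = list(type = "none"),
              walker_count = 20L, tau = 1, iterations = 400L, seed = 3L,
              recycling = list(target = "target"))
  rec <- run_simulation(cfg)
  est <- flux_rate_estimate(rec$flux, tau = rec$tau, burn_in = 50)
  # recycling resets to state 1 each time a walker arrives in state 2, so
  # the per-iteration flux is Bernoulli(a) per unit weight: rate -> a
  expect_lt(abs(est$rate - a), 3 * est$se)
  expect_gt(est$se, 0)
})

test_that("uniform ensembles give a flat weight profile", {
  rec <- fake_rec(10, 5, function(t) seq(0.5, 9.5, length.out = 10))
  wp <- weight_profile(rec, "x", breaks = 0:10)
  expect_equal(wp$mean_weight, rep(0.1, 10))
  expect_equal(wp$min_weight, rep(0.1, 10))
  expect_equal(wp$max_weight, rep(0.1, 10))
  expect_equal(wp$occupancy, rep(5L, 10))
})

test_that("state occupancy sums weights of walkers inside the state", {
  rec <- fake_rec(4, 1, function(t) c(9, 9, 1, 1),
                  weights_fun = function(t) c(0.1, 0.2, 0.3, 0.4))
  tgt <- state_def("hit", list(x = c(8.5, Inf)))
  expect_equal(state_occupancy(rec, tgt, 1), 0.3, tolerance = 1e-12)
})
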