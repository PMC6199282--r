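test_that("selection probabilities form a stable softmax over neighbour h", {
  h <- matrix(1, 4, 4)
  expect_equal(selection_probabilities(h, c(2, 2), alpha = 0), rep(0.25, 4))
  expect_equal(selection_probabilities(h, c(2, 2), alpha = 3), rep(0.25, 4))

  # one neighbour at h = 4, the rest at 0: closed-form softmax value
  h2 <- matrix(0, 3, 3)
  h2[2, 3] <- 4  # right neighbour of (2, 2)
  p <- selection_probabilities(h2, c(2, 2), alpha = 3)
  expect_equal(p[4], exp(12) / (3 + exp(12)), tolerance = 1e-12)
  expect_equal(p[1], 1 / (3 + exp(12)), tolerance = 1e-12)

  # extreme alpha stays finite and normalized
  p30 <- selection_probabilities(h2, c(2, 2), alpha = 30)
  expect_true(all(is.finite(p30)))
  expect_equal(sum(p30), 1, tolerance = 1e-12)

  # property: sums to 1 within 1e-12, entries in (0, 1]
  withr::with_seed(3, {
    for (i in 1:50) {
      hr <- matrix(runif(25, 0, 4), 5, 5)
      pr <- selection_probabilities(hr, c(sample(5, 1), sample(5, 1)),
                                    alpha = runif(1, 0, 12))
      expect_lt(abs(sum(pr) - 1), 1e-12)
      expect_true(all(pr > 0 & pr <= 1))
    }
  })
})

test_that("Fermi rule is logistic, symmetric and monotone", {
  expect_equal(fermi_probability(1.3, 1.3, K = 0.1), 0.5)
  expect_equal(fermi_probability(0, 1, K = 0.1), 1 / (1 + exp(-10)))
  withr::with_seed(8, {
    for (i in 1:50) {
      a <- runif(1, -5, 5); b <- runif(1, -5, 5); K <- runif(1, 0.01, 2)
      expect_equal(fermi_probability(a, b, K) + fermi_probability(b, a, K), 1)
    }
  })
  fy <- seq(-3, 3, length.out = 25)
  w <- fermi_probability(0.7, fy, K = 0.1)
  expect_true(all(diff(w) >= 0))
})

test_that("all-C and all-D lattices are absorbing for the kernel", {
  p <- tiny_params(L = 8L, b = 1.4, u = 0.6, alpha = 4)
  for (strat in c(0L, 1L)) {
    st <- const_state(8L, strat)
    st$h_field <- rand_state(8L, 99)$h_field
    st <- lattice_state(st$strategies, st$h_field)
    set.seed(1)
    for (i in 1:50) st <- elementary_step(st, p)$state
    expect_true(all(st$strategies == strat))
    set.seed(2)
    out <- mcs_sweep(st, p)
    expect_equal(out$rho_c, as.numeric(strat))
    expect_true(all(out$state$strategies == strat))
  }
})

test_that("elementary steps report a valid event record", {
  p <- tiny_params(L = 6L)
  st <- rand_state(6L, 21)
  set.seed(30)
  out <- elementary_step(st, p, focal = c(3, 4))
  ev <- out$event
  expect_identical(c(ev$focal_row, ev$focal_col), c(3L, 4L))
  # chosen neighbour is one of the four torus neighbours
  dr <- abs(ev$neighbor_row - 3L); dcc <- abs(ev$neighbor_col - 4L)
  dr <- min(dr, 6L - dr); dcc <- min(dcc, 6L - dcc)
  expect_equal(dr + dcc, 1L)
  # fitnesses match the model computation
  f_focal <- fitness(game_payoff(st, c(3, 4), payoff_matrix(p$b)),
                     local_environment(st$h_field, c(3, 4)), p$u)
  expect_equal(ev$focal_fitness, f_focal)
  # a non-adopted step leaves the grid unchanged; an adopted one copies
  if (ev$adopted) {
    expect_identical(out$state$strategies[3, 4],
                     st$strategies[ev$neighbor_row, ev$neighbor_col])
  } else {
    expect_identical(out$state$strategies, st$strategies)
  }
})

test_that("one sweep equals L^2 elementary steps on the same RNG stream", {
  p <- tiny_params(L = 5L, b = 1.3, u = 0.4, alpha = 2)
  st0 <- rand_state(5L, 77)
  set.seed(123)
  swept <- mcs_sweep(st0, p)
  set.seed(123)
  st <- st0
  for (i in 1:25) st <- elementary_step(st, p)$state
  expect_identical(st$strategies, swept$state$strategies)
  expect_equal(rho_c(st), swept$rho_c)
})

test_that("fixed seeds give bit-identical trajectories", {
  p <- tiny_params(L = 15L, mcs = 120L, window = 40L)
  r1 <- run_single(p, seed = 5)
  r2 <- run_single(p, seed = 5)
  expect_identical(r1$rho_trajectory, r2$rho_trajectory)
  expect_identical(r1$final_strategies, r2$final_strategies)
})
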