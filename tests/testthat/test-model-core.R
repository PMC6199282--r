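test_that("parameter validation names the offending field", {
  expect_error(sim_params(L = 1), "'L'")
  expect_error(sim_params(u = 1.5), "'u'")
  expect_error(sim_params(u = -0.1), "'u'")
  expect_error(sim_params(alpha = -1), "'alpha'")
  expect_error(sim_params(K = 0), "'K'")
  expect_error(sim_params(b = 0.9), "'b'")
  expect_error(sim_params(total_mcs = 100, avg_window = 200), "'avg_window'")
  expect_error(payoff_matrix(0.5), "'b'")
})

test_that("defaults match the reference study settings", {
  p <- sim_params()
  expect_identical(p$L, 100L)
  expect_equal(p$K, 0.1)
  expect_identical(p$total_mcs, 60000L)
  expect_identical(p$avg_window, 10000L)
  expect_equal(p$stationarity_tol, 1e-2)
  expect_identical(p$n_replicates, 40L)
  pm <- payoff_matrix(1.3)
  expect_equal(pm$R, 1)
  expect_equal(pm$T, 1.3)
  expect_equal(pm$P, 0)
  expect_equal(pm$S, 0)
})

test_that("initial lattices are fair, discrete-h, and seed-reproducible", {
  p <- tiny_params(L = 50L)
  set.seed(11)
  st <- init_lattice(p)
  # every h is one of the 41 levels 0.0 .. 4.0
  expect_true(all(st$h_field >= 0 & st$h_field <= 4))
  expect_true(all(abs(st$h_field * 10 - round(st$h_field * 10)) < 1e-12))
  # env field always consistent with h field
  expect_identical(st$env_field, environment_field(st$h_field))

  set.seed(42); a <- init_lattice(p)
  set.seed(42); b <- init_lattice(p)
  expect_identical(a$strategies, b$strategies)
  expect_identical(a$h_field, b$h_field)

  # grand-mean initial cooperator fraction over 100 seeds within 3 binomial SE
  rho <- vapply(1:100, function(s) { set.seed(s); rho_c(init_lattice(p)) },
                numeric(1))
  se <- 0.5 / sqrt(100 * 50^2)
  expect_lt(abs(mean(rho) - 0.5), 3 * se)
})

test_that("game payoff follows the weak PD against the four neighbours", {
  pm <- payoff_matrix(1.5)
  allC <- const_state(4L, 1L)
  expect_equal(game_payoff(allC, c(2, 2), pm), 4)     # 4 * R
  # every site of an all-C lattice earns exactly 4
  for (r in 1:4) for (cc in 1:4) {
    expect_equal(game_payoff(allC, c(r, cc), pm), 4)
  }
  oneD <- allC
  oneD$strategies[2, 2] <- 0L
  oneD <- lattice_state(oneD$strategies, oneD$h_field)
  expect_equal(game_payoff(oneD, c(2, 2), pm), 6)     # D among 4 C: 4 * b
  allD <- const_state(4L, 0L)
  oneC <- allD
  oneC$strategies[3, 3] <- 1L
  oneC <- lattice_state(oneC$strategies, oneC$h_field)
  expect_equal(game_payoff(oneC, c(3, 3), payoff_matrix(2)), 0)  # C among D: 4 * S

  # payoff bounded in [0, 4 * max(1, b)] on random configurations
  for (s in 1:20) {
    st <- rand_state(5L, 100 + s)
    pmr <- payoff_matrix(1 + s / 40)
    pay <- game_payoff(st, c((s %% 5) + 1L, ((s * 3) %% 5) + 1L), pmr)
    expect_gte(pay, 0)
    expect_lte(pay, 4 * max(1, pmr$T))
  }
})

test_that("environment is the mean of the neighbours' h, focal excluded", {
  expect_equal(local_environment(matrix(2, 4, 4), c(3, 2)), 2)
  h <- matrix(1, 3, 3)
  h[1, 2] <- 0.0; h[3, 2] <- 0.1; h[2, 1] <- 0.2; h[2, 3] <- 0.3
  h[2, 2] <- 3.7  # focal h must not matter
  expect_equal(local_environment(h, c(2, 2)), 0.15)
  h[2, 2] <- 0.0
  expect_equal(local_environment(h, c(2, 2)), 0.15)
  # full-field computation agrees with the per-site one everywhere
  st <- rand_state(6L, 7)
  ef <- environment_field(st$h_field)
  for (r in 1:6) for (cc in 1:6) {
    expect_equal(ef[r, cc], local_environment(st$h_field, c(r, cc)))
  }
})

test_that("fitness is the affine payoff-environment mixture", {
  expect_equal(fitness(3, 1.7, u = 0), 3)
  expect_equal(fitness(3, 1.7, u = 1), 1.7)
  expect_equal(fitness(2, 1, u = 0.5), 1.5)
  expect_error(fitness(1, 1, u = 1.2), "'u'")
  # F(u) = P + u * (H - P) for random inputs
  withr::with_seed(5, {
    for (i in 1:50) {
      pp <- runif(1, 0, 6); hh <- runif(1, 0, 4); uu <- runif(1)
      expect_equal(fitness(pp, hh, uu), pp + uu * (hh - pp))
    }
  })
})
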