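test_that("stationarity check compares consecutive window means strictly", {
  expect_true(stationarity_check(rep(0.5, 100), window = 50, tol = 1e-2))
  expect_false(stationarity_check(c(rep(0, 50), rep(0.5, 50)),
                                  window = 50, tol = 1e-2))
  # difference exactly equal to tol fails the strict '<'
  expect_false(stationarity_check(c(rep(0, 5), rep(0.01, 5)),
                                  window = 5, tol = 0.01))
  expect_true(stationarity_check(c(rep(0, 5), rep(0.00999, 5)),
                                 window = 5, tol = 0.01))
  expect_error(stationarity_check(rep(0.5, 9), window = 5, tol = 1e-2),
               "2 \\* window")
})

test_that("runs record trajectories, equilibria and snapshots coherently", {
  p <- tiny_params(L = 20L, b = 1.2, u = 0.4, alpha = 3, mcs = 150L,
                   window = 50L, snapshot_times = c(0L, 10L, 150L))
  r <- run_single(p, seed = 9)
  expect_length(r$rho_trajectory, r$mcs_executed)
  expect_gte(r$mcs_executed, p$total_mcs)
  expect_true(all(r$rho_trajectory >= 0 & r$rho_trajectory <= 1))
  expect_equal(r$rho_equilibrium, mean(tail(r$rho_trajectory, p$avg_window)))
  expect_named(r$snapshots, c("0", "10", "150"))
  expect_equal(rho_c(r$snapshots[["0"]]), 0.5, tolerance = 0.12)
  expect_identical(r$snapshots[["150"]], r$final_strategies)
})

test_that("the traditional game at b = 1.05 drives cooperators extinct", {
  p <- sim_params(L = 30L, b = 1.05, u = 0, alpha = 0, total_mcs = 2000L,
                  avg_window = 500L, n_replicates = 1L)
  r <- run_single(p, seed = 4)
  expect_equal(r$rho_equilibrium, 0)
  # absorbing: once extinct, the trajectory stays at 0
  first0 <- match(0, r$rho_trajectory)
  expect_true(all(r$rho_trajectory[first0:length(r$rho_trajectory)] == 0))
  expect_true(r$stationary)
})

test_that("ensembles are deterministic, exchangeable and correctly summarised", {
  p <- tiny_params(L = 15L, b = 1.1, u = 0.5, alpha = 3, mcs = 120L,
                   window = 40L, reps = 3L, seed = 77L)
  e1 <- run_ensemble(p)
  e2 <- run_ensemble(p)
  expect_identical(e1$per_replicate, e2$per_replicate)
  expect_equal(e1$rho_mean, mean(e1$per_replicate$rho_equilibrium))
  expect_equal(e1$rho_sd, sd(e1$per_replicate$rho_equilibrium))

  # permuting the child seeds permutes replicates but not the mean
  perm <- c(2L, 3L, 1L)
  e3 <- run_ensemble(p, seeds = e1$seeds[perm])
  expect_equal(e3$per_replicate$rho_equilibrium,
               e1$per_replicate$rho_equilibrium[perm])
  expect_equal(e3$rho_mean, e1$rho_mean)

  # single replicate: mean is that run, sd undefined
  p1 <- tiny_params(L = 15L, mcs = 120L, window = 40L, reps = 1L, seed = 5L)
  e4 <- run_ensemble(p1)
  expect_equal(e4$rho_mean,
               run_single(p1, seed = e4$seeds[1])$rho_equilibrium)
  expect_true(is.na(e4$rho_sd))
})

test_that("a shared heterogeneity field is reused across replicates", {
  p <- tiny_params(L = 12L, mcs = 100L, window = 30L, reps = 2L, seed = 19L)
  e <- run_ensemble(p, share_h = TRUE)
  expect_identical(e$runs[[1]]$h_field, e$runs[[2]]$h_field)
  e2 <- run_ensemble(p, share_h = FALSE)
  expect_false(identical(e2$runs[[1]]$h_field, e2$runs[[2]]$h_field))
})

test_that("purely environmental fitness keeps the ensemble mean near one half", {
  p <- sim_params(L = 30L, b = 1.2, u = 1, alpha = 3, total_mcs = 600L,
                  avg_window = 200L, n_replicates = 10L, seed = 31L)
  e <- run_ensemble(p, keep_runs = FALSE)
  se <- e$rho_sd / sqrt(p$n_replicates)
  expect_lt(abs(e$rho_mean - 0.5), max(3 * se, 0.05))
})

test_that("tidiers return the documented tabular shapes", {
  p <- tiny_params(L = 12L, mcs = 100L, window = 30L, reps = 2L, seed = 3L)
  r <- run_single(p, seed = 3)
  tr <- tidy(r)
  expect_named(tr, c("mcs", "rho_c"))
  expect_identical(nrow(tr), r$mcs_executed)
  expect_identical(glance(r)$rho_equilibrium, r$rho_equilibrium)
  e <- run_ensemble(p)
  expect_identical(nrow(tidy(e)), 2L)
  g <- glance(e)
  expect_equal(g$rho_mean, e$rho_mean)
  expect_identical(g$n_replicates, 2L)
})
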