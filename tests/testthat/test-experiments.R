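test_that("sweep specs validate their axes", {
  p <- tiny_params()
  expect_error(sweep_spec(p, list(param = "zeta", values = 1:3)), "parameter")
  expect_error(sweep_spec(p, list(param = "b", values = numeric(0))),
               "strictly increasing")
  expect_error(sweep_spec(p, list(param = "b", values = c(1.2, 1.1))),
               "strictly increasing")
  expect_error(sweep_spec(p, list(param = "b", values = c(1, 1.1)),
                          list(param = "b", values = c(1, 1.1))),
               "different")
})

test_that("sweeps are reproducible and grid-point seeds are value-stable", {
  p <- tiny_params(L = 12L, u = 0.5, alpha = 3, mcs = 100L, window = 30L,
                   reps = 2L, seed = 41L)
  s2 <- sweep_spec(p, list(param = "b", values = c(1.0, 1.1)))
  a <- run_sweep(s2)
  b <- run_sweep(s2)
  expect_identical(a$results, b$results)

  # extending the grid leaves existing points untouched
  s3 <- sweep_spec(p, list(param = "b", values = c(1.0, 1.1, 1.2)))
  c3 <- run_sweep(s3)
  expect_identical(c3$results[1:2, ], a$results)

  # 2D grids carry both axis columns
  s2d <- sweep_spec(p, list(param = "b", values = c(1.0, 1.1)),
                    list(param = "u", values = c(0.2, 0.8)))
  d <- run_sweep(s2d)
  expect_identical(nrow(d$results), 4L)
  expect_named(d$results, c("b", "u", "rho_mean", "rho_sd", "n_replicates",
                            "seed", "valid"))
})

test_that("locate_optimum maximises rho with ties toward the smaller value", {
  p <- tiny_params()
  fake <- function(vals, rho) {
    structure(list(
      spec = sweep_spec(p, list(param = "alpha", values = vals)),
      results = tibble::tibble(alpha = vals, rho_mean = rho, rho_sd = 0,
                               n_replicates = 2L, seed = 1L, valid = TRUE)
    ), class = "heterogame_sweep")
  }
  expect_equal(locate_optimum(fake(0:4, c(.1, .2, .3, .4, .5)), "alpha")$alpha, 4)
  expect_equal(locate_optimum(fake(0:4, rep(0.5, 5)), "alpha")$alpha, 0)
  expect_equal(locate_optimum(fake(0:4, c(.1, .9, .9, .2, .1)), "alpha")$alpha, 1)
  sw <- fake(0:2, c(.1, .2, .3))
  sw$results$valid <- FALSE
  expect_error(locate_optimum(sw, "alpha"), "valid")
  expect_error(locate_optimum(fake(0:2, c(.1, .2, .3)), "u"), "over")
})

test_that("pair concordance counts same-strategy bonds exactly", {
  L <- 4L
  expect_equal(pair_concordance(matrix(1L, L, L)), 1)
  checker <- outer(1:L, 1:L, function(r, cc) as.integer((r + cc) %% 2L))
  expect_equal(pair_concordance(checker), 0)
  # two homogeneous halves of a 4x4 torus: 24 of 32 bonds concordant
  halves <- matrix(rep(c(0L, 0L, 1L, 1L), each = L), L, L)
  expect_equal(pair_concordance(halves), 24 / 32)
})

test_that("snapshot series returns the requested grids in order", {
  p <- tiny_params(L = 20L, b = 1.1, u = 0.8, alpha = 3, mcs = 300L,
                   window = 100L, snapshot_times = c(0L, 10L, 100L, 300L),
                   seed = 13L)
  snaps <- snapshot_series(p)
  expect_named(snaps, c("0", "10", "100", "300"))
  init <- snaps[["0"]]
  # random initial condition: half-half and spatially uncorrelated
  expect_equal(rho_c(init), 0.5, tolerance = 0.12)
  expect_equal(pair_concordance(init), 0.5, tolerance = 0.12)
})

test_that("strategy clusters coarsen while u = 1 keeps rho near one half", {
  p <- sim_params(L = 30L, b = 1.2, u = 1, alpha = 3, total_mcs = 600L,
                  avg_window = 200L, n_replicates = 1L,
                  snapshot_times = c(0L, 600L))
  snaps <- snapshot_series(p, seed = 17)
  expect_gt(pair_concordance(snaps[["600"]]),
            pair_concordance(snaps[["0"]]) + 0.1)
})

test_that("cooperators dominate and cluster at strong environmental weight", {
  p <- sim_params(L = 50L, b = 1.1, u = 0.8, alpha = 3, total_mcs = 3000L,
                  avg_window = 1000L, n_replicates = 1L,
                  snapshot_times = c(0L, 3000L))
  snaps <- snapshot_series(p, seed = 23)
  final <- snaps[["3000"]]
  expect_gt(rho_c(final), 0.5)
  expect_gt(pair_concordance(final), pair_concordance(snaps[["0"]]))
})

test_that("cooperation does not rise with temptation along a b sweep", {
  p <- sim_params(L = 30L, u = 0.5, alpha = 3, K = 0.1, total_mcs = 1500L,
                  avg_window = 500L, n_replicates = 3L, seed = 61L)
  sw <- run_sweep(sweep_spec(p, list(param = "b",
                                     values = c(1.0, 1.1, 1.2, 1.3))))
  res <- sw$results
  for (i in seq_len(nrow(res) - 1L)) {
    pooled_se <- sqrt(res$rho_sd[i]^2 + res$rho_sd[i + 1]^2) /
      sqrt(res$n_replicates[i])
    expect_lte(res$rho_mean[i + 1], res$rho_mean[i] + 2 * pooled_se + 1e-9)
  }
})
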