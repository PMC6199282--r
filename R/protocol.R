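#' Stationarity check on a cooperator-fraction trajectory
#'
#' The system is declared stationary when the absolute difference between the
#' mean of the last `window` trajectory entries and the mean of the `window`
#' entries before them is strictly below `tol`.
#'
#' @param trajectory Numeric vector of per-sweep cooperator fractions.
#' @param window Window length (sweeps).
#' @param tol Threshold; the comparison is strict (`<`).
#' @return `TRUE` or `FALSE`.
#' @examples
#' stationarity_check(rep(0.5, 100), window = 50, tol = 1e-2)  # TRUE
#' @export
stationarity_check <- function(trajectory, window, tol) {
  window <- as.integer(window)
  if (length(trajectory) < 2L * window) {
    stop("trajectory must contain at least 2 * window entries", call. = FALSE)
  }
  n <- length(trajectory)
  last <- mean(trajectory[(n - window + 1L):n])
  prev <- mean(trajectory[(n - 2L * window + 1L):(n - window)])
  abs(last - prev) < tol
}

# run `n` sweeps from the current working strategies, honouring absorbing
# states: once all-C or all-D is reached the trajectory is constant and no
# further RNG is consumed.
run_block <- function(strat, h_field, params, n, absorbed, current_rho) {
  if (n <= 0L) return(list(rho = numeric(0), absorbed = absorbed))
  if (absorbed) return(list(rho = rep(current_rho, n), absorbed = TRUE))
  res <- cpp_run_sweeps(strat, h_field, params$b, params$u, params$alpha,
                        params$K, as.integer(n), TRUE)
  rho <- res$rho
  if (res$absorbed && length(rho) < n) {
    fill <- if (length(rho)) rho[length(rho)] else current_rho
    rho <- c(rho, rep(fill, n - length(rho)))
  }
  list(rho = rho, absorbed = res$absorbed)
}

#' Execute one full simulation run
#'
#' Initializes a lattice from `seed`, runs `total_mcs` sweeps recording the
#' cooperator fraction after each and the strategy grid at the requested
#' snapshot times, then applies the stationarity check. While the check
#' fails, `extension_block` further sweeps are appended and the check is
#' repeated, up to `max_extensions` times; the equilibrium cooperator
#' fraction is the mean over the final `avg_window` sweeps of the (possibly
#' extended) trajectory. Absorbing states (all-C / all-D) short-circuit to a
#' constant trajectory.
#'
#' @param params A [sim_params()] object.
#' @param seed RNG seed for this run; defaults to `params$seed`.
#' @param h_field Optional shared quenched heterogeneity field; by default a
#'   fresh field is drawn for the run.
#' @param max_extensions Hard cap on stationarity extensions (default 10);
#'   reaching it flags the result non-stationary rather than erroring.
#' @return A `heterogame_run`: parameters, seed, per-sweep trajectory,
#'   `rho_equilibrium`, `mcs_executed`, `stationary` flag, extension count,
#'   snapshots (named by MCS index), the quenched `h_field` and the final
#'   strategy grid.
#' @examples
#' p <- sim_params(L = 20, b = 1.05, u = 0, alpha = 0,
#'                 total_mcs = 300, avg_window = 100, n_replicates = 1)
#' r <- run_single(p, seed = 42)
#' r$rho_equilibrium
#' @export
run_single <- function(params, seed = params$seed, h_field = NULL,
                       max_extensions = 10L) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  state <- init_lattice(params, h_field = h_field)
  strat <- state$strategies + 0L  # working grid, mutated in place by C++
  snap_times <- params$snapshot_times
  snapshots <- list()
  if (0L %in% snap_times) snapshots[["0"]] <- strat + 0L

  current_rho <- mean(strat)
  absorbed <- current_rho %in% c(0, 1)
  traj <- numeric(0)
  boundaries <- sort(unique(c(snap_times[snap_times > 0L], params$total_mcs)))
  pos <- 0L
  for (bnd in boundaries) {
    blk <- run_block(strat, state$h_field, params, bnd - pos, absorbed,
                     current_rho)
    absorbed <- blk$absorbed
    traj <- c(traj, blk$rho)
    if (length(traj)) current_rho <- traj[length(traj)]
    pos <- bnd
    if (bnd %in% snap_times) snapshots[[as.character(bnd)]] <- strat + 0L
  }

  window <- params$avg_window
  stationary <- stationarity_check(traj, window, params$stationarity_tol)
  n_ext <- 0L
  while (!stationary && n_ext < max_extensions) {
    blk <- run_block(strat, state$h_field, params, params$extension_block,
                     absorbed, current_rho)
    absorbed <- blk$absorbed
    traj <- c(traj, blk$rho)
    current_rho <- traj[length(traj)]
    n_ext <- n_ext + 1L
    stationary <- stationarity_check(traj, window, params$stationarity_tol)
  }

  structure(
    list(params = params, seed = as.integer(seed),
         rho_trajectory = traj,
         rho_equilibrium = mean(traj[(length(traj) - window + 1L):length(traj)]),
         mcs_executed = length(traj), stationary = stationary,
         n_extensions = n_ext, snapshots = snapshots,
         h_field = state$h_field, final_strategies = strat),
    class = "heterogame_run"
  )
}

#' @export
print.heterogame_run <- function(x, ...) {
  cat(sprintf(
    "Spatial PD run (seed %d): L = %d, b = %g, u = %g, alpha = %g, K = %g\n",
    x$seed, x$params$L, x$params$b, x$params$u, x$params$alpha, x$params$K))
  cat(sprintf("  %d MCS executed (%d extensions), stationary: %s\n",
              x$mcs_executed, x$n_extensions, x$stationary))
  cat(sprintf("  equilibrium rho_c = %.4f (mean of last %d MCS)\n",
              x$rho_equilibrium, x$params$avg_window))
  if (length(x$snapshots)) {
    cat("  snapshots at MCS:", paste(names(x$snapshots), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run a replicate ensemble
#'
#' Derives `n_replicates` child seeds deterministically from the master seed
#' and executes [run_single()] for each, with an independent lattice and
#' (by default) an independently drawn quenched heterogeneity field per
#' replicate. Reports the replicate mean and standard deviation of the
#' equilibrium cooperator fraction.
#'
#' @param params A [sim_params()] object (`n_replicates` and `seed` are
#'   taken from it).
#' @param seeds Optional explicit per-replicate seeds (length
#'   `n_replicates`), overriding the derived ones.
#' @param share_h If `TRUE`, one heterogeneity field (drawn deterministically
#'   from the master seed) is shared by all replicates instead of being
#'   redrawn per replicate.
#' @param keep_runs Keep the full `heterogame_run` objects (default); set
#'   `FALSE` in large sweeps to retain only per-replicate summaries.
#' @return A `heterogame_ensemble` with `rho_mean`, `rho_sd` (`NA` for a
#'   single replicate), a `per_replicate` summary tibble, the seeds, and
#'   (optionally) the runs.
#' @examples
#' p <- sim_params(L = 20, b = 1.05, u = 0.5, alpha = 3, total_mcs = 300,
#'                 avg_window = 100, n_replicates = 2, seed = 7)
#' e <- run_ensemble(p)
#' glance(e)
#' @export
run_ensemble <- function(params, seeds = NULL, share_h = FALSE,
                         keep_runs = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_replicates
  if (is.null(seeds)) {
    seeds <- child_seeds(params$seed, n)
  } else if (length(seeds) != n) {
    stop("configuration error: 'seeds' must have length n_replicates",
         call. = FALSE)
  }
  h_field <- NULL
  if (share_h) {
    set.seed(mix_seed(params$seed, "shared-h-field"))
    h_field <- draw_h_field(params$L)
  }
  runs <- purrr::map(seeds, function(s) run_single(params, seed = s,
                                                   h_field = h_field))
  per_replicate <- tibble::tibble(
    replicate = seq_len(n),
    seed = as.integer(seeds),
    rho_equilibrium = vapply(runs, `[[`, numeric(1), "rho_equilibrium"),
    mcs_executed = vapply(runs, `[[`, integer(1), "mcs_executed"),
    stationary = vapply(runs, `[[`, logical(1), "stationary")
  )
  structure(
    list(params = params, seeds = as.integer(seeds),
         per_replicate = per_replicate,
         rho_mean = mean(per_replicate$rho_equilibrium),
         rho_sd = if (n > 1L) stats::sd(per_replicate$rho_equilibrium) else NA_real_,
         runs = if (keep_runs) runs else NULL),
    class = "heterogame_ensemble"
  )
}

#' @export
print.heterogame_ensemble <- function(x, ...) {
  cat(sprintf(
    "Spatial PD ensemble: %d replicates at L = %d, b = %g, u = %g, alpha = %g\n",
    x$params$n_replicates, x$params$L, x$params$b, x$params$u, x$params$alpha))
  cat(sprintf("  rho_c = %.4f (sd %s)\n", x$rho_mean,
              ifelse(is.na(x$rho_sd), "NA", sprintf("%.4f", x$rho_sd))))
  invisible(x)
}
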