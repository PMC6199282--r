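#' Simulation parameters
#'
#' Immutable description of one experiment: the weak prisoner's dilemma on an
#' `L` x `L` periodic square lattice with temptation `b`, environment weight
#' `u`, preference selection parameter `alpha` and Fermi noise `K`, plus the
#' measurement schedule (total Monte Carlo steps, equilibrium averaging
#' window, stationarity rule, replicate count and master seed).
#'
#' Defaults are the study's reference settings: a 100 x 100 lattice, `K =
#' 0.1`, 6e4 Monte Carlo steps with the cooperator fraction averaged over the
#' final 1e4, a stationarity threshold of 1e-2, and 40 independent replicates.
#'
#' @param L Lattice side length (sites); the lattice has `L^2` players.
#' @param b Temptation to defect, the payoff T of a defector against a
#'   cooperator (R = 1, P = S = 0); must satisfy `b >= 1`.
#' @param u Environment weight in `[0, 1]`: fitness is
#'   `(1 - u) * payoff + u * H` where `H` is the mean heterogeneity of the
#'   four neighbours. `u = 0` recovers the traditional game.
#' @param alpha Preference selection parameter (`>= 0`); the imitation target
#'   is drawn with probability proportional to `exp(alpha * h_y)`. `alpha = 0`
#'   is uniform random neighbour choice.
#' @param K Fermi noise amplitude (`> 0`).
#' @param total_mcs Scheduled number of full Monte Carlo steps (sweeps).
#' @param avg_window Number of final sweeps averaged for the equilibrium
#'   cooperator fraction; also the window of the stationarity check, so
#'   `total_mcs >= 2 * avg_window` is required.
#' @param stationarity_tol Threshold for the stationarity check (strict `<`).
#' @param extension_block Sweeps appended when the stationarity check fails;
#'   defaults to `avg_window`.
#' @param n_replicates Number of independent runs in an ensemble.
#' @param seed Master RNG seed (integer).
#' @param snapshot_times Integer vector of sweep indices at which to record
#'   the strategy grid (0 = initial condition); all must lie in
#'   `[0, total_mcs]`.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params(L = 20, b = 1.1, u = 0.5, alpha = 3,
#'                 total_mcs = 200, avg_window = 50, n_replicates = 2)
#' p
#' @export
sim_params <- function(L = 100L, b = 1.1, u = 0, alpha = 0, K = 0.1,
                       total_mcs = 60000L, avg_window = 10000L,
                       stationarity_tol = 1e-2, extension_block = avg_window,
                       n_replicates = 40L, seed = 1L,
                       snapshot_times = integer(0)) {
  chk_num <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop("configuration error: '", name, "' must be a single finite number",
           call. = FALSE)
    }
  }
  for (nm in c("L", "b", "u", "alpha", "K", "total_mcs", "avg_window",
               "stationarity_tol", "extension_block", "n_replicates", "seed")) {
    chk_num(get(nm), nm)
  }
  fail <- function(name, msg) {
    stop("configuration error: '", name, "' ", msg, call. = FALSE)
  }
  L <- as.integer(L)
  if (L < 2L) fail("L", "must be at least 2")
  if (b < 1) fail("b", "must satisfy b >= 1 (weak prisoner's dilemma)")
  if (u < 0 || u > 1) fail("u", "must lie in [0, 1]")
  if (alpha < 0) fail("alpha", "must be non-negative")
  if (K <= 0) fail("K", "must be positive")
  total_mcs <- as.integer(total_mcs)
  avg_window <- as.integer(avg_window)
  extension_block <- as.integer(extension_block)
  n_replicates <- as.integer(n_replicates)
  seed <- as.integer(seed)
  if (total_mcs < 1L) fail("total_mcs", "must be at least 1")
  if (avg_window < 1L) fail("avg_window", "must be at least 1")
  if (avg_window > total_mcs) fail("avg_window", "must not exceed total_mcs")
  if (2L * avg_window > total_mcs) {
    fail("avg_window",
         "must satisfy 2 * avg_window <= total_mcs (stationarity check needs two windows)")
  }
  if (stationarity_tol <= 0) fail("stationarity_tol", "must be positive")
  if (extension_block < 1L) fail("extension_block", "must be at least 1")
  if (n_replicates < 1L) fail("n_replicates", "must be at least 1")
  snapshot_times <- sort(unique(as.integer(snapshot_times)))
  if (length(snapshot_times) &&
      (any(snapshot_times < 0L) || any(snapshot_times > total_mcs))) {
    fail("snapshot_times", "must lie in [0, total_mcs]")
  }
  structure(
    list(L = L, b = b, u = u, alpha = alpha, K = K, total_mcs = total_mcs,
         avg_window = avg_window, stationarity_tol = stationarity_tol,
         extension_block = extension_block, n_replicates = n_replicates,
         seed = seed, snapshot_times = snapshot_times),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Spatial PD simulation parameters\n")
  cat(sprintf("  lattice: %d x %d (periodic, von Neumann k = 4)\n", x$L, x$L))
  cat(sprintf("  payoffs: T = b = %g, R = 1, P = S = 0\n", x$b))
  cat(sprintf("  u = %g, alpha = %g, K = %g\n", x$u, x$alpha, x$K))
  cat(sprintf("  schedule: %d MCS, averaging last %d, stationarity tol %g\n",
              x$total_mcs, x$avg_window, x$stationarity_tol))
  cat(sprintf("  replicates: %d, master seed %d\n", x$n_replicates, x$seed))
  if (length(x$snapshot_times)) {
    cat("  snapshots at MCS:", paste(x$snapshot_times, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Weak prisoner's dilemma payoff matrix
#'
#' The single-parameter weak PD: reward `R = 1`, temptation `T = b`,
#' punishment and sucker's payoff `P = S = 0`, so `T > R > P = S` for
#' `b > 1`.
#'
#' @param b Temptation to defect (`>= 1`).
#' @return An object of class `payoff_matrix` with elements `R`, `T`, `P`,
#'   `S`.
#' @examples
#' payoff_matrix(1.3)
#' @export
payoff_matrix <- function(b = 1.1) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b < 1) {
    stop("configuration error: 'b' must be a single number >= 1",
         call. = FALSE)
  }
  structure(list(R = 1, T = b, P = 0, S = 0), class = "payoff_matrix")
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat(sprintf("Weak PD payoffs: R = %g, T = %g, P = %g, S = %g\n",
              x$R, x$T, x$P, x$S))
  invisible(x)
}

# Rebuild params with one field changed (revalidates everything).
set_param <- function(params, name, value) {
  stopifnot(inherits(params, "sim_params"))
  if (!name %in% c("b", "u", "alpha", "K", "L", "seed", "n_replicates",
                   "total_mcs", "avg_window", "snapshot_times")) {
    stop("configuration error: unknown parameter '", name, "'", call. = FALSE)
  }
  fields <- unclass(params)
  fields[[name]] <- value
  do.call(sim_params, fields)
}
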