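sweep_param_names <- c("b", "u", "alpha", "K", "L")

check_axis <- function(axis, which) {
  if (!is.list(axis) || !all(c("param", "values") %in% names(axis))) {
    stop("configuration error: '", which,
         "' must be list(param = <name>, values = <numeric>)", call. = FALSE)
  }
  if (!axis$param %in% sweep_param_names) {
    stop("configuration error: sweep parameter must be one of ",
         paste(sweep_param_names, collapse = ", "), call. = FALSE)
  }
  v <- axis$values
  if (!is.numeric(v) || length(v) == 0L || any(diff(v) <= 0)) {
    stop("configuration error: '", which,
         "' values must be non-empty and strictly increasing", call. = FALSE)
  }
  list(param = axis$param, values = as.numeric(v))
}

#' Specify a 1D or 2D parameter sweep
#'
#' @param base_params A [sim_params()] object giving the fixed parameters,
#'   replicate count and master seed.
#' @param axis1 `list(param = , values = )`: parameter name (one of `b`,
#'   `u`, `alpha`, `K`, `L`) and a strictly increasing value grid.
#' @param axis2 Optional second axis of the same form (different parameter).
#' @return A `sweep_spec` object.
#' @examples
#' p <- sim_params(L = 20, alpha = 3, total_mcs = 200, avg_window = 50,
#'                 n_replicates = 2)
#' sweep_spec(p, list(param = "b", values = seq(1, 1.2, 0.1)))
#' @export
sweep_spec <- function(base_params, axis1, axis2 = NULL) {
  stopifnot(inherits(base_params, "sim_params"))
  axis1 <- check_axis(axis1, "axis1")
  if (!is.null(axis2)) {
    axis2 <- check_axis(axis2, "axis2")
    if (axis2$param == axis1$param) {
      stop("configuration error: axis1 and axis2 must sweep different parameters",
           call. = FALSE)
    }
  }
  structure(list(base_params = base_params, axis1 = axis1, axis2 = axis2),
            class = "sweep_spec")
}

#' @export
print.sweep_spec <- function(x, ...) {
  cat(sprintf("Sweep over %s (%d values)", x$axis1$param,
              length(x$axis1$values)))
  if (!is.null(x$axis2)) {
    cat(sprintf(" x %s (%d values)", x$axis2$param, length(x$axis2$values)))
  }
  cat("\n")
  invisible(x)
}

#' Run a parameter sweep
#'
#' Runs a replicate ensemble at every grid point. Each point gets a
#' deterministic seed hashed from the master seed and the point's parameter
#' values, so adding grid points never perturbs existing ones and rerunning
#' the same spec reproduces the grid exactly. A failure at one point marks
#' that point invalid and the sweep continues.
#'
#' @param spec A [sweep_spec()].
#' @param share_h Passed to [run_ensemble()].
#' @param verbose Print one line per completed grid point.
#' @return A `heterogame_sweep`: the spec, a `results` tibble (axis value
#'   column(s), `rho_mean`, `rho_sd`, `n_replicates`, `seed`, `valid`) and
#'   provenance (master seed, package version, timestamps).
#' @examples
#' p <- sim_params(L = 20, u = 0.5, alpha = 3, total_mcs = 200,
#'                 avg_window = 50, n_replicates = 2, seed = 11)
#' sw <- run_sweep(sweep_spec(p, list(param = "b", values = c(1, 1.1))))
#' tidy(sw)
#' @export
run_sweep <- function(spec, share_h = FALSE, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  started <- Sys.time()
  a1 <- spec$axis1
  a2 <- spec$axis2
  grid <- if (is.null(a2)) {
    tibble::tibble(v1 = a1$values)
  } else {
    tidyr::expand_grid(v1 = a1$values, v2 = a2$values)
  }
  master <- spec$base_params$seed
  res <- purrr::pmap(grid, function(v1, v2 = NULL) {
    p <- set_param(spec$base_params, a1$param, v1)
    seed_args <- list(master, a1$param, v1)
    if (!is.null(v2)) {
      p <- set_param(p, a2$param, v2)
      seed_args <- c(seed_args, list(a2$param, v2))
    }
    pt_seed <- do.call(mix_seed, seed_args)
    p <- set_param(p, "seed", pt_seed)
    out <- tryCatch(
      run_ensemble(p, share_h = share_h, keep_runs = FALSE),
      error = function(e) e
    )
    if (inherits(out, "error")) {
      row <- tibble::tibble(rho_mean = NA_real_, rho_sd = NA_real_,
                            n_replicates = p$n_replicates, seed = pt_seed,
                            valid = FALSE)
    } else {
      row <- tibble::tibble(rho_mean = out$rho_mean, rho_sd = out$rho_sd,
                            n_replicates = p$n_replicates, seed = pt_seed,
                            valid = TRUE)
    }
    if (verbose) {
      message(sprintf("  %s = %g%s: rho_c = %s", a1$param, v1,
                      if (is.null(v2)) "" else sprintf(", %s = %g", a2$param, v2),
                      ifelse(row$valid, sprintf("%.4f", row$rho_mean), "failed")))
    }
    row
  })
  results <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  names(results)[1] <- a1$param
  if (!is.null(a2)) names(results)[2] <- a2$param
  structure(
    list(spec = spec, results = results,
         provenance = list(master_seed = master,
                           package_version = as.character(utils::packageVersion("heterogame")),
                           started = format(started, usetz = TRUE),
                           finished = format(Sys.time(), usetz = TRUE))),
    class = "heterogame_sweep"
  )
}

#' @export
print.heterogame_sweep <- function(x, ...) {
  print(x$spec)
  print(x$results, n = 10)
  invisible(x)
}

#' Locate the cooperation optimum along a 1D sweep
#'
#' Returns the grid value of the swept parameter at which the replicate-mean
#' cooperator fraction is maximal. Ties are broken toward the smaller
#' parameter value; invalid grid points are excluded.
#'
#' @param result A `heterogame_sweep` from a 1D sweep.
#' @param axis Name of the swept parameter (must match the sweep's axis).
#' @return A one-row tibble with the optimal parameter value and its
#'   `rho_mean`.
#' @export
locate_optimum <- function(result, axis) {
  stopifnot(inherits(result, "heterogame_sweep"))
  if (!is.null(result$spec$axis2)) {
    stop("locate_optimum requires a 1D sweep", call. = FALSE)
  }
  if (!identical(axis, result$spec$axis1$param)) {
    stop("sweep is over '", result$spec$axis1$param, "', not '", axis, "'",
         call. = FALSE)
  }
  ok <- dplyr::filter(result$results, .data$valid)
  if (nrow(ok) == 0L) stop("no valid grid points in sweep", call. = FALSE)
  best <- ok[which.max(ok$rho_mean), , drop = FALSE]  # which.max: first max
  tibble::tibble(!!axis := best[[axis]], rho_mean = best$rho_mean)
}

#' Strategy snapshots along a single run
#'
#' Runs one simulation and returns the strategy grids recorded at the
#' requested sweep indices (index 0 is the random initial condition).
#'
#' @param params A [sim_params()] with non-empty `snapshot_times`.
#' @param seed Seed for the run; defaults to `params$seed`.
#' @return Named list of integer strategy matrices (1 = C, 0 = D), names
#'   being the MCS indices as characters, in increasing order.
#' @examples
#' p <- sim_params(L = 20, b = 1.1, u = 0.8, alpha = 3, total_mcs = 200,
#'                 avg_window = 50, snapshot_times = c(0, 10, 200))
#' snaps <- snapshot_series(p, seed = 3)
#' sapply(snaps, mean)
#' @export
snapshot_series <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  if (!length(params$snapshot_times)) {
    stop("configuration error: 'snapshot_times' must be non-empty",
         call. = FALSE)
  }
  run <- run_single(params, seed = seed)
  run$snapshots[order(as.integer(names(run$snapshots)))]
}

#' Fraction of same-strategy nearest-neighbour pairs
#'
#' A simple spatial clustering statistic: the fraction of the `2 L^2` unique
#' nearest-neighbour bonds of the torus whose two sites carry the same
#' strategy. A random half-half configuration gives ~0.5; cluster formation
#' raises it.
#'
#' @param grid Integer strategy matrix (or a `lattice_state`).
#' @return A value in `[0, 1]`.
#' @export
pair_concordance <- function(grid) {
  if (inherits(grid, "lattice_state")) grid <- grid$strategies
  L <- nrow(grid)
  stopifnot(is.matrix(grid), ncol(grid) == L)
  dn <- shift_down(L)
  same_v <- grid == grid[dn, , drop = FALSE]   # vertical bonds
  same_h <- grid == grid[, dn, drop = FALSE]   # horizontal bonds
  (sum(same_v) + sum(same_h)) / (2 * L * L)
}
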