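#' Tidy a single run into its trajectory
#'
#' @param x A `heterogame_run`.
#' @param ... Unused.
#' @return Tibble with columns `mcs` (1-based sweep index) and `rho_c`.
#' @export
tidy.heterogame_run <- function(x, ...) {
  tibble::tibble(mcs = seq_along(x$rho_trajectory), rho_c = x$rho_trajectory)
}

#' One-row summary of a single run
#'
#' @param x A `heterogame_run`.
#' @param ... Unused.
#' @return One-row tibble with the run's parameters and outcome.
#' @export
glance.heterogame_run <- function(x, ...) {
  p <- x$params
  tibble::tibble(L = p$L, b = p$b, u = p$u, alpha = p$alpha, K = p$K,
                 seed = x$seed, rho_equilibrium = x$rho_equilibrium,
                 mcs_executed = x$mcs_executed, stationary = x$stationary,
                 n_extensions = x$n_extensions)
}

#' Tidy an ensemble into per-replicate results
#'
#' @param x A `heterogame_ensemble`.
#' @param ... Unused.
#' @return The per-replicate summary tibble (replicate, seed,
#'   `rho_equilibrium`, `mcs_executed`, `stationary`).
#' @export
tidy.heterogame_ensemble <- function(x, ...) x$per_replicate

#' One-row summary of an ensemble
#'
#' @param x A `heterogame_ensemble`.
#' @param ... Unused.
#' @return One-row tibble with the parameters, `rho_mean`, `rho_sd` and the
#'   replicate count.
#' @export
glance.heterogame_ensemble <- function(x, ...) {
  p <- x$params
  tibble::tibble(L = p$L, b = p$b, u = p$u, alpha = p$alpha, K = p$K,
                 rho_mean = x$rho_mean, rho_sd = x$rho_sd,
                 n_replicates = p$n_replicates, master_seed = p$seed)
}

#' Tidy a sweep into its grid of results
#'
#' @param x A `heterogame_sweep`.
#' @param ... Unused.
#' @return The results tibble: axis value column(s), `rho_mean`, `rho_sd`,
#'   `n_replicates`, per-point `seed` and `valid` flag.
#' @export
tidy.heterogame_sweep <- function(x, ...) x$results

#' One-row summary of a sweep
#'
#' @param x A `heterogame_sweep`.
#' @param ... Unused.
#' @return One-row tibble describing axes, grid size and provenance.
#' @export
glance.heterogame_sweep <- function(x, ...) {
  tibble::tibble(
    axis1 = x$spec$axis1$param,
    axis2 = if (is.null(x$spec$axis2)) NA_character_ else x$spec$axis2$param,
    n_points = nrow(x$results),
    n_valid = sum(x$results$valid),
    master_seed = x$provenance$master_seed,
    package_version = x$provenance$package_version
  )
}
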