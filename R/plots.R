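#' Plot the cooperator-fraction trajectory of a run
#'
#' @param object A `heterogame_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.heterogame_run <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$mcs, y = .data$rho_c)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Monte Carlo step",
      y = expression(rho[c]),
      title = sprintf("b = %g, u = %g, alpha = %g (seed %d)",
                      object$params$b, object$params$u, object$params$alpha,
                      object$seed)
    ) +
    ggplot2::theme_minimal()
}

#' Plot replicate equilibria of an ensemble
#'
#' @param object A `heterogame_ensemble`.
#' @param ... Unused.
#' @return A ggplot: per-replicate equilibrium cooperator fractions with the
#'   ensemble mean.
#' @export
autoplot.heterogame_ensemble <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$replicate, y = .data$rho_equilibrium)) +
    ggplot2::geom_point(colour = "#2166ac") +
    ggplot2::geom_hline(yintercept = object$rho_mean, linetype = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "replicate", y = expression(rho[c])) +
    ggplot2::theme_minimal()
}

#' Plot a sweep: cooperation curve (1D) or phase plane (2D)
#'
#' @param object A `heterogame_sweep`.
#' @param ... Unused.
#' @return A ggplot: for a 1D sweep, `rho_mean` against the swept parameter
#'   with a +/- 1 sd ribbon; for a 2D sweep, a colour-coded parameter plane.
#' @export
autoplot.heterogame_sweep <- function(object, ...) {
  a1 <- object$spec$axis1$param
  a2 <- if (is.null(object$spec$axis2)) NULL else object$spec$axis2$param
  d <- dplyr::filter(object$results, .data$valid)
  if (is.null(a2)) {
    g <- ggplot2::ggplot(d, ggplot2::aes(x = .data[[a1]], y = .data$rho_mean))
    if (any(!is.na(d$rho_sd))) {
      g <- g + ggplot2::geom_ribbon(
        ggplot2::aes(ymin = pmax(0, .data$rho_mean - .data$rho_sd),
                     ymax = pmin(1, .data$rho_mean + .data$rho_sd)),
        fill = "#2166ac", alpha = 0.15)
    }
    g + ggplot2::geom_line(colour = "#2166ac") +
      ggplot2::geom_point(colour = "#2166ac") +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(x = a1, y = expression(rho[c])) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data[[a1]], y = .data[[a2]],
                                    fill = .data$rho_mean)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1),
                                    name = expression(rho[c])) +
      ggplot2::labs(x = a1, y = a2) +
      ggplot2::theme_minimal()
  }
}

#' Two-colour raster of a strategy snapshot
#'
#' Cooperators are drawn yellow, defectors blue.
#'
#' @param grid Integer strategy matrix (1 = C, 0 = D) or `lattice_state`.
#' @param title Optional plot title.
#' @return A ggplot.
#' @export
plot_snapshot <- function(grid, title = NULL) {
  if (inherits(grid, "lattice_state")) grid <- grid$strategies
  d <- tidyr::expand_grid(row = seq_len(nrow(grid)), col = seq_len(ncol(grid)))
  d$strategy <- factor(ifelse(grid[cbind(d$row, d$col)] == 1L, "C", "D"),
                       levels = c("C", "D"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$strategy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(C = "#f4d03f", D = "#2166ac")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = title) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "bottom")
}
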