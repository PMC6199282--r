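#' @rdname init_lattice
#' @export
h_levels <- function() (0:40) / 10

# cyclic row/col shift indices for an L x L torus
shift_up <- function(L) c(L, seq_len(L - 1L))
shift_down <- function(L) c(seq_len(L - 1L) + 1L, 1L)

# (row, col) pairs of the 4 torus neighbours of `site`, in the canonical
# order up, down, left, right
neighbor_sites <- function(L, site) {
  r <- site[[1]]; c <- site[[2]]
  up <- if (r == 1L) L else r - 1L
  dn <- if (r == L) 1L else r + 1L
  lf <- if (c == 1L) L else c - 1L
  rt <- if (c == L) 1L else c + 1L
  list(c(up, c), c(dn, c), c(r, lf), c(r, rt))
}

check_site <- function(L, site) {
  if (length(site) != 2L || any(site < 1L) || any(site > L)) {
    stop("site must be a (row, col) pair within the ", L, " x ", L,
         " lattice", call. = FALSE)
  }
}

#' Environment field: mean neighbour heterogeneity for every site
#'
#' Computes `H[r, c]`, the arithmetic mean of the heterogeneity values of the
#' four von Neumann neighbours of each site (the site's own `h` is excluded),
#' with periodic wrap.
#'
#' @param h_field Square numeric matrix of per-site heterogeneity values.
#' @return A matrix of the same shape.
#' @examples
#' h <- matrix(runif(16), 4, 4)
#' environment_field(h)
#' @export
environment_field <- function(h_field) {
  L <- nrow(h_field)
  stopifnot(is.matrix(h_field), ncol(h_field) == L, L >= 2L)
  up <- shift_up(L)
  dn <- shift_down(L)
  (h_field[up, , drop = FALSE] + h_field[dn, , drop = FALSE] +
     h_field[, up, drop = FALSE] + h_field[, dn, drop = FALSE]) / 4
}

#' Environment of a single site
#'
#' The mean heterogeneity of the four torus neighbours of `site`; the focal
#' site's own `h` does not enter.
#'
#' @param h_field Square numeric matrix of heterogeneity values.
#' @param site Integer `(row, col)` pair, 1-based.
#' @return A single environment value.
#' @examples
#' h <- matrix(2, 4, 4)
#' local_environment(h, c(2, 3))  # 2
#' @export
local_environment <- function(h_field, site) {
  L <- nrow(h_field)
  check_site(L, site)
  mean(vapply(neighbor_sites(L, site),
              function(s) h_field[s[1], s[2]], numeric(1)))
}

draw_h_field <- function(L) {
  matrix(h_levels()[sample.int(41L, L * L, replace = TRUE)], L, L)
}

#' Initialize a lattice state
#'
#' Draws the initial configuration from the current RNG stream: each site is
#' a cooperator or defector with probability 1/2, and each heterogeneity
#' value `h` is drawn uniformly from the 41 discrete levels
#' `0.0, 0.1, ..., 4.0`. Both fields are quenched for the duration of a run.
#' `h_levels()` returns those 41 levels.
#'
#' @param params A [sim_params()] object (only `L` is used here).
#' @param h_field Optional pre-drawn heterogeneity matrix, to share one
#'   quenched field across replicates; by default a fresh field is drawn.
#' @return A `lattice_state`: list with `strategies` (integer matrix, 1 = C,
#'   0 = D), `h_field`, `env_field` (consistent with `h_field`) and `L`.
#' @examples
#' set.seed(1)
#' st <- init_lattice(sim_params(L = 10, total_mcs = 10, avg_window = 5))
#' mean(st$strategies)
#' @export
init_lattice <- function(params, h_field = NULL) {
  stopifnot(inherits(params, "sim_params"))
  L <- params$L
  strategies <- matrix(sample(c(0L, 1L), L * L, replace = TRUE), L, L)
  if (is.null(h_field)) {
    h_field <- draw_h_field(L)
  } else {
    stopifnot(is.matrix(h_field), nrow(h_field) == L, ncol(h_field) == L)
  }
  new_lattice_state(strategies, h_field)
}

#' Construct a lattice state from explicit fields
#'
#' Builds a `lattice_state` from a strategy grid and a heterogeneity grid,
#' computing the environment field from `h_field`. Useful for setting up
#' exact configurations in tests and examples; [init_lattice()] draws random
#' ones.
#'
#' @param strategies Square integer matrix of 0 (defector) / 1 (cooperator).
#' @param h_field Square numeric matrix of the same size.
#' @return A `lattice_state`.
#' @export
lattice_state <- function(strategies, h_field) {
  L <- nrow(strategies)
  stopifnot(is.matrix(strategies), ncol(strategies) == L, L >= 2L,
            all(strategies %in% c(0L, 1L)),
            is.matrix(h_field), nrow(h_field) == L, ncol(h_field) == L)
  storage.mode(strategies) <- "integer"
  structure(
    list(strategies = strategies, h_field = h_field,
         env_field = environment_field(h_field), L = L),
    class = "lattice_state"
  )
}

new_lattice_state <- lattice_state

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("Lattice state: %d x %d torus, rho_c = %.4f, mean h = %.3f\n",
              x$L, x$L, mean(x$strategies), mean(x$h_field)))
  invisible(x)
}

#' Cooperator fraction of a strategy grid or lattice state
#'
#' @param x A `lattice_state` or a 0/1 strategy matrix (1 = cooperator).
#' @return The fraction of cooperators in `[0, 1]`.
#' @export
rho_c <- function(x) {
  if (inherits(x, "lattice_state")) x <- x$strategies
  mean(x == 1L)
}

#' Accumulated game payoff of one site
#'
#' Sum over the four torus neighbours of the pairwise weak-PD payoff of the
#' focal strategy against each neighbour: `payoff(C, C) = R`,
#' `payoff(C, D) = S`, `payoff(D, C) = T`, `payoff(D, D) = P`. Computed
#' fresh from the current strategies.
#'
#' @param state A `lattice_state`.
#' @param site Integer `(row, col)` pair, 1-based.
#' @param payoffs A [payoff_matrix()]; defaults to `b = 1.1`.
#' @return The payoff of the focal site.
#' @examples
#' st <- lattice_state(matrix(1L, 3, 3), matrix(1, 3, 3))
#' game_payoff(st, c(2, 2), payoff_matrix(1.5))  # 4 * R = 4
#' @export
game_payoff <- function(state, site, payoffs = payoff_matrix()) {
  stopifnot(inherits(state, "lattice_state"), inherits(payoffs, "payoff_matrix"))
  check_site(state$L, site)
  # rows: focal strategy (D, C); cols: neighbour strategy (D, C)
  lut <- matrix(c(payoffs$P, payoffs$S, payoffs$T, payoffs$R), 2, 2)
  s_x <- state$strategies[site[1], site[2]]
  sum(vapply(neighbor_sites(state$L, site), function(s) {
    lut[s_x + 1L, state$strategies[s[1], s[2]] + 1L]
  }, numeric(1)))
}

#' Fitness: payoff-environment mixture
#'
#' `F = (1 - u) * payoff + u * env`. At `u = 0` fitness is the game payoff
#' alone (the traditional model); at `u = 1` it is entirely environmental.
#' Vectorised over its numeric arguments.
#'
#' @param payoff Game payoff value(s).
#' @param env Environment value(s).
#' @param u Environment weight in `[0, 1]`.
#' @return Fitness value(s).
#' @examples
#' fitness(3, 1.7, u = 0)    # 3
#' fitness(3, 1.7, u = 1)    # 1.7
#' fitness(2, 1, u = 0.5)    # 1.5
#' @export
fitness <- function(payoff, env, u) {
  if (any(u < 0 | u > 1)) {
    stop("configuration error: 'u' must lie in [0, 1]", call. = FALSE)
  }
  (1 - u) * payoff + u * env
}

# 1-based (row, col) <-> 0-based linear index (column-major, matching C++)
site_to_linear <- function(L, site) (site[1] - 1L) + (site[2] - 1L) * L
linear_to_site <- function(L, idx) c(idx %% L + 1L, idx %/% L + 1L)
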