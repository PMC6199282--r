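#' Preference selection probabilities over the four neighbours
#'
#' Softmax over the neighbours' heterogeneity values: neighbour `y` of the
#' focal site is chosen as imitation target with probability
#' `exp(alpha * h_y) / sum_z exp(alpha * h_z)`, the sum running over the four
#' von Neumann neighbours. Computed with a max-shift so large `alpha * h`
#' cannot overflow. `alpha = 0` gives the uniform choice (1/4 each).
#'
#' @param h_field Square numeric matrix of heterogeneity values.
#' @param site Integer `(row, col)` pair, 1-based.
#' @param alpha Preference selection parameter (`>= 0`).
#' @return Numeric vector of length 4 summing to 1, in the neighbour order
#'   up, down, left, right.
#' @examples
#' h <- matrix(1, 4, 4)
#' selection_probabilities(h, c(2, 2), alpha = 3)  # uniform 0.25
#' @export
selection_probabilities <- function(h_field, site, alpha) {
  if (alpha < 0) stop("configuration error: 'alpha' must be non-negative",
                      call. = FALSE)
  L <- nrow(h_field)
  check_site(L, site)
  h_nbr <- vapply(neighbor_sites(L, site),
                  function(s) h_field[s[1], s[2]], numeric(1))
  w <- exp(alpha * (h_nbr - max(h_nbr)))
  w / sum(w)
}

#' Fermi adoption probability
#'
#' Probability that the focal player adopts the chosen neighbour's strategy:
#' `W = 1 / (1 + exp((f_focal - f_neighbor) / K))`. Equal fitnesses give 1/2;
#' a fitter neighbour is imitated with probability above 1/2. Vectorised.
#'
#' @param f_focal Fitness of the focal player.
#' @param f_neighbor Fitness of the selected neighbour.
#' @param K Noise amplitude (`> 0`); `1/K` is the intensity of selection.
#' @return Adoption probability in `(0, 1)` (limits 0/1 reached only by
#'   floating-point underflow).
#' @examples
#' fermi_probability(1, 1, K = 0.1)  # 0.5
#' fermi_probability(0, 1, K = 0.1)  # ~1
#' @export
fermi_probability <- function(f_focal, f_neighbor, K) {
  if (any(K <= 0)) stop("configuration error: 'K' must be positive",
                        call. = FALSE)
  1 / (1 + exp((f_focal - f_neighbor) / K))
}

#' One elementary Monte Carlo update
#'
#' Picks a focal player uniformly at random (or uses `focal`), computes its
#' fitness from its instantaneous payoff and environment, draws one of its
#' four neighbours by [selection_probabilities()], computes that neighbour's
#' fitness the same way, and adopts the neighbour's strategy with the Fermi
#' probability. The RNG draw order is fixed (focal, neighbour, adoption; the
#' adoption draw happens even when both strategies agree) so seeded streams
#' are reproducible.
#'
#' @param state A `lattice_state`.
#' @param params A [sim_params()] object supplying `b`, `u`, `alpha`, `K`.
#' @param focal Optional `(row, col)` pair forcing the focal site (the focal
#'   draw is then skipped).
#' @return A list with `state` (the possibly updated lattice) and `event`, a
#'   one-row tibble: focal and chosen-neighbour coordinates, both fitnesses,
#'   and whether the strategy was adopted / actually changed.
#' @examples
#' set.seed(1)
#' p <- sim_params(L = 10, b = 1.2, u = 0.3, alpha = 2,
#'                 total_mcs = 10, avg_window = 5)
#' st <- init_lattice(p)
#' elementary_step(st, p)$event
#' @export
elementary_step <- function(state, params, focal = NULL) {
  stopifnot(inherits(state, "lattice_state"), inherits(params, "sim_params"))
  L <- state$L
  if (L != params$L) stop("state and params disagree on L", call. = FALSE)
  focal0 <- -1L
  if (!is.null(focal)) {
    check_site(L, focal)
    focal0 <- site_to_linear(L, as.integer(focal))
  }
  strat <- state$strategies + 0L  # private copy; C++ mutates in place
  ev <- cpp_elementary_step(strat, state$h_field, params$b, params$u,
                            params$alpha, params$K, focal0)
  state$strategies <- strat
  fs <- linear_to_site(L, ev$focal)
  ns <- linear_to_site(L, ev$neighbor)
  event <- tibble::tibble(
    focal_row = fs[1], focal_col = fs[2],
    neighbor_row = ns[1], neighbor_col = ns[2],
    focal_fitness = ev$focal_fitness, neighbor_fitness = ev$neighbor_fitness,
    adopted = ev$adopted, flipped = ev$flipped
  )
  list(state = state, event = event)
}

#' One full Monte Carlo step (sweep)
#'
#' Performs `L^2` elementary updates with independently drawn focal sites
#' (random sequential order: some sites may be updated several times, others
#' not at all — each player gets a chance to update once on average).
#'
#' @inheritParams elementary_step
#' @return A list with the updated `state` and `rho_c`, the post-sweep
#'   cooperator fraction.
#' @examples
#' set.seed(1)
#' p <- sim_params(L = 10, b = 1.2, u = 0.3, alpha = 2,
#'                 total_mcs = 10, avg_window = 5)
#' st <- init_lattice(p)
#' mcs_sweep(st, p)$rho_c
#' @export
mcs_sweep <- function(state, params) {
  stopifnot(inherits(state, "lattice_state"), inherits(params, "sim_params"))
  if (state$L != params$L) stop("state and params disagree on L", call. = FALSE)
  strat <- state$strategies + 0L
  res <- cpp_run_sweeps(strat, state$h_field, params$b, params$u,
                        params$alpha, params$K, 1L, FALSE)
  state$strategies <- strat
  list(state = state, rho_c = res$rho[1])
}
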