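# Exact one-step calculators used to validate the stochastic kernel. These
# deliberately share no code with the C++ kernel or the model helpers: every
# payoff, environment, selection and adoption probability is recomputed here
# in plain straight-line R, so agreement between kernel and oracle is
# evidence rather than tautology.

#' Local configuration around one focal player
#'
#' Everything that enters the exact probability of a strategy change of the
#' focal player in one forced elementary update: the focal strategy and
#' heterogeneity, and for each of the four neighbours its strategy, its
#' heterogeneity, and the strategies and heterogeneities of its three
#' remaining neighbours (the fourth being the focal player).
#'
#' @param focal_strategy `"C"` or `"D"`.
#' @param focal_h Heterogeneity of the focal player.
#' @param neighbors List of 4 lists, each with elements `strategy` (`"C"` /
#'   `"D"`), `h`, `other_strategies` (character, length 3) and `other_h`
#'   (numeric, length 3).
#' @param b,u,alpha,K Model parameters.
#' @return A `local_config` object.
#' @export
local_config <- function(focal_strategy, focal_h, neighbors, b, u, alpha, K) {
  ok_strat <- function(s) is.character(s) && all(s %in% c("C", "D"))
  if (!ok_strat(focal_strategy) || length(focal_strategy) != 1L) {
    stop("contract error: focal_strategy must be \"C\" or \"D\"", call. = FALSE)
  }
  if (!is.numeric(focal_h) || length(focal_h) != 1L) {
    stop("contract error: focal_h must be a single number", call. = FALSE)
  }
  if (!is.list(neighbors) || length(neighbors) != 4L) {
    stop("contract error: exactly 4 neighbors required", call. = FALSE)
  }
  for (nb in neighbors) {
    if (!all(c("strategy", "h", "other_strategies", "other_h") %in% names(nb)) ||
        !ok_strat(nb$strategy) || length(nb$strategy) != 1L ||
        !is.numeric(nb$h) || length(nb$h) != 1L ||
        !ok_strat(nb$other_strategies) || length(nb$other_strategies) != 3L ||
        !is.numeric(nb$other_h) || length(nb$other_h) != 3L) {
      stop("contract error: each neighbor needs strategy, h, 3 other_strategies and 3 other_h",
           call. = FALSE)
    }
  }
  structure(list(focal_strategy = focal_strategy, focal_h = focal_h,
                 neighbors = neighbors, b = b, u = u, alpha = alpha, K = K),
            class = "local_config")
}

# pairwise weak-PD payoff, oracle-side
pair_payoff_chr <- function(mine, theirs, b) {
  if (mine == "C") {
    if (theirs == "C") 1 else 0
  } else {
    if (theirs == "C") b else 0
  }
}

#' Exact flip probability of the focal player
#'
#' Closed-form probability that one forced elementary update changes the
#' focal player's strategy: the sum over opposite-strategy neighbours `y` of
#' (softmax selection probability of `y`) times (Fermi adoption probability
#' given the two fitnesses), all evaluated from the supplied configuration.
#'
#' @param config A [local_config()].
#' @return A probability in `[0, 1]`.
#' @examples
#' nb <- replicate(4, list(strategy = "C", h = 1,
#'                         other_strategies = rep("C", 3),
#'                         other_h = rep(1, 3)), simplify = FALSE)
#' cfg <- local_config("C", 1, nb, b = 1.2, u = 0.5, alpha = 2, K = 0.1)
#' exact_flip_probability(cfg)  # 0: no opposite-strategy neighbor
#' @export
exact_flip_probability <- function(config) {
  if (!inherits(config, "local_config")) {
    stop("contract error: config must be a local_config", call. = FALSE)
  }
  nbs <- config$neighbors
  b <- config$b; u <- config$u; alpha <- config$alpha; K <- config$K

  h_nbr <- vapply(nbs, `[[`, numeric(1), "h")
  w <- exp(alpha * (h_nbr - max(h_nbr)))
  omega <- w / sum(w)

  px <- 0
  for (nb in nbs) px <- px + pair_payoff_chr(config$focal_strategy, nb$strategy, b)
  hx <- mean(h_nbr)
  fx <- (1 - u) * px + u * hx

  p_flip <- 0
  for (k in seq_len(4L)) {
    nb <- nbs[[k]]
    if (nb$strategy == config$focal_strategy) next
    py <- pair_payoff_chr(nb$strategy, config$focal_strategy, b)
    for (j in seq_len(3L)) {
      py <- py + pair_payoff_chr(nb$strategy, nb$other_strategies[j], b)
    }
    hy <- (config$focal_h + sum(nb$other_h)) / 4
    fy <- (1 - u) * py + u * hy
    p_flip <- p_flip + omega[k] * (1 / (1 + exp((fx - fy) / K)))
  }
  p_flip
}

#' Extract the local configuration of a lattice site
#'
#' Builds the [local_config()] of `site` from a full lattice state, for
#' cross-checking the oracle against kernel simulations. Requires `L >= 3`
#' so each neighbour's neighbourhood contains the focal site exactly once.
#'
#' @param state A `lattice_state`.
#' @param site Integer `(row, col)` pair.
#' @param params A [sim_params()] supplying `b`, `u`, `alpha`, `K`.
#' @return A `local_config`.
#' @export
local_config_from_state <- function(state, site, params) {
  stopifnot(inherits(state, "lattice_state"), inherits(params, "sim_params"))
  L <- state$L
  if (L < 3L) stop("contract error: local_config extraction needs L >= 3",
                   call. = FALSE)
  check_site(L, site)
  chr <- function(s) if (s == 1L) "C" else "D"
  nbs <- lapply(neighbor_sites(L, site), function(y) {
    yy <- neighbor_sites(L, y)
    is_focal <- vapply(yy, function(z) all(z == site), logical(1))
    others <- yy[!is_focal]
    list(strategy = chr(state$strategies[y[1], y[2]]),
         h = state$h_field[y[1], y[2]],
         other_strategies = vapply(others, function(z)
           chr(state$strategies[z[1], z[2]]), character(1)),
         other_h = vapply(others, function(z)
           state$h_field[z[1], z[2]], numeric(1)))
  })
  local_config(chr(state$strategies[site[1], site[2]]),
               state$h_field[site[1], site[2]],
               nbs, params$b, params$u, params$alpha, params$K)
}

#' Exact one-step flip distribution over a whole (small) lattice
#'
#' For every site, the probability that a single elementary update —
#' including the uniform `1/L^2` focal draw — flips that site's strategy.
#' Together with the no-change probability these masses sum to one.
#' Intended for small lattices (the cost is `O(L^2)` but the point is
#' exhaustive validation, recommended `L <= 6`).
#'
#' @param state A `lattice_state`.
#' @param params A [sim_params()].
#' @return List with `flip_prob` (matrix of per-site flip probabilities) and
#'   `no_change` (scalar; `1 - sum(flip_prob)`).
#' @export
exact_one_step_distribution <- function(state, params) {
  stopifnot(inherits(state, "lattice_state"), inherits(params, "sim_params"))
  L <- state$L
  N <- L * L
  strat <- state$strategies
  h <- state$h_field
  b <- params$b; u <- params$u; alpha <- params$alpha; K <- params$K

  wrap <- function(i) ((i - 1L) %% L) + 1L
  nbrs_of <- function(r, c) {
    list(c(wrap(r - 1L), c), c(wrap(r + 1L), c),
         c(r, wrap(c - 1L)), c(r, wrap(c + 1L)))
  }
  pay <- function(r, c) {
    s <- strat[r, c]
    tot <- 0
    for (z in nbrs_of(r, c)) {
      sz <- strat[z[1], z[2]]
      tot <- tot + if (s == 1L) (if (sz == 1L) 1 else 0) else
        (if (sz == 1L) b else 0)
    }
    tot
  }
  env <- function(r, c) {
    mean(vapply(nbrs_of(r, c), function(z) h[z[1], z[2]], numeric(1)))
  }

  flip <- matrix(0, L, L)
  for (c in seq_len(L)) {
    for (r in seq_len(L)) {
      nb <- nbrs_of(r, c)
      h_nbr <- vapply(nb, function(z) h[z[1], z[2]], numeric(1))
      w <- exp(alpha * (h_nbr - max(h_nbr)))
      omega <- w / sum(w)
      fx <- (1 - u) * pay(r, c) + u * env(r, c)
      p <- 0
      for (k in seq_len(4L)) {
        y <- nb[[k]]
        if (strat[y[1], y[2]] == strat[r, c]) next
        fy <- (1 - u) * pay(y[1], y[2]) + u * env(y[1], y[2])
        p <- p + omega[k] * (1 / (1 + exp((fx - fy) / K)))
      }
      flip[r, c] <- p / N
    }
  }
  list(flip_prob = flip, no_change = 1 - sum(flip))
}
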