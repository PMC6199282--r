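# Named scaled-down reproductions of the study's headline results. Each runs
# at L = 50 with 7000 MCS averaging the last 2000 — the desk-scale protocol —
# and reports measured quantities with their expected bands.

repro_base <- function(seed, n_replicates) {
  sim_params(L = 50L, K = 0.1, total_mcs = 7000L, avg_window = 2000L,
             n_replicates = n_replicates, seed = seed)
}

repro_defs <- function() {
  list(
    "u1-neutrality" = list(
      description = paste(
        "Purely environmental fitness (u = 1, alpha = 3): the ensemble-mean",
        "equilibrium cooperator fraction stays at 0.5 independently of b",
        "(b in {1.1, 1.3}, 20 replicates each)."),
      fun = function(seed) {
        rows <- purrr::map(c(1.1, 1.3), function(b) {
          p <- repro_base(mix_seed(seed, "u1-neutrality", b), 20L)
          p <- set_param(set_param(set_param(p, "u", 1), "alpha", 3), "b", b)
          ens <- run_ensemble(p, keep_runs = FALSE)
          tibble::tibble(b = b, rho_mean = ens$rho_mean, rho_sd = ens$rho_sd,
                         n = p$n_replicates)
        })
        per_b <- dplyr::bind_rows(rows)
        se <- per_b$rho_sd / sqrt(per_b$n)
        within <- abs(per_b$rho_mean - 0.5) <= 3 * se
        se_diff <- sqrt(sum(se^2))
        b_indep <- abs(diff(per_b$rho_mean)) <= 3 * se_diff
        tibble::tibble(
          quantity = c("grand_mean_rho", "abs_b_difference"),
          value = c(mean(per_b$rho_mean), abs(diff(per_b$rho_mean))),
          n = sum(per_b$n),
          target = c("within 3 SE of 0.5 at each b", "<= 3 SE between b values"),
          pass = c(all(within), b_indep)
        )
      }),
    "alpha0-u-sweep" = list(
      description = paste(
        "Heterogeneity alone (alpha = 0, b = 1.1): sweeping u over 0..1 in",
        "steps of 0.1 (10 replicates per point), the cooperator fraction",
        "peaks near 0.6 at u near 0.7."),
      fun = function(seed) {
        p <- repro_base(mix_seed(seed, "alpha0-u-sweep"), 10L)
        p <- set_param(set_param(p, "alpha", 0), "b", 1.1)
        sw <- run_sweep(sweep_spec(p, list(param = "u", values = seq(0, 1, 0.1))))
        opt <- locate_optimum(sw, "u")
        tibble::tibble(
          quantity = c("max_rho", "argmax_u"),
          value = c(opt$rho_mean, opt$u),
          n = nrow(sw$results) * 10L,
          target = c("0.6 +/- 0.1", "0.7 +/- 0.1"),
          pass = c(abs(opt$rho_mean - 0.6) <= 0.1, abs(opt$u - 0.7) <= 0.1)
        )
      }),
    "high-u-cooperation" = list(
      description = paste(
        "Strong environmental weight (u = 0.8, alpha = 3) sustains",
        "cooperation above 80% even at b = 1.3 (10 replicates)."),
      fun = function(seed) {
        p <- repro_base(mix_seed(seed, "high-u-cooperation"), 10L)
        p <- set_param(set_param(set_param(p, "u", 0.8), "alpha", 3), "b", 1.3)
        ens <- run_ensemble(p, keep_runs = FALSE)
        tibble::tibble(quantity = "rho_percent", value = 100 * ens$rho_mean,
                       n = p$n_replicates, target = ">= 80",
                       pass = 100 * ens$rho_mean >= 80)
      }),
    "optimal-alpha" = list(
      description = paste(
        "Preference-selection resonance (u = 0.5, b = 1.05): sweeping alpha",
        "over 0..12 (5 replicates per point), the cooperation optimum lies",
        "at alpha between 2 and 6."),
      fun = function(seed) {
        p <- repro_base(mix_seed(seed, "optimal-alpha"), 5L)
        p <- set_param(set_param(p, "u", 0.5), "b", 1.05)
        sw <- run_sweep(sweep_spec(p, list(param = "alpha", values = 0:12)))
        opt <- locate_optimum(sw, "alpha")
        tibble::tibble(
          quantity = c("argmax_alpha", "max_rho"),
          value = c(opt$alpha, opt$rho_mean),
          n = nrow(sw$results) * 5L,
          target = c("in [2, 6]", "(informational)"),
          pass = c(opt$alpha >= 2 && opt$alpha <= 6, NA)
        )
      })
  )
}

#' List the packaged scaled-down reproductions
#'
#' @return Tibble with the reproduction names and what each measures.
#' @export
reproductions <- function() {
  defs <- repro_defs()
  tibble::tibble(name = names(defs),
                 description = vapply(defs, `[[`, character(1), "description"))
}

#' Run a named scaled-down reproduction
#'
#' Executes one of the packaged desk-scale experiments (see
#' [reproductions()]) with all randomness derived from `seed`, and compares
#' each measured quantity against its expected band.
#'
#' @param name Reproduction name, one of `reproductions()$name`.
#' @param seed Master seed (integer).
#' @return A `heterogame_reproduction`: the name, seed, and a `measurements`
#'   tibble (`quantity`, `value`, `n`, `target`, `pass`).
#' @export
run_reproduction <- function(name, seed) {
  defs <- repro_defs()
  if (!name %in% names(defs)) {
    stop("unknown reproduction '", name, "'; see reproductions()",
         call. = FALSE)
  }
  seed <- as.integer(seed)
  structure(list(name = name, seed = seed,
                 description = defs[[name]]$description,
                 measurements = defs[[name]]$fun(seed)),
            class = "heterogame_reproduction")
}

#' @export
print.heterogame_reproduction <- function(x, ...) {
  cat("Reproduction:", x$name, "(seed", paste0(x$seed, ")"), "\n")
  cat(" ", x$description, "\n")
  m <- x$measurements
  for (i in seq_len(nrow(m))) {
    status <- if (is.na(m$pass[i])) "  --  " else
      if (m$pass[i]) "PASS" else "FAIL"
    cat(sprintf("  %-18s %10.4f  target %-28s %s\n",
                m$quantity[i], m$value[i], m$target[i], status))
  }
  invisible(x)
}
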