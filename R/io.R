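#' Parse an axis specification string
#'
#' Accepts `"b=1.0:1.5:0.05"` (from:to:step) or `"alpha=0,1,2,3"` (explicit
#' comma-separated values).
#'
#' @param text Axis string.
#' @return `list(param = , values = )` suitable for [sweep_spec()].
#' @examples
#' parse_axis("u=0:1:0.1")
#' @export
parse_axis <- function(text) {
  parts <- strsplit(text, "=", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop("configuration error: axis must look like 'name=from:to:step' or 'name=v1,v2,...'",
         call. = FALSE)
  }
  vals <- if (grepl(":", parts[2], fixed = TRUE)) {
    fts <- as.numeric(strsplit(parts[2], ":", fixed = TRUE)[[1]])
    if (length(fts) != 3L || anyNA(fts)) {
      stop("configuration error: range axis must be 'from:to:step'", call. = FALSE)
    }
    # tolerate floating-point drift at the upper end
    seq(fts[1], fts[2] + fts[3] * 1e-9, by = fts[3])
  } else {
    as.numeric(strsplit(parts[2], ",", fixed = TRUE)[[1]])
  }
  if (anyNA(vals)) stop("configuration error: non-numeric axis values",
                        call. = FALSE)
  list(param = parts[1], values = round(vals, 10))
}

#' Load simulation parameters (or a sweep) from a config file
#'
#' Reads a flat YAML key-value file whose keys match the [sim_params()]
#' fields; unknown keys are rejected and out-of-range values raise the named
#' configuration error of [sim_params()]. An empty file yields the package
#' defaults. The optional keys `axis1` / `axis2` (axis strings, see
#' [parse_axis()]) turn the result into a [sweep_spec()]. Entries in
#' `overrides` (e.g. from CLI flags) take precedence over file values.
#'
#' @param path Path to the YAML file.
#' @param overrides Named list of values overriding the file.
#' @return A `sim_params` or, when an axis is given, a `sweep_spec`.
#' @export
load_config <- function(path, overrides = list()) {
  if (!file.exists(path)) {
    stop("configuration error: config file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) {
    stop("configuration error: config must be a flat key-value mapping",
         call. = FALSE)
  }
  allowed <- c(names(formals(sim_params)), "axis1", "axis2")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("configuration error: unknown key '", unknown[1], "'", call. = FALSE)
  }
  unknown_ov <- setdiff(names(overrides), allowed)
  if (length(unknown_ov)) {
    stop("configuration error: unknown key '", unknown_ov[1], "'",
         call. = FALSE)
  }
  cfg <- utils::modifyList(cfg, overrides)
  axis1 <- cfg$axis1
  axis2 <- cfg$axis2
  cfg$axis1 <- NULL
  cfg$axis2 <- NULL
  params <- do.call(sim_params, cfg)
  if (is.null(axis1)) {
    if (!is.null(axis2)) {
      stop("configuration error: 'axis2' requires 'axis1'", call. = FALSE)
    }
    return(params)
  }
  sweep_spec(params, parse_axis(axis1),
             if (is.null(axis2)) NULL else parse_axis(axis2))
}

write_csv6 <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- fmt6(out[[nm]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  path
}

#' Write a strategy snapshot as a plain-text grid
#'
#' Format: a header line `# rows cols mcs`, then one line per lattice row of
#' `C`/`D` characters (row 1 first, columns left to right).
#'
#' @param grid Integer strategy matrix (1 = C, 0 = D).
#' @param path Output path.
#' @param mcs MCS index recorded in the header.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(grid, path, mcs = 0L) {
  lines <- c(sprintf("# %d %d %d", nrow(grid), ncol(grid), as.integer(mcs)),
             apply(grid, 1L, function(r) paste(ifelse(r == 1L, "C", "D"),
                                               collapse = "")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text strategy snapshot
#'
#' @param path Path written by [write_snapshot()].
#' @return Integer strategy matrix with attribute `mcs`.
#' @export
read_snapshot <- function(path) {
  if (!file.exists(path)) stop("snapshot file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- as.integer(strsplit(sub("^#\\s*", "", lines[1]), "\\s+")[[1]])
  rows <- hdr[1]; cols <- hdr[2]
  body <- lines[-1]
  if (length(body) != rows) stop("snapshot corrupt: wrong row count in ", path,
                                 call. = FALSE)
  grid <- t(vapply(body, function(ln) {
    as.integer(strsplit(ln, "")[[1]] == "C")
  }, integer(cols)))
  dimnames(grid) <- NULL
  attr(grid, "mcs") <- hdr[3]
  grid
}

#' Write a snapshot as an ASCII portable graymap (PGM, P2)
#'
#' Cooperators map to gray level 255, defectors to 0.
#'
#' @inheritParams write_snapshot
#' @return `path`, invisibly.
#' @export
write_snapshot_pgm <- function(grid, path, mcs = 0L) {
  lines <- c("P2", sprintf("# mcs %d", as.integer(mcs)),
             sprintf("%d %d", ncol(grid), nrow(grid)), "255",
             apply(grid, 1L, function(r) paste(ifelse(r == 1L, 255L, 0L),
                                               collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

write_manifest <- function(path, kind, params, files, extra = list()) {
  manifest <- c(list(
    kind = kind,
    package = "heterogame",
    package_version = as.character(utils::packageVersion("heterogame")),
    created = format(Sys.time(), usetz = TRUE),
    parameters = unclass(params),
    files = basename(files)
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Write simulation results to a directory
#'
#' Persists a result object as version-control-friendly text: CSV tables
#' (numeric fields at 6 significant digits), a JSON manifest holding the
#' resolved parameters and seeds (sufficient to re-run the computation
#' bit-identically), and — for runs with snapshots — plain-text strategy
#' grids plus PGM images.
#'
#' @param result A `heterogame_run`, `heterogame_ensemble` or
#'   `heterogame_sweep`.
#' @param path Output directory (created if missing).
#' @param ... Unused.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(result, path, ...) UseMethod("write_results")

#' @export
write_results.heterogame_run <- function(result, path, ...) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  files <- c(files, write_csv6(tidy(result), file.path(path, "trajectory.csv")))
  for (nm in names(result$snapshots)) {
    g <- result$snapshots[[nm]]
    files <- c(files,
               write_snapshot(g, file.path(path, sprintf("snapshot_%s.txt", nm)),
                              as.integer(nm)),
               write_snapshot_pgm(g, file.path(path, sprintf("snapshot_%s.pgm", nm)),
                                  as.integer(nm)))
  }
  mf <- write_manifest(file.path(path, "manifest.json"), "run", result$params,
                       files,
                       extra = list(seed = result$seed,
                                    rho_equilibrium = result$rho_equilibrium,
                                    mcs_executed = result$mcs_executed,
                                    stationary = result$stationary))
  invisible(c(files, mf))
}

#' @export
write_results.heterogame_ensemble <- function(result, path, ...) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    write_csv6(glance(result), file.path(path, "ensemble.csv")),
    write_csv6(tidy(result), file.path(path, "replicates.csv"))
  )
  mf <- write_manifest(file.path(path, "manifest.json"), "ensemble",
                       result$params, files,
                       extra = list(master_seed = result$params$seed,
                                    replicate_seeds = result$seeds,
                                    rho_mean = result$rho_mean,
                                    rho_sd = result$rho_sd))
  invisible(c(files, mf))
}

#' @export
write_results.heterogame_sweep <- function(result, path, ...) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cols <- c(names(result$results)[seq_len(1L + !is.null(result$spec$axis2))],
            "rho_mean", "rho_sd", "n_replicates")
  files <- write_csv6(result$results[cols], file.path(path, "sweep.csv"))
  mf <- write_manifest(file.path(path, "manifest.json"), "sweep",
                       result$spec$base_params, files,
                       extra = list(axis1 = result$spec$axis1,
                                    axis2 = result$spec$axis2,
                                    provenance = result$provenance,
                                    point_seeds = result$results$seed))
  invisible(c(files, mf))
}
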