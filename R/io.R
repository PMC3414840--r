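# Configuration, CSV export with provenance headers, and the run driver
# behind the command-line interface (inst/cli/wallkinetics.R).
#
# Config format: flat key = value lines grouped under TOML-style section
# headers [dimensionless] / [dimensional] / [grids] / [numerics] / [run].
# Exactly one of [dimensionless] and [dimensional] may be present.
# CSV dialect: comma-separated, '.' decimal, '#'-prefixed provenance
# header lines carrying the full parameter set.

param_header_lines <- function(p) {
  c(sprintf("# wallkinetics %s", as.character(utils::packageVersion("wallkinetics"))),
    sprintf("# beta=%.17g sigma=%.17g Gamma=%.17g", p$beta, p$sigma, p$Gamma),
    sprintf("# g_xet=%.17g g_xeh=%.17g g_exp=%.17g coupling=%s scale=%.17g",
            p$g_xet, p$g_xeh, p$g_exp, p$enzyme_coupling, p$breakage_scale))
}

#' Export a curve object to CSV with a provenance header
#'
#' Writes a [stress_curve()] (columns `alpha, sigma_inf, phi_eff`), a
#' [steady_profile()] (`y, n, L, stress_density`) or a [transient_trace()]
#' (`t, alpha_t, sigma_crosslink, sigma_total`) as a comma-separated file
#' with `#`-prefixed header lines recording the full parameter set. Output
#' is byte-deterministic for identical inputs.
#'
#' @param x the object to export.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(x, path) {
  UseMethod("write_curve_csv")
}

write_csv_impl <- function(df, p, path, extra = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(param_header_lines(p), extra), con)
  writeLines(paste(names(df), collapse = ","), con)
  rows <- do.call(paste, c(lapply(df, function(col) {
    sprintf("%.15g", col)
  }), sep = ","))
  writeLines(rows, con)
  invisible(path)
}

#' @export
write_curve_csv.stress_curve <- function(x, path) {
  write_csv_impl(as.data.frame(x)[c("alpha", "sigma_inf", "phi_eff")],
                 attr(x, "params"), path)
}

#' @export
write_curve_csv.crosslink_profile <- function(x, path) {
  write_csv_impl(as.data.frame(x), x$params, path,
                 extra = sprintf("# alpha=%.17g A=%.17g", x$alpha, x$A))
}

#' @export
write_curve_csv.transient_trace <- function(x, path) {
  pk <- attr(x, "peak")
  write_csv_impl(
    as.data.frame(x)[c("t", "alpha_t", "sigma_crosslink", "sigma_total")],
    attr(x, "params"), path,
    extra = sprintf("# alpha=%.17g alpha_t_peak=%.17g sigma_peak=%.17g",
                    attr(x, "alpha"), pk$alpha_t_peak, pk$sigma_peak))
}

#' @export
write_curve_csv.data.frame <- function(x, path) {
  p <- attr(x, "params")
  if (is.null(p)) p <- wall_params(beta = 1)  # header still written
  write_csv_impl(x, p, path)
}

#' Read a run configuration file
#'
#' Parses the flat TOML-style configuration format (`key = value` lines
#' under `[section]` headers; `#` comments). Numeric-looking values are
#' coerced to numbers. Supplying both a `[dimensionless]` and a
#' `[dimensional]` block is an error.
#'
#' @param path config file path.
#' @return A named list of sections, each a named list of values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- "run"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2)
      stop(sprintf("cannot parse config line: '%s'", ln), call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[section]][[key]] <- if (!is.na(num)) num else val
  }
  if (!is.null(out$dimensionless) && !is.null(out$dimensional))
    stop("config mixes [dimensionless] and [dimensional] parameter blocks",
         call. = FALSE)
  out
}

#' Build and validate a run configuration
#'
#' Assembles the configuration consumed by [run_wall_model()]. Invalid
#' configurations raise a structured error listing every offending key.
#'
#' @param mode one of `"steady"`, `"transient"`, `"enzyme-sweep"`,
#'   `"expansin-sweep"`, `"lockhart"`, `"dimensional"`.
#' @param params a [wall_params()] object (all modes except
#'   `"dimensional"`).
#' @param dimensional a [dimensional_params()] object (mode
#'   `"dimensional"`).
#' @param alpha_min,alpha_max,alpha_n log-spaced strain-rate grid.
#' @param alpha single strain rate (mode `"transient"`).
#' @param sweep_values enzyme strengths for the sweep modes.
#' @param sweep_enzyme `"xeh"` or `"xet"` (mode `"enzyme-sweep"`).
#' @param outdir output directory.
#' @param seed integer seed recorded with the run.
#' @param numerics a [wall_numerics()] object, or `NULL`.
#' @return A validated config list of class `run_config`.
#' @export
run_config <- function(mode, params = NULL, dimensional = NULL,
                       alpha_min = 0.1, alpha_max = 100, alpha_n = 50L,
                       alpha = 1, sweep_values = c(0, 1, 10, 100),
                       sweep_enzyme = "xeh", outdir = ".", seed = 1L,
                       numerics = NULL) {
  modes <- c("steady", "transient", "enzyme-sweep", "expansin-sweep",
             "lockhart", "dimensional")
  bad <- character(0)
  if (!mode %in% modes)
    bad <- c(bad, sprintf("mode (got '%s'; must be one of %s)", mode,
                          paste(modes, collapse = ", ")))
  if (mode == "dimensional") {
    if (!inherits(dimensional, "dimensional_params"))
      bad <- c(bad, "dimensional (required for mode 'dimensional')")
  } else if (!inherits(params, "wall_params")) {
    bad <- c(bad, "params (a wall_params object is required)")
  }
  if (!is.numeric(alpha_min) || !is.numeric(alpha_max) ||
      alpha_min <= 0 || alpha_max <= alpha_min)
    bad <- c(bad, "alpha_min/alpha_max (need 0 < alpha_min < alpha_max)")
  if (!is.numeric(alpha_n) || alpha_n < 1)
    bad <- c(bad, "alpha_n (need >= 1 grid point)")
  if (!is.numeric(alpha) || alpha <= 0)
    bad <- c(bad, "alpha (need > 0)")
  if (mode %in% c("enzyme-sweep", "expansin-sweep") &&
      (length(sweep_values) < 1 || any(sweep_values < 0)))
    bad <- c(bad, "sweep_values (need non-negative strengths)")
  if (mode == "enzyme-sweep" && !sweep_enzyme %in% c("xeh", "xet"))
    bad <- c(bad, "sweep_enzyme (must be 'xeh' or 'xet')")
  if (length(bad) > 0)
    stop("invalid run configuration:\n  - ",
         paste(bad, collapse = "\n  - "), call. = FALSE)
  structure(list(mode = mode, params = params, dimensional = dimensional,
                 alpha_min = alpha_min, alpha_max = alpha_max,
                 alpha_n = as.integer(alpha_n), alpha = alpha,
                 sweep_values = sweep_values, sweep_enzyme = sweep_enzyme,
                 outdir = outdir, seed = as.integer(seed),
                 numerics = as_wall_numerics(numerics)),
            class = "run_config")
}

#' Execute a configured run
#'
#' Dispatches on the configured mode, writes the CSV/JSON artifacts into
#' the output directory and returns a summary record. Outputs are
#' deterministic for a fixed configuration and seed.
#'
#' @param config a [run_config()] object.
#' @return A list summarising the run (mode, files written, key numbers),
#'   invisibly.
#' @export
run_wall_model <- function(config) {
  if (!inherits(config, "run_config"))
    stop("expected a 'run_config' object", call. = FALSE)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  grid <- exp(seq(log(config$alpha_min), log(config$alpha_max),
                  length.out = config$alpha_n))
  num <- config$numerics
  files <- character(0)
  info <- list(mode = config$mode, seed = config$seed)
  out_path <- function(name) file.path(config$outdir, name)

  if (config$mode == "steady") {
    cur <- stress_curve(grid, config$params, num)
    files <- out_path("steady_curve.csv")
    write_curve_csv(cur, files)
    info$monotone <- attr(cur, "monotone")
    info$sigma_range <- range(cur$sigma_inf)
  } else if (config$mode == "transient") {
    tr <- transient_trace(config$alpha, config$params, num)
    files <- out_path("transient_trace.csv")
    write_curve_csv(tr, files)
    info$peak <- attr(tr, "peak")
  } else if (config$mode %in% c("enzyme-sweep", "expansin-sweep")) {
    base <- config$params
    for (g in config$sweep_values) {
      pg <- if (config$mode == "expansin-sweep") {
        wall_params(beta = base$beta, sigma = base$sigma,
                    Gamma = base$Gamma, g_exp = g,
                    rest_length = base$rest_length)
      } else if (config$sweep_enzyme == "xeh") {
        wall_params(beta = base$beta, sigma = base$sigma,
                    Gamma = base$Gamma, g_xeh = g, g_xet = base$g_xet)
      } else {
        wall_params(beta = base$beta, sigma = base$sigma,
                    Gamma = base$Gamma, g_xet = g, g_xeh = base$g_xeh)
      }
      cur <- stress_curve(grid, pg, num)
      f <- out_path(sprintf("%s_g%g.csv",
                            sub("-sweep", "", config$mode), g))
      write_curve_csv(cur, f)
      files <- c(files, f)
    }
  } else if (config$mode == "lockhart") {
    cur <- stress_curve(grid, config$params, num)
    fit <- lockhart_extract(cur, num)
    f1 <- out_path("steady_curve.csv"); write_curve_csv(cur, f1)
    f2 <- out_path("lockhart_fit.json")
    writeLines(format(fit), f2)
    files <- c(f1, f2)
    info$fit <- fit
  } else if (config$mode == "dimensional") {
    nd <- nondimensionalize(config$dimensional)
    rates <- exp(seq(log(config$alpha_min), log(config$alpha_max),
                     length.out = config$alpha_n)) * nd$scales$k0
    dc <- dimensional_curve(config$dimensional, rates, num)
    attr(dc, "params") <- nd$params
    files <- out_path("dimensional_curve.csv")
    write_curve_csv(dc, files)
    info$E <- nd$scales$E
  }
  info$files <- files
  message(sprintf("[wallkinetics] mode '%s': wrote %d file(s) to %s",
                  config$mode, length(files), config$outdir))
  invisible(info)
}

#' Regenerate the package's reference figure data
#'
#' Writes one CSV per figure panel of the model's standard result set:
#' steady crosslink profiles and their `y^(1/alpha)` approximation
#' (`alpha = 0.1, 1, 10, 100`, `beta = 0.1`), the breakage kernel `G`
#' against its asymptotic limits (`beta = 0.01, 0.03, 0.1`), intramural
#' stress distributions (`alpha = 1, 3, 10, 100`), steady stress curves
#' with the scission-layer and saturating approximations
#' (`beta = 0.01, 0.03, 0.1`; matrix variant `Gamma = 0.01`), effective
#' extensibility curves, transient overshoot traces
#' (`alpha = 1, 5, 10, 50, 100`), and XEH / XET / expansin enzyme sweeps
#' (`g = 0, 1, 10, 100`). Data generation only; plotting is left to the
#' caller.
#'
#' @param outdir output directory.
#' @param numerics a [wall_numerics()] object, or `NULL`.
#' @param alpha_n grid resolution for the stress curves.
#' @param n_t time resolution of the transient traces.
#' @return Character vector of files written, invisibly.
#' @export
reproduce_figures <- function(outdir, numerics = NULL, alpha_n = 40L,
                              n_t = 400L) {
  num <- as_wall_numerics(numerics)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(obj, name) {
    f <- file.path(outdir, name)
    write_curve_csv(obj, f)
    files <<- c(files, f)
  }
  grid <- exp(seq(log(0.1), log(100), length.out = alpha_n))

  # steady profiles and their power-law approximation
  p1 <- wall_params(beta = 0.1)
  for (a in c(0.1, 1, 10, 100)) {
    pr <- steady_profile(a, p1, num)
    df <- as.data.frame(pr)
    df$n_powerlaw <- pr$y^(1 / a)
    attr(df, "params") <- p1
    put(df, sprintf("profile_alpha%g.csv", a))
  }
  # breakage kernel vs asymptotics
  for (b in c(0.01, 0.03, 0.1)) {
    pb <- wall_params(beta = b)
    y <- exp(seq(log(max(b / 30, 1e-4)), 0, length.out = 200))
    df <- data.frame(y = y, G = g_integral(y, pb, num),
                     G_asymptotic = g_asymptotic(y, pb))
    attr(df, "params") <- pb
    put(df, sprintf("g_kernel_beta%g.csv", b))
  }
  # intramural stress distribution
  for (a in c(1, 3, 10, 100))
    put(steady_profile(a, p1, num), sprintf("stress_dist_alpha%g.csv", a))
  # steady stress curves and approximations
  for (b in c(0.01, 0.03, 0.1)) {
    pb <- wall_params(beta = b)
    cur <- stress_curve(grid, pb, num)
    fC <- fit_C(pb, num)
    df <- as.data.frame(cur)
    df$sigma_scission <- sigma_approx_full(grid, pb, fC$C)
    df$sigma_saturating <- sigma_approx_limit(grid, pb, fC$L_script)
    attr(df, "params") <- pb
    put(df, sprintf("steady_beta%g.csv", b))
  }
  # matrix-dominated post-yield variant with the Lockhart overlay
  pg <- wall_params(beta = 0.1, Gamma = 0.01)
  cur <- stress_curve(grid, pg, num)
  fC <- fit_C(pg, num)
  df <- as.data.frame(cur)
  # piecewise-linear Lockhart limits: (1+Gamma)*alpha pre-yield,
  # L + Gamma*alpha post-yield (the lower envelope)
  df$sigma_lockhart <- pmin((1 + pg$Gamma) * grid,
                            fC$L_script + pg$Gamma * grid)
  attr(df, "params") <- pg
  put(df, "steady_matrix.csv")
  # transient overshoot traces
  for (a in c(1, 5, 10, 50, 100))
    put(transient_trace(a, p1, num, n_t = n_t),
        sprintf("transient_alpha%g.csv", a))
  # enzyme sweeps
  for (g in c(0, 1, 10, 100)) {
    put(stress_curve(grid, wall_params(beta = 0.1, g_xeh = g), num),
        sprintf("xeh_g%g.csv", g))
    put(stress_curve(grid, wall_params(beta = 0.1, g_xet = g), num),
        sprintf("xet_g%g.csv", g))
    put(stress_curve(grid, wall_params(beta = 0.1, g_exp = g), num),
        sprintf("expansin_g%g.csv", g))
  }
  invisible(files)
}
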